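# Morphologic traits: height percentiles, projected area, trapezoidal
# integrators, and the full trait record.

test_that("height filter removes points below the threshold", {
  cl <- data.frame(x = 1:3, y = 0, z = 0, height = c(0.02, 0.10, 0.5))
  expect_equal(height_filter(cl, 0.05)$height, c(0.10, 0.5))
  expect_equal(nrow(height_filter(cl, 0)), 3)
  same <- data.frame(x = 1, y = 1, z = 1, height = 0.5)
  expect_equal(nrow(height_filter(same, 0.05)), 1)
})

test_that("canopy height percentiles use interpolated order statistics", {
  # 100 heights 0.01..1.00: the 85th percentile under linear interpolation
  # is 0.01 * (1 + 0.85 * 99) = 0.8515
  cl <- data.frame(height = seq(0.01, 1, by = 0.01))
  ch <- canopy_height(cl)
  expect_equal(unname(ch["p85"]), 0.8515)
  expect_equal(unname(ch["p100"]), 1.0)
  expect_true(all(diff(ch) >= 0))                 # monotone in level
  # order invariance
  expect_equal(canopy_height(cl[sample(100), , drop = FALSE]), ch)
  # constant heights: every percentile equals the constant
  cc <- data.frame(height = rep(0.4, 17))
  expect_true(all(canopy_height(cc) == 0.4))
  expect_error(canopy_height(cl[0, , drop = FALSE]), "empty")
})

test_that("projected area recovers a dense unit square and rejects degenerate input", {
  g <- expand.grid(x = seq(0, 1, length.out = 50),
                   y = seq(0, 1, length.out = 50))
  pa <- projected_area(g, method = "alpha", param = 0.5)
  expect_equal(pa$pca, 1, tolerance = 0.02)
  expect_equal(unname(pa$bbox), c(1, 1))
  pg <- projected_area(g, method = "grid", param = 0.02)
  expect_equal(pg$pca, 1, tolerance = 0.05)
  expect_error(projected_area(data.frame(x = 1:3, y = 2 * (1:3))),
               "collinear")
  expect_error(projected_area(g[1:2, ]), "3 distinct")
})

test_that("alpha-shape area is concave: below the convex hull, above for large alpha", {
  set.seed(5)
  th <- runif(800, 0, 2 * pi); r <- sqrt(runif(800))
  disk <- data.frame(x = r * cos(th), y = r * sin(th))
  hull_area <- abs(sum(with(disk[chull(disk$x, disk$y), ],
                            x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2)
  a_small <- projected_area(disk, "alpha", param = 0.2)$pca
  a_big <- projected_area(disk, "alpha", param = 10)$pca
  expect_lte(a_small, hull_area + 1e-9)
  expect_equal(a_big, hull_area, tolerance = 1e-9)
  expect_equal(a_small, pi, tolerance = 0.1)

  # an annulus keeps its hole
  th2 <- runif(2000, 0, 2 * pi); r2 <- sqrt(runif(2000, 0.5^2, 1))
  ann <- data.frame(x = r2 * cos(th2), y = r2 * sin(th2))
  a_ann <- projected_area(ann, "alpha", param = 0.15)$pca
  expect_equal(a_ann, pi * (1 - 0.25), tolerance = 0.12)
})

test_that("grid-method area is monotone under point-set inclusion", {
  set.seed(8)
  big <- data.frame(x = runif(500), y = runif(500))
  small <- big[1:100, ]
  a_small <- projected_area(small, "grid", param = 0.05)$pca
  a_big <- projected_area(big, "grid", param = 0.05)$pca
  expect_lte(a_small, a_big)
})

test_that("scan_area implements the trapezoidal rule exactly on linear pieces", {
  # rectangle
  expect_equal(scan_area(c(0, 2), c(0.7, 0.7)), 1.4)
  # ramp z = y over [0, 1] at arbitrary knots: exactly 0.5
  set.seed(2)
  y <- sort(c(0, runif(40), 1))
  expect_equal(scan_area(y, y), 0.5, tolerance = 1e-15)
  # fewer than 2 samples
  expect_equal(scan_area(numeric(0), numeric(0)), 0)
  expect_equal(scan_area(1, 1), 0)
  expect_error(scan_area(c(1, 0), c(1, 1)), "sorted")

  # semicircular profile sampled at 571 points: quadrature oracle
  y <- seq(-1, 1, length.out = 571)
  z <- sqrt(pmax(1 - y^2, 0))
  oracle <- integrate(function(u) sqrt(pmax(1 - u^2, 0)), -1, 1,
                      abs.tol = 1e-12)$value
  expect_equal(scan_area(y, z), oracle, tolerance = 1e-3)
  expect_equal(oracle, pi / 2, tolerance = 1e-9)
})

test_that("scan_area is exact to 1e-12 relative error on piecewise-linear profiles", {
  set.seed(31)
  for (rep in 1:25) {
    # random piecewise-linear profile: knots + exact trapezoid-by-parts
    k <- sample(3:12, 1)
    knots_y <- sort(runif(k, 0, 3))
    knots_z <- runif(k, 0, 2)
    # resample at the knots plus points on the segments (still exact)
    yy <- sort(unique(c(knots_y, runif(20, min(knots_y), max(knots_y)))))
    zz <- approx(knots_y, knots_z, xout = yy)$y
    truth <- sum(diff(knots_y) * (head(knots_z, -1) + tail(knots_z, -1)) / 2)
    expect_equal(scan_area(yy, zz), truth, tolerance = 1e-12)
  }
})

test_that("plant_volume integrates per-scan areas along the track", {
  expect_equal(plant_volume(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_warning(v1 <- plant_volume(1, 0.5), "fewer than 2")
  expect_equal(v1, 0)
  expect_error(plant_volume(c(1, 0), c(1, 1)), "sorted")
  # linear area profile: exact
  l <- seq(0, 2, by = 0.05)
  expect_equal(plant_volume(l, 3 * l), 0.5 * 2 * 6 * 2 / 2)
})

test_that("simulated box volume is recovered within 2% at 0.01 m scan spacing", {
  sc <- build_scene(list(canopy_shape("box", 2, 0, list(lx = 2, ly = 1, h = 0.5))))
  res <- run_pipeline(sc, pass_config(range_noise_sd = 0), key = "box0")
  expect_equal(res$traits$pv, 1, tolerance = 0.02)
  expect_equal(res$traits$max_ch, 0.5, tolerance = 0.01)
})

test_that("hemisphere traits match the visibility-corrected analytic oracle", {
  # From a single 2.4 m overhead pass the dome rim below the tangent
  # circle (z_t = rho^2 / 2.4 per slice) is self-occluded; the honest
  # oracle is the visible part of the solid, not the full solid.
  res <- run_pipeline(hemi_scene(), pass_config(range_noise_sd = 0),
                      key = "hemi0")
  tr <- res$traits
  expect_equal(tr$max_ch, 1, tolerance = 0.01)
  # visible footprint: integral of the per-slice tangent half-width
  vis_area <- 2 * integrate(function(x) {
    rho2 <- pmax(1 - x^2, 0)
    sqrt(rho2) * sqrt(pmax(1 - rho2 / 2.4^2, 0))
  }, -1, 1)$value
  expect_equal(tr$pca, vis_area, tolerance = 0.05)
  # visible volume: per-slice area above the tangent chord
  vis_vol <- integrate(Vectorize(function(x) {
    rho2 <- max(1 - x^2, 0); rho <- sqrt(rho2)
    if (rho < 1e-9) return(0)
    yt <- rho * sqrt(max(1 - rho2 / 5.76, 0)); zt <- rho2 / 2.4
    yt * zt + rho2 * asin(min(yt / rho, 1))
  }), -1, 1)$value
  expect_equal(tr$pv, vis_vol, tolerance = 0.05)
  # percentile vector monotone, bbox consistency, pv bound
  ch <- unlist(tr[paste0("ch_p", c(85, 88, 91, 94, 97, 100))])
  expect_true(all(diff(ch) >= 0))
  expect_lte(tr$pca, tr$bbox_length * tr$bbox_width)
  expect_lte(tr$pv, tr$bbox_length * tr$bbox_width * tr$max_ch)
})

test_that("volume error shrinks when scan and beam spacing are halved", {
  sc <- hemi_scene()
  coarse <- run_pipeline(sc, pass_config(range_noise_sd = 0,
                                         resolution_deg = 2 / 3,
                                         f_lidar = 25, f_gps = 5),
                         key = "hemi_coarse")
  fine <- run_pipeline(sc, pass_config(range_noise_sd = 0), key = "hemi0")
  err_coarse <- abs(coarse$traits$pv - 2 * pi / 3)
  err_fine <- abs(fine$traits$pv - 2 * pi / 3)
  expect_lt(err_fine, err_coarse)
})

test_that("traits are invariant under in-plane translation", {
  set.seed(21)
  cl <- data.frame(x = runif(400, 0, 1), y = runif(400, 0, 1),
                   z = runif(400, 0, 0.5))
  cl$height <- cl$z
  cl$frame_index <- as.integer(cut(cl$x, 20))
  cl$beam_order <- ave(seq_len(400), cl$frame_index, FUN = seq_along)
  t0 <- extract_traits(cl, plot_id = "a")
  cl2 <- cl; cl2$x <- cl$x + 5; cl2$y <- cl$y - 3
  t1 <- extract_traits(cl2, plot_id = "a")
  for (col in c("max_ch", "pca", "pv", "bbox_length", "bbox_width",
                "ch_p85", "ch_p100"))
    expect_equal(t1[[col]], t0[[col]], tolerance = 1e-9)
})

test_that("degenerate plots yield an explicit empty record", {
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      height = numeric(), frame_index = integer())
  rec <- extract_traits(empty, plot_id = "void")
  expect_equal(rec$n_points, 0)
  expect_true(is.na(rec$pv) && is.na(rec$pca) && is.na(rec$max_ch))
})
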