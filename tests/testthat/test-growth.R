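# Logistic growth fitting, growth rates, cultivar ANOVA, and
# trait-yield regression.

dap8 <- c(45, 52, 67, 74, 88, 95, 102, 109)

test_that("noise-free logistic data is recovered to 1e-6 relative error", {
  grid <- expand.grid(x0 = c(0.05, 0.1, 0.3), xn = c(0.8, 1.0, 2.5),
                      tau = c(0.05, 0.12, 0.2))
  for (k in seq_len(nrow(grid))) {
    p <- grid[k, ]
    y <- logistic3(dap8, p$x0, p$xn, p$tau, T = 45)
    fit <- fit_3plm(dap8, y, T = 45)
    expect_true(fit$converged)
    expect_equal(unname(fit$par[["x0"]]), p$x0, tolerance = 1e-6)
    expect_equal(unname(fit$par[["xn"]]), p$xn, tolerance = 1e-6)
    expect_equal(unname(fit$par[["tau"]]), p$tau, tolerance = 1e-6)
  }
})

test_that("the fitted curve passes through x0 at the reference day", {
  y <- logistic3(dap8, 0.1, 1, 0.12, T = 45)
  fit <- fit_3plm(dap8, y, T = 45)
  expect_equal(predict_3plm(fit, 45), unname(fit$par[["x0"]]),
               tolerance = 1e-12)
  # asymptote and the degenerate x0 = xn case
  expect_equal(logistic3(1e6, 0.1, 1, 0.12), 1, tolerance = 1e-12)
  expect_equal(logistic3(c(0, 50, 200), 0.7, 0.7, 0.3), rep(0.7, 3))
})

test_that("noisy replicates give nearly unbiased parameter estimates", {
  truth <- c(x0 = 0.1, xn = 1.0, tau = 0.12)
  est <- matrix(NA_real_, 50, 3, dimnames = list(NULL, names(truth)))
  set.seed(1234)
  for (r in 1:50) {
    y <- logistic3(dap8, truth["x0"], truth["xn"], truth["tau"], T = 45) +
      rnorm(8, sd = 0.02 * truth["xn"])
    fit <- fit_3plm(dap8, pmax(y, 1e-4), T = 45)
    est[r, ] <- fit$par[names(truth)]
  }
  bias <- abs(colMeans(est) - truth) / truth
  expect_true(all(bias <= 0.05))
})

test_that("constant series flags tau as unidentifiable and CIs are ordered", {
  fit <- fit_3plm(dap8, rep(0.8, 8), T = 45)
  expect_equal(unname(fit$par[["x0"]]), 0.8, tolerance = 1e-4)
  expect_equal(unname(fit$par[["xn"]]), 0.8, tolerance = 1e-4)
  expect_true("tau_unidentifiable" %in% fit$flags)

  y <- logistic3(dap8, 0.1, 1, 0.12, T = 45) + c(0.01, -0.01)
  f2 <- fit_3plm(dap8, y, T = 45)
  expect_true(all(f2$ci["lwr", ] <= f2$par & f2$par <= f2$ci["upr", ]))
  expect_error(fit_3plm(c(45, 52, 67), c(1, 2, 3)), "at least 4")
  expect_error(fit_3plm(dap8, -seq_len(8)), "positive")

  # bootstrap intervals bracket the estimates too
  fb <- fit_3plm(dap8, y, T = 45, ci_method = "bootstrap", n_boot = 50)
  expect_true(all(fb$ci["lwr", ] <= fb$par + 1e-9 &
                    fb$par <= fb$ci["upr", ] + 1e-9))
})

test_that("growth rate is the per-interval difference quotient with period labels", {
  gr <- growth_rate(c(45, 55), c(1.0, 1.18))
  expect_equal(gr$gr, 0.018)
  # constant series: zero everywhere; linear series: constant slope
  expect_true(all(growth_rate(dap8, rep(2, 8))$gr == 0))
  expect_equal(growth_rate(dap8, 0.3 * dap8)$gr, rep(0.3, 7))
  # reference calendar labels P1..P8
  gr8 <- growth_rate(c(43, dap8), seq(0.1, 0.9, by = 0.1))
  expect_equal(gr8$interval, paste0("P", 1:8))
  expect_equal(growth_rate(c(50, 60), c(1, 2))$interval, "I1")
  expect_equal(nrow(growth_rate(45, 1)), 0)
  expect_error(growth_rate(c(45, 45), c(1, 2)), "duplicate")
})

test_that("cultivar ANOVA reduces to the two-sample t-test when there are two groups", {
  set.seed(77)
  d <- data.frame(dap = 45,
                  trait = c(rnorm(10, 1), rnorm(10, 1.3)),
                  cultivar = rep(c("a", "b"), each = 10))
  res <- cultivar_anova(d, trait_cols = "trait")
  tt <- t.test(trait ~ cultivar, data = d, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # F = t^2
  f <- anova(lm(trait ~ cultivar, d))[1, "F value"]
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-12)
})

test_that("cultivar ANOVA detects huge effects and validates its inputs", {
  set.seed(42)
  d <- data.frame(dap = rep(c(45, 52), each = 16),
                  trait = rnorm(32, sd = 1) +
                    rep(rep(c(0, 10), each = 8), 2),
                  cultivar = rep(rep(c("a", "b"), each = 8), 2))
  res <- cultivar_anova(d, trait_cols = "trait")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_value < 1e-6))
  bad <- data.frame(dap = 45, trait = c(1, 2), cultivar = c("a", "b"))
  expect_error(cultivar_anova(bad, trait_cols = "trait"), ">= 2")
})

test_that("ANOVA null p-values are uniform (KS) and rejection is calibrated", {
  set.seed(2024)
  p <- replicate(1000, {
    d <- data.frame(dap = 45, trait = rnorm(32),
                    cultivar = rep(paste0("cv", 1:4), each = 8))
    cultivar_anova(d, trait_cols = "trait")$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("trait-yield regression reports exact and null R^2 correctly", {
  tr <- data.frame(plot_id = sprintf("p%02d", 1:8), dap = 45,
                   trait = seq(0.5, 1.2, by = 0.1))
  yl <- data.frame(plot_id = tr$plot_id, cultivar = "a",
                   yield = 2 * tr$trait)
  res <- trait_yield_regression(tr, yl, trait_cols = "trait")
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(unname(res$slope), 2, tolerance = 1e-12)

  # R^2 invariant under affine rescaling of the trait
  tr2 <- tr; tr2$trait <- 3.7 * tr$trait - 1.2
  yl2 <- yl; yl2$yield <- yl$yield + rnorm(8, sd = 0.1)
  r_a <- trait_yield_regression(tr, yl2, trait_cols = "trait")$r2
  r_b <- trait_yield_regression(tr2, yl2, trait_cols = "trait")$r2
  expect_equal(r_a, r_b, tolerance = 1e-12)

  # constant trait: flagged NA
  tr3 <- tr; tr3$trait <- 1
  expect_warning(res3 <- trait_yield_regression(tr3, yl, trait_cols = "trait"),
                 "constant")
  expect_true(is.na(res3$r2))
  expect_error(trait_yield_regression(tr[1:2, ], yl, trait_cols = "trait"),
               "fewer than 3")
})

test_that("null mean R^2 is about 1/(n-1) at n = 32", {
  set.seed(55)
  r2 <- replicate(500, {
    tr <- data.frame(plot_id = sprintf("p%02d", 1:32), dap = 45,
                     trait = rnorm(32))
    yl <- data.frame(plot_id = tr$plot_id, cultivar = "a",
                     yield = abs(rnorm(32, 900, 80)))
    trait_yield_regression(tr, yl, trait_cols = "trait", by = "pooled")$r2
  })
  expect_equal(mean(r2), 1 / 31, tolerance = 0.25)
  expect_lt(abs(mean(r2) - 1 / 31), 0.008)
})

test_that("simulated field traits support the full growth workflow", {
  sim <- simulate_field_traits(seed = 9)
  expect_equal(nrow(sim$traits), 4 * 32 * 8)
  # per-cultivar mean fits recover distinct asymptotes
  fits <- lapply(split(sim$traits, sim$traits$cultivar), function(d) {
    agg <- aggregate(trait ~ dap, d, mean)
    fit_3plm(agg$dap, agg$trait, T = 45)
  })
  xns <- vapply(fits, function(f) unname(f$par[["xn"]]), numeric(1))
  expect_equal(unname(xns[c("cv1", "cv4")]), c(1.08, 0.88), tolerance = 0.05)
  # cultivar effect is detectable; trait correlates with yield
  an <- cultivar_anova(sim$traits[sim$traits$dap == 88, ],
                       trait_cols = "trait")
  expect_lt(an$p_value, 0.01)
  r2 <- trait_yield_regression(sim$traits[sim$traits$dap == 88, ],
                               sim$yields, trait_cols = "trait")
  expect_true(all(r2$n == 32))
  expect_gt(mean(r2$r2), 0.2)
})
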