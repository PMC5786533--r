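# Seeded scan simulator over analytic canopy solids.
#
# The scene is a flat ground plane carrying parametric solids (hemisphere,
# ellipsoid cap, box, cone) whose maximum height, footprint area and volume
# are known in closed form, plus optional weed spheres and enclosure walls.
# Beams are cast exactly against these surfaces, so the simulator doubles
# as the analytic oracle for every downstream stage.

#' Define an analytic canopy solid
#'
#' Shapes rest on the scene's ground plane; their apex height, footprint
#' area and volume are computed in closed form and attached as ground
#' truth.
#'
#' @param kind one of `"hemisphere"`, `"ellipsoid_cap"`, `"box"`, `"cone"`.
#' @param center_x,center_y footprint centre in metres.
#' @param dims named list of dimensions in metres:
#'   hemisphere `r`; ellipsoid_cap semi-axes `a`, `b`, `c` (upper half);
#'   box `lx`, `ly`, `h`; cone base radius `r` and height `h`.
#' @return an object of class `canopy_shape`.
#' @examples
#' canopy_shape("hemisphere", 0, 0, list(r = 1))
#' @export
canopy_shape <- function(kind, center_x, center_y, dims) {
  kind <- match.arg(kind, c("hemisphere", "ellipsoid_cap", "box", "cone"))
  need <- switch(kind,
    hemisphere = "r", ellipsoid_cap = c("a", "b", "c"),
    box = c("lx", "ly", "h"), cone = c("r", "h"))
  missing <- setdiff(need, names(dims))
  if (length(missing))
    stop(sprintf("shape '%s' needs dims: %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  dims <- dims[need]
  if (any(!vapply(dims, function(d) is.numeric(d) && d > 0, logical(1))))
    stop("all shape dimensions must be positive numbers", call. = FALSE)
  s <- list(kind = kind, center_x = center_x, center_y = center_y,
            dims = lapply(dims, as.numeric))
  s <- c(s, shape_truth(s))
  structure(s, class = "canopy_shape")
}

# closed-form max height, footprint area, volume and footprint bbox
shape_truth <- function(s) {
  d <- s$dims
  out <- switch(s$kind,
    hemisphere = list(max_height = d$r, footprint_area = pi * d$r^2,
                      volume = 2 / 3 * pi * d$r^3, half_x = d$r, half_y = d$r),
    ellipsoid_cap = list(max_height = d$c, footprint_area = pi * d$a * d$b,
                         volume = 2 / 3 * pi * d$a * d$b * d$c,
                         half_x = d$a, half_y = d$b),
    box = list(max_height = d$h, footprint_area = d$lx * d$ly,
               volume = d$lx * d$ly * d$h,
               half_x = d$lx / 2, half_y = d$ly / 2),
    cone = list(max_height = d$h, footprint_area = pi * d$r^2,
                volume = pi * d$r^2 * d$h / 3, half_x = d$r, half_y = d$r))
  out
}

#' @export
print.canopy_shape <- function(x, ...) {
  cat(sprintf("<canopy_shape %s at (%.2f, %.2f): h=%.3f m, A=%.3f m^2, V=%.3f m^3>\n",
              x$kind, x$center_x, x$center_y,
              x$max_height, x$footprint_area, x$volume))
  invisible(x)
}

#' Assemble a simulated field scene
#'
#' @param shapes list of [canopy_shape()] objects.
#' @param ground_z elevation of the ground plane (m).
#' @param weeds list of weed blobs, each a list with `center` (x, y),
#'   `radius` (m) and optionally `z` (centre height; defaults to resting
#'   on the ground).  Weeds are ray-cast as small spheres detached from
#'   the canopy solids.
#' @param enclosure_halfwidth cross-track distance of the two vertical
#'   enclosure walls (m), or `NULL` for no walls.
#' @return an object of class `scene` carrying a `ground_truth`
#'   data frame (one row per shape, closed-form values).
#' @examples
#' sc <- build_scene(list(canopy_shape("hemisphere", 2, 0, list(r = 1))))
#' sc$ground_truth
#' @export
build_scene <- function(shapes = list(), ground_z = 0, weeds = list(),
                        enclosure_halfwidth = NULL) {
  if (inherits(shapes, "canopy_shape")) shapes <- list(shapes)
  ok <- vapply(shapes, inherits, logical(1), what = "canopy_shape")
  if (length(shapes) && !all(ok))
    stop("'shapes' must be a list of canopy_shape objects", call. = FALSE)
  # reject overlapping footprints (conservative bbox test)
  if (length(shapes) >= 2) {
    for (i in seq_len(length(shapes) - 1)) {
      for (j in seq(i + 1, length(shapes))) {
        a <- shapes[[i]]; b <- shapes[[j]]
        if (abs(a$center_x - b$center_x) < a$half_x + b$half_x &&
            abs(a$center_y - b$center_y) < a$half_y + b$half_y)
          stop(sprintf("footprints of shapes %d (%s) and %d (%s) overlap",
                       i, a$kind, j, b$kind), call. = FALSE)
      }
    }
  }
  weeds <- lapply(weeds, function(w) {
    stopifnot(length(w$center) == 2, is.numeric(w$radius), w$radius > 0)
    if (is.null(w$z)) w$z <- ground_z + w$radius
    w
  })
  for (w in weeds) {
    for (s in shapes) {
      if (abs(w$center[1] - s$center_x) < s$half_x + w$radius &&
          abs(w$center[2] - s$center_y) < s$half_y + w$radius)
        stop("weed blob intersects a shape footprint", call. = FALSE)
    }
  }
  gt <- if (length(shapes)) {
    data.frame(
      shape = seq_along(shapes),
      kind = vapply(shapes, `[[`, character(1), "kind"),
      center_x = vapply(shapes, `[[`, numeric(1), "center_x"),
      center_y = vapply(shapes, `[[`, numeric(1), "center_y"),
      max_height = vapply(shapes, `[[`, numeric(1), "max_height"),
      footprint_area = vapply(shapes, `[[`, numeric(1), "footprint_area"),
      volume = vapply(shapes, `[[`, numeric(1), "volume"))
  } else {
    data.frame(shape = integer(), kind = character(), center_x = numeric(),
               center_y = numeric(), max_height = numeric(),
               footprint_area = numeric(), volume = numeric())
  }
  structure(list(ground_z = ground_z, shapes = shapes, weeds = weeds,
                 enclosure_halfwidth = enclosure_halfwidth,
                 ground_truth = gt),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene: %d shape(s), %d weed blob(s), ground z=%.2f%s>\n",
              length(x$shapes), length(x$weeds), x$ground_z,
              if (is.null(x$enclosure_halfwidth)) ""
              else sprintf(", walls at y=±%.2f", x$enclosure_halfwidth)))
  invisible(x)
}

#' Scanner pass configuration
#'
#' Defaults reproduce the reference acquisition geometry: an overhead
#' scanner 2.4 m above ground, 190 degree aperture at 1/3 degree
#' resolution (571 beams per frame), 50 Hz frames, 5 Hz GPS fixes, and a
#' platform speed of 0.5 m/s.
#'
#' @param speed platform speed (m/s).
#' @param f_gps GPS fix rate (Hz).
#' @param f_lidar frame rate (Hz); must be an integer multiple of `f_gps`.
#' @param aperture_deg angular span of one frame (degrees).
#' @param resolution_deg beam spacing (degrees); `aperture_deg /
#'   resolution_deg` must be an integer.
#' @param sensor_height scanner elevation above ground (m).
#' @param range_noise_sd additive Gaussian range noise, 1 sd (m).
#' @param max_range no-echo sentinel range (m).
#' @param seed RNG seed used for the range noise.
#' @return an object of class `pass_config`.
#' @export
pass_config <- function(speed = 0.5, f_gps = 5, f_lidar = 50,
                        aperture_deg = 190, resolution_deg = 1 / 3,
                        sensor_height = 2.4, range_noise_sd = 0.005,
                        max_range = 80, seed = 1L) {
  alpha <- f_lidar / f_gps
  if (abs(alpha - round(alpha)) > 1e-9)
    stop("f_lidar must be an integer multiple of f_gps", call. = FALSE)
  nb <- aperture_deg / resolution_deg
  if (abs(nb - round(nb)) > 1e-6)
    stop("aperture_deg / resolution_deg must be an integer", call. = FALSE)
  stopifnot(speed > 0, sensor_height > 0, range_noise_sd >= 0, max_range > 0)
  structure(list(speed = speed, f_gps = f_gps, f_lidar = f_lidar,
                 aperture_deg = aperture_deg, resolution_deg = resolution_deg,
                 sensor_height = sensor_height,
                 range_noise_sd = range_noise_sd, max_range = max_range,
                 seed = as.integer(seed)),
            class = "pass_config")
}

#' Beam angles of one frame
#'
#' Angles are measured in the vertical scan plane with 90 degrees at
#' nadir; a 190 degree aperture spans -5 to 185 degrees.
#'
#' @param cfg a [pass_config()].
#' @return numeric vector of `floor(aperture/resolution) + 1` angles (deg).
#' @export
beam_angles <- function(cfg) {
  nb <- floor(cfg$aperture_deg / cfg$resolution_deg + 1e-9) + 1
  90 - cfg$aperture_deg / 2 + (seq_len(nb) - 1) * cfg$resolution_deg
}

# Vectorised exact ray casting.  O: n x 3 origins, D: n x 3 unit
# directions.  Returns the distance to the nearest surface (Inf = no hit).
cast_rays <- function(scene, O, D) {
  n <- nrow(O)
  best <- rep(Inf, n)
  gz <- scene$ground_z
  take <- function(t, best) {
    t[!is.finite(t) | t <= 1e-12] <- Inf
    pmin(best, t)
  }
  # ground plane
  tg <- (gz - O[, 3]) / D[, 3]
  best <- take(ifelse(D[, 3] < 0, tg, Inf), best)
  # quadric helper: smallest positive root of a t^2 + b t + c = 0
  # subject to a per-root z-interval predicate
  quad_hits <- function(a, b, c, zmin, zmax, Oz, Dz) {
    disc <- b^2 - 4 * a * c
    tbest <- rep(Inf, length(a))
    ok <- disc >= 0 & abs(a) > 1e-300
    if (!any(ok)) return(tbest)
    sq <- sqrt(pmax(disc, 0))
    for (sgn in c(-1, 1)) {
      t <- (-b + sgn * sq) / (2 * a)
      z <- Oz + t * Dz
      good <- ok & t > 1e-12 & z >= zmin - 1e-12 & z <= zmax + 1e-12
      tbest[good] <- pmin(tbest[good], t[good])
    }
    tbest
  }
  for (s in scene$shapes) {
    d <- s$dims
    if (s$kind == "hemisphere" || s$kind == "ellipsoid_cap") {
      ax <- if (s$kind == "hemisphere") c(d$r, d$r, d$r) else c(d$a, d$b, d$c)
      ox <- (O[, 1] - s$center_x) / ax[1]
      oy <- (O[, 2] - s$center_y) / ax[2]
      oz <- (O[, 3] - gz) / ax[3]
      dx <- D[, 1] / ax[1]; dy <- D[, 2] / ax[2]; dz <- D[, 3] / ax[3]
      a <- dx^2 + dy^2 + dz^2
      b <- 2 * (ox * dx + oy * dy + oz * dz)
      c0 <- ox^2 + oy^2 + oz^2 - 1
      best <- take(quad_hits(a, b, c0, gz, Inf, O[, 3], D[, 3]), best)
    } else if (s$kind == "cone") {
      k <- (d$r / d$h)^2
      apex_z <- gz + d$h
      wx <- O[, 1] - s$center_x; wy <- O[, 2] - s$center_y
      wz <- O[, 3] - apex_z
      a <- D[, 1]^2 + D[, 2]^2 - k * D[, 3]^2
      b <- 2 * (wx * D[, 1] + wy * D[, 2] - k * wz * D[, 3])
      c0 <- wx^2 + wy^2 - k * wz^2
      best <- take(quad_hits(a, b, c0, gz, apex_z, O[, 3], D[, 3]), best)
    } else if (s$kind == "box") {
      lo <- c(s$center_x - d$lx / 2, s$center_y - d$ly / 2, gz)
      hi <- c(s$center_x + d$lx / 2, s$center_y + d$ly / 2, gz + d$h)
      tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
      for (ax in 1:3) {
        dd <- D[, ax]; oo <- O[, ax]
        t1 <- (lo[ax] - oo) / dd
        t2 <- (hi[ax] - oo) / dd
        par <- abs(dd) < 1e-300
        lo_t <- pmin(t1, t2); hi_t <- pmax(t1, t2)
        # parallel rays: inside slab keeps (-Inf, Inf), outside never hits
        inside <- oo >= lo[ax] & oo <= hi[ax]
        lo_t[par] <- ifelse(inside[par], -Inf, Inf)
        hi_t[par] <- ifelse(inside[par], Inf, -Inf)
        tmin <- pmax(tmin, lo_t); tmax <- pmin(tmax, hi_t)
      }
      hit <- tmin <= tmax & tmax > 1e-12
      tbox <- ifelse(hit, ifelse(tmin > 1e-12, tmin, tmax), Inf)
      best <- take(tbox, best)
    }
  }
  for (w in scene$weeds) {
    ox <- O[, 1] - w$center[1]; oy <- O[, 2] - w$center[2]
    oz <- O[, 3] - w$z
    a <- rowSums(D^2)
    b <- 2 * (ox * D[, 1] + oy * D[, 2] + oz * D[, 3])
    c0 <- ox^2 + oy^2 + oz^2 - w$radius^2
    best <- take(quad_hits(a, b, c0, -Inf, Inf, O[, 3], D[, 3]), best)
  }
  if (!is.null(scene$enclosure_halfwidth)) {
    w <- scene$enclosure_halfwidth
    for (side in c(-1, 1)) {
      t <- (side * w - O[, 2]) / D[, 2]
      best <- take(t, best)
    }
  }
  best
}

#' Cast a single beam against a scene
#'
#' @param scene a [build_scene()] scene.
#' @param origin numeric length-3 beam origin (m).
#' @param direction numeric length-3 unit direction.
#' @return range to the nearest surface in metres, or `Inf` for no hit.
#' @export
cast_beam <- function(scene, origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6)
    stop("'direction' must be a unit vector", call. = FALSE)
  cast_rays(scene, matrix(origin, 1), matrix(direction, 1))
}

#' Simulate a constant-speed scanner pass over a scene
#'
#' The platform moves at constant speed along a straight segment with the
#' scanner at `sensor_height` above ground.  GPS fixes are emitted exactly
#' on the trajectory at `f_gps`; one LiDAR frame is emitted every
#' `1/f_lidar` seconds on the same clock.  No-hit beams carry the
#' `max_range` sentinel; i.i.d. Gaussian noise (sd `range_noise_sd`) is
#' added to hit ranges under the configured seed, so identical seeds give
#' identical streams.
#'
#' @param scene a [build_scene()] scene.
#' @param cfg a [pass_config()].
#' @param path list with numeric `from` and `to` (x, y) endpoints (m).
#' @return list with elements `gps` (data frame `t, x, y, z`), `frames`
#'   (long data frame `t, frame_id, angle_deg, range_m`), and `truth`
#'   (the scene's ground-truth table plus the trajectory).
#' @examples
#' sc <- build_scene(list(canopy_shape("hemisphere", 2, 0, list(r = 1))))
#' sim <- simulate_pass(sc, pass_config(range_noise_sd = 0),
#'                      list(from = c(0, 0), to = c(4, 0)))
#' nrow(sim$gps)
#' @export
simulate_pass <- function(scene, cfg, path) {
  stopifnot(inherits(scene, "scene"), inherits(cfg, "pass_config"))
  from <- as.numeric(path$from); to <- as.numeric(path$to)
  stopifnot(length(from) == 2, length(to) == 2)
  L <- sqrt(sum((to - from)^2))
  if (L <= 0) stop("zero-length path", call. = FALSE)
  hmax <- if (length(scene$shapes))
    max(vapply(scene$shapes, `[[`, numeric(1), "max_height")) else 0
  if (cfg$sensor_height <= hmax)
    stop("sensor_height must exceed the tallest shape", call. = FALSE)
  u <- (to - from) / L             # travel direction (2D)
  l <- c(-u[2], u[1])              # left cross-track unit
  T_end <- L / cfg$speed
  z0 <- scene$ground_z + cfg$sensor_height

  t_gps <- (0:floor(T_end * cfg$f_gps + 1e-9)) / cfg$f_gps
  gps <- data.frame(
    t = t_gps,
    x = from[1] + u[1] * cfg$speed * t_gps,
    y = from[2] + u[2] * cfg$speed * t_gps,
    z = z0)

  t_frames <- (0:floor(T_end * cfg$f_lidar + 1e-9)) / cfg$f_lidar
  nf <- length(t_frames)
  ang <- beam_angles(cfg)
  nb <- length(ang)
  th <- ang * pi / 180
  # one beam direction set per frame: d = cos(theta) * left - sin(theta) * z
  dirs <- matrix(c(cos(th) * l[1], cos(th) * l[2], -sin(th)), ncol = 3)
  O <- cbind(rep(from[1] + u[1] * cfg$speed * t_frames, each = nb),
             rep(from[2] + u[2] * cfg$speed * t_frames, each = nb),
             z0)
  D <- dirs[rep(seq_len(nb), nf), , drop = FALSE]
  r <- cast_rays(scene, O, D)
  r[r > cfg$max_range] <- Inf
  hit <- is.finite(r)
  if (cfg$range_noise_sd > 0) {
    r[hit] <- with_seed(cfg$seed,
                        r[hit] + rnorm(sum(hit), sd = cfg$range_noise_sd))
    r[hit] <- pmax(r[hit], 0)
  }
  r[!hit] <- cfg$max_range
  frames <- data.frame(
    t = rep(t_frames, each = nb),
    frame_id = rep(seq_len(nf), each = nb),
    angle_deg = rep(ang, nf),
    range_m = r)
  truth <- list(ground_truth = scene$ground_truth,
                trajectory = gps[, c("t", "x", "y", "z")],
                sensor_z = z0)
  list(gps = gps, frames = frames, truth = truth)
}

# evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
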