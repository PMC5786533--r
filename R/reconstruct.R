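# GPS/LiDAR fusion: georeference every scanned frame by constant-speed
# interpolation between consecutive GPS fixes, then map each beam's polar
# measurement into the local metric frame.

#' Sensor and fusion configuration
#'
#' @param f_gps GPS fix rate (Hz).
#' @param f_lidar frame rate (Hz); `f_lidar / f_gps` (the frame
#'   multiplicity per GPS interval) must be a positive integer.
#' @param sensor_height scanner elevation above ground (m); informational.
#' @param d_offset length-3 LiDAR-to-GPS lever arm (m), added to every
#'   interpolated frame position.
#' @param enclosure_range_bounds length-2 accepted beam-range interval
#'   (m) for the enclosure distance filter.
#' @param max_range no-echo sentinel range (m); beams at or beyond it are
#'   dropped during reconstruction.
#' @param clock_offset constant LiDAR-minus-GPS clock offset (s),
#'   subtracted from frame timestamps before synchronization.
#' @return an object of class `sensor_config`.
#' @export
sensor_config <- function(f_gps = 5, f_lidar = 50, sensor_height = 2.4,
                          d_offset = c(0, 0, 0),
                          enclosure_range_bounds = c(0, Inf),
                          max_range = 80, clock_offset = 0) {
  alpha <- f_lidar / f_gps
  if (alpha <= 0 || abs(alpha - round(alpha)) > 1e-9)
    stop("f_lidar / f_gps must be a positive integer", call. = FALSE)
  stopifnot(length(d_offset) == 3, length(enclosure_range_bounds) == 2,
            enclosure_range_bounds[1] < enclosure_range_bounds[2])
  structure(list(f_gps = f_gps, f_lidar = f_lidar, alpha = as.integer(round(alpha)),
                 sensor_height = sensor_height, d_offset = as.numeric(d_offset),
                 enclosure_range_bounds = as.numeric(enclosure_range_bounds),
                 max_range = max_range, clock_offset = clock_offset),
            class = "sensor_config")
}

check_gps <- function(gps) {
  stopifnot(is.data.frame(gps), all(c("t", "x", "y", "z") %in% names(gps)))
  if (nrow(gps) == 0) stop("empty GPS stream", call. = FALSE)
  if (is.unsorted(gps$t, strictly = TRUE))
    stop("GPS timestamps must be strictly increasing", call. = FALSE)
  gps
}

#' Assign each LiDAR frame to its GPS interval
#'
#' Frames are matched to fixes on a shared clock: a frame belongs to the
#' interval starting at the last fix at or before its timestamp (a frame
#' exactly on a fix time starts that fix's interval).  Frames timestamped
#' before the first fix are dropped and counted.
#'
#' @param gps data frame `t, x, y, z` with strictly increasing `t`.
#' @param frames long data frame `t, frame_id, angle_deg, range_m`.
#' @param cfg a [sensor_config()].
#' @return a per-frame data frame `frame_id, t, interval, j` (interval is
#'   the 1-based fix index; `j` counts frames within the interval from 0)
#'   with attribute `dropped` (count of too-early frames).
#' @export
synchronize <- function(gps, frames, cfg = sensor_config()) {
  check_gps(gps)
  stopifnot(all(c("t", "frame_id", "range_m") %in% names(frames)))
  if (nrow(frames) == 0) stop("empty frame stream", call. = FALSE)
  ft <- frames[!duplicated(frames$frame_id), c("frame_id", "t")]
  ft <- ft[order(ft$t, ft$frame_id), ]
  ft$t <- ft$t - cfg$clock_offset
  if (max(ft$t) < min(gps$t))
    stop("GPS and LiDAR time spans do not overlap", call. = FALSE)
  iv <- findInterval(ft$t + 1e-12, gps$t)
  drop <- iv == 0
  out <- data.frame(frame_id = ft$frame_id[!drop], t = ft$t[!drop],
                    interval = iv[!drop])
  out$j <- stats::ave(rep(0, nrow(out)), out$interval,
                      FUN = function(v) seq_along(v) - 1)
  attr(out, "dropped") <- sum(drop)
  out
}

#' Interpolate a position for every frame
#'
#' Within the GPS interval `[P(i), P(i+1)]` the platform is assumed to
#' move at constant speed, so the j-th of the `alpha = f_lidar / f_gps`
#' frames in the interval sits at `P(i) + j * (P(i+1) - P(i)) / alpha`,
#' plus the fixed LiDAR-to-GPS offset.  Frames at or after the last fix
#' are extrapolated at the last interval's velocity; their count is
#' returned as attribute `extrapolated`.
#'
#' @param gps data frame `t, x, y, z`.
#' @param sync synchronization table from [synchronize()], or `NULL` to
#'   compute it from `frames`.
#' @param cfg a [sensor_config()].
#' @param frames frame stream, required when `sync` is `NULL`.
#' @return data frame `frame_id, x, y, z` of frame positions.
#' @export
frame_positions <- function(gps, sync = NULL, cfg = sensor_config(),
                            frames = NULL) {
  check_gps(gps)
  if (is.null(sync)) sync <- synchronize(gps, frames, cfg)
  n <- nrow(gps)
  P <- as.matrix(gps[, c("x", "y", "z")])
  # forward per-interval step; the last interval's step also serves the tail
  if (n >= 2) {
    step <- (P[-1, , drop = FALSE] - P[-n, , drop = FALSE]) / cfg$alpha
    step <- rbind(step, step[n - 1, ])
  } else {
    step <- matrix(0, 1, 3)
  }
  i <- pmin(sync$interval, n)
  pos <- P[i, , drop = FALSE] + sync$j * step[i, , drop = FALSE]
  pos <- sweep(pos, 2, cfg$d_offset, `+`)
  out <- data.frame(frame_id = sync$frame_id,
                    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  attr(out, "extrapolated") <- sum(sync$interval >= n)
  out
}

#' Convert one frame's polar beams to 3D points
#'
#' Under the scan-plane convention (vertical plane perpendicular to the
#' travel direction, angle 90 degrees at nadir) a beam `(theta, r)` maps
#' to an offset `r cos(theta)` along the cross-track axis and
#' `-r sin(theta)` vertically from the frame position.  No-hit sentinel
#' beams (range at or beyond `max_range`) and non-finite ranges are
#' skipped.
#'
#' @param frame data frame `angle_deg, range_m` for one frame.
#' @param position length-3 frame position.
#' @param cfg a [sensor_config()].
#' @param travel 2D unit travel direction (default `c(1, 0)`); the
#'   cross-track axis is its 90 degree left rotation.
#' @return data frame `x, y, z, beam_order, range` of valid points.
#' @export
frame_to_points <- function(frame, position, cfg = sensor_config(),
                            travel = c(1, 0)) {
  th <- frame$angle_deg * pi / 180
  r <- frame$range_m
  keep <- is.finite(r) & r >= 0 & r < cfg$max_range - 1e-9
  l <- c(-travel[2], travel[1])
  data.frame(
    x = position[1] + r[keep] * cos(th[keep]) * l[1],
    y = position[2] + r[keep] * cos(th[keep]) * l[2],
    z = position[3] - r[keep] * sin(th[keep]),
    beam_order = which(keep),
    range = r[keep])
}

#' Reconstruct a georeferenced point cloud from the two raw streams
#'
#' Runs [synchronize()], [frame_positions()] and the polar-to-Cartesian
#' mapping over all frames, using each frame's local travel direction
#' (from its interval's GPS step) to orient the scan plane.
#'
#' @param gps data frame `t, x, y, z`.
#' @param frames long data frame `t, frame_id, angle_deg, range_m` with
#'   beams of each frame in scan order.
#' @param cfg a [sensor_config()].
#' @param apply_enclosure_filter drop points whose beam range falls
#'   outside `cfg$enclosure_range_bounds` (default `TRUE`).
#' @return a `point_cloud` data frame with columns `x, y, z, frame_index,
#'   beam_order, range` and attributes `dropped_frames`, `extrapolated`,
#'   `filtered` (enclosure-filtered point count), `n_valid_beams`.
#' @export
reconstruct_cloud <- function(gps, frames, cfg = sensor_config(),
                              apply_enclosure_filter = TRUE) {
  sync <- synchronize(gps, frames, cfg)
  pos <- frame_positions(gps, sync, cfg)
  n <- nrow(gps)
  P <- as.matrix(gps[, c("x", "y", "z")])
  if (n >= 2) {
    step2 <- (P[-1, 1:2, drop = FALSE] - P[-n, 1:2, drop = FALSE])
    step2 <- rbind(step2, step2[n - 1, ])
  } else {
    step2 <- matrix(c(1, 0), 1, 2)
  }
  # per-interval travel direction; stationary intervals fall back to +x
  nrm <- sqrt(rowSums(step2^2))
  trav <- step2 / ifelse(nrm > 1e-12, nrm, 1)
  trav[nrm <= 1e-12, 1] <- 1
  trav[nrm <= 1e-12, 2] <- 0

  fr <- frames[frames$frame_id %in% sync$frame_id, ]
  fr <- fr[order(match(fr$frame_id, sync$frame_id)), ]
  nb <- tabulate(match(fr$frame_id, sync$frame_id), nbins = nrow(sync))
  rowi <- rep(seq_len(nrow(sync)), nb)
  iv <- pmin(sync$interval, n)[rowi]
  th <- fr$angle_deg * pi / 180
  r <- fr$range_m
  beam_order <- sequence(nb)
  keep <- is.finite(r) & r >= 0 & r < cfg$max_range - 1e-9
  lx <- -trav[iv, 2]; ly <- trav[iv, 1]
  cloud <- data.frame(
    x = pos$x[rowi] + r * cos(th) * lx,
    y = pos$y[rowi] + r * cos(th) * ly,
    z = pos$z[rowi] - r * sin(th),
    frame_index = sync$frame_id[rowi],
    beam_order = beam_order,
    range = r)[keep, ]
  rownames(cloud) <- NULL
  n_valid <- nrow(cloud)
  filtered <- 0L
  if (apply_enclosure_filter) {
    cloud <- enclosure_filter(cloud, cfg$enclosure_range_bounds)
    filtered <- attr(cloud, "filtered")
  }
  structure(as_point_cloud(cloud),
            dropped_frames = attr(sync, "dropped"),
            extrapolated = attr(pos, "extrapolated"),
            n_valid_beams = n_valid,
            filtered = filtered)
}

#' Enclosure distance filter
#'
#' Removes points whose originating beam range lies outside the accepted
#' interval; wall returns of a scanning enclosure fall outside it by
#' construction.
#'
#' @param cloud a point cloud with a `range` column.
#' @param bounds length-2 accepted range interval (m).
#' @return the filtered cloud with attribute `filtered` (removed count).
#' @export
enclosure_filter <- function(cloud, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  keep <- cloud$range >= bounds[1] & cloud$range <= bounds[2]
  out <- cloud[keep, ]
  rownames(out) <- NULL
  attr(out, "filtered") <- sum(!keep)
  as_point_cloud(out)
}

as_point_cloud <- function(df) {
  class(df) <- unique(c("point_cloud", class(df)))
  df
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points", nrow(x)))
  if (nrow(x))
    cat(sprintf(", x [%.2f, %.2f], z [%.2f, %.2f]",
                min(x$x), max(x$x), min(x$z), max(x$z)))
  cat(">\n")
  invisible(x)
}
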