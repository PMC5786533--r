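# Plot segmentation: crop row clouds into plots by the field layout,
# separate the ground plane by RANSAC, and remove detached weed clusters
# by Euclidean (single-linkage) clustering.

#' Field layout
#'
#' Defaults describe the reference trial: 16 rows x 8 columns, plots
#' 3.05 m wide (along travel), inter-row spacing 1.52 m and inter-column
#' spacing 1.83 m.
#'
#' @param n_rows,n_cols plot grid counts.
#' @param plot_width along-track plot extent (m).
#' @param inter_row row pitch (m).
#' @param inter_col gap between consecutive plots along the travel
#'   direction (m).
#' @param origin field corner (x, y) in the local frame (m).
#' @return an object of class `plot_layout`.
#' @export
plot_layout <- function(n_rows = 16, n_cols = 8, plot_width = 3.05,
                        inter_row = 1.52, inter_col = 1.83,
                        origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, plot_width > 0, inter_row > 0,
            inter_col > 0, length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 plot_width = plot_width, inter_row = inter_row,
                 inter_col = inter_col, origin = as.numeric(origin)),
            class = "plot_layout")
}

#' Crop one plot from a row cloud
#'
#' One row is scanned per pass, so cropping acts on the along-track axis
#' only: the closed interval `[start, start + plot_width]` of column
#' `col`, where `start = origin_x + col * (plot_width + inter_col)`.
#' A point on a shared edge stays with the lower-index plot (the next
#' plot starts after the inter-column gap).  Cross-track extent is
#' already bounded by the enclosure filter.
#'
#' @param row_cloud a `point_cloud` of one scanned row.
#' @param layout a [plot_layout()].
#' @param row,col 0-based plot indices.
#' @return the cropped cloud (frame/beam metadata preserved) with
#'   attributes `plot_bounds` (the along-track interval) and `plot_id`.
#'   An empty crop warns but is not an error.
#' @export
crop_plot <- function(row_cloud, layout, row = 0L, col = 0L) {
  stopifnot(inherits(layout, "plot_layout"))
  if (row < 0 || row >= layout$n_rows || col < 0 || col >= layout$n_cols)
    stop(sprintf("plot index (row %d, col %d) outside the %d x %d grid",
                 row, col, layout$n_rows, layout$n_cols), call. = FALSE)
  start <- layout$origin[1] + col * (layout$plot_width + layout$inter_col)
  keep <- row_cloud$x >= start & row_cloud$x <= start + layout$plot_width
  out <- row_cloud[keep, ]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning(sprintf("plot (row %d, col %d) crop is empty", row, col))
  structure(as_point_cloud(out),
            plot_bounds = c(start, start + layout$plot_width),
            plot_id = sprintf("r%02d_c%02d", row, col))
}

#' Fit the ground plane by RANSAC
#'
#' Repeated minimal (3-point) sampling with inlier counting at
#' `dist_threshold`, followed by a total-least-squares refinement on the
#' winning consensus set.  The returned normal is unit length and
#' oriented upward.
#'
#' @param cloud a point cloud (needs >= 3 non-collinear points).
#' @param dist_threshold inlier distance to the candidate plane (m).
#' @param n_iter number of sampling iterations.
#' @param seed RNG seed; identical seeds give identical masks.
#' @return list of class `ground_plane` with `normal` (a, b, c), `d`
#'   (plane `ax + by + cz + d = 0`), `inlier_count`, `dist_threshold`,
#'   and logical `inlier_mask`.
#' @export
fit_ground_ransac <- function(cloud, dist_threshold = 0.03, n_iter = 1000,
                              seed = 1L) {
  X <- as.matrix(cloud[, c("x", "y", "z")])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 points to fit a plane", call. = FALSE)
  best <- NULL
  best_in <- -1L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, 3)
      p <- X[idx, ]
      nv <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next          # collinear sample
      nv <- nv / nn
      d <- -sum(nv * p[1, ])
      cnt <- sum(abs(X %*% nv + d) <= dist_threshold)
      if (cnt > best_in) {
        best_in <- cnt
        best <- c(nv, d)
      }
    }
  })
  if (is.null(best))
    stop("degenerate input: no non-collinear 3-point sample found",
         call. = FALSE)
  mask <- abs(X %*% best[1:3] + best[4]) <= dist_threshold
  # total-least-squares refinement on the consensus set
  fit <- tls_plane(X[mask, , drop = FALSE])
  mask <- as.vector(abs(X %*% fit$normal + fit$d) <= dist_threshold)
  structure(list(normal = fit$normal, d = fit$d,
                 inlier_count = sum(mask), dist_threshold = dist_threshold,
                 inlier_mask = mask),
            class = "ground_plane")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthogonal-regression plane through a point set (upward unit normal)
tls_plane <- function(X) {
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0, nv = 3)
  nv <- sv$v[, 3]
  if (nv[3] < 0) nv <- -nv
  if (abs(nv[3]) < 1e-12 && (nv[1] < 0 || (nv[1] == 0 && nv[2] < 0)))
    nv <- -nv                      # deterministic sign for vertical planes
  list(normal = nv, d = -sum(nv * ctr))
}

#' @export
print.ground_plane <- function(x, ...) {
  cat(sprintf("<ground_plane: n=(%.4f, %.4f, %.4f), d=%.4f, %d inliers>\n",
              x$normal[1], x$normal[2], x$normal[3], x$d, x$inlier_count))
  invisible(x)
}

#' Split a cloud into ground and plant points
#'
#' Partitions by signed distance to the fitted plane: points within (or
#' below) `dist_threshold` of the plane are ground, the rest are plants.
#' Plant points gain a `height` column (perpendicular distance above the
#' plane); the partition is exhaustive and disjoint.
#'
#' @param cloud a point cloud.
#' @param plane a [fit_ground_ransac()] result.
#' @param dist_threshold ground band half-width (m); defaults to the
#'   plane's own threshold.
#' @return list with `plant` (cloud + `height`) and `ground` clouds.
#' @export
remove_ground <- function(cloud, plane, dist_threshold = plane$dist_threshold) {
  X <- as.matrix(cloud[, c("x", "y", "z")])
  h <- as.vector(X %*% plane$normal + plane$d)
  is_ground <- h <= dist_threshold
  plant <- cloud[!is_ground, ]
  plant$height <- h[!is_ground]
  rownames(plant) <- NULL
  ground <- cloud[is_ground, ]
  rownames(ground) <- NULL
  if (nrow(plant) == 0) warning("no points above the ground band")
  list(plant = as_point_cloud(plant), ground = as_point_cloud(ground))
}

#' Remove detached weed clusters
#'
#' Splits the plant cloud into single-linkage connected components under
#' an inter-point distance tolerance (a spatial grid keeps the search
#' near-linear; the output is identical to the naive all-pairs method).
#' The largest component is always kept; any other component is kept when
#' it holds at least `min_cluster_size` points *and* its footprint
#' centroid lies inside the plot's interior band (at least
#' `margin_frac * plot width` from either along-track edge).  Everything
#' else is treated as weeds and removed.
#'
#' @param plant_cloud a non-empty plant cloud.
#' @param tolerance inter-point connection distance (m).
#' @param min_cluster_size minimum retained component size (points).
#' @param plot_bounds along-track plot interval; defaults to the cloud's
#'   `plot_bounds` attribute, else its x-range.
#' @param margin_frac interior margin as a fraction of the plot width.
#' @return the retained cloud with attributes `removed` (point count),
#'   `n_components`, and `component` column labelling retained points.
#' @export
cluster_denoise <- function(plant_cloud, tolerance = 0.1,
                            min_cluster_size = 30, plot_bounds = NULL,
                            margin_frac = 0.1) {
  if (nrow(plant_cloud) == 0) stop("empty cloud", call. = FALSE)
  if (is.null(plot_bounds)) plot_bounds <- attr(plant_cloud, "plot_bounds")
  if (is.null(plot_bounds)) plot_bounds <- range(plant_cloud$x)
  lab <- cpp_euclidean_cluster(
    as.matrix(plant_cloud[, c("x", "y", "z")]), tolerance)
  sizes <- tabulate(lab)
  largest <- which.max(sizes)
  margin <- margin_frac * diff(plot_bounds)
  inner <- plot_bounds + c(margin, -margin)
  cx <- vapply(split(plant_cloud$x, lab), mean, numeric(1))
  central <- cx >= inner[1] & cx <= inner[2]
  keep_comp <- seq_along(sizes) == largest |
    (sizes >= min_cluster_size & central)
  keep <- keep_comp[lab]
  out <- plant_cloud[keep, ]
  out$component <- lab[keep]
  rownames(out) <- NULL
  structure(as_point_cloud(out),
            removed = sum(!keep), n_components = length(sizes),
            plot_bounds = plot_bounds,
            plot_id = attr(plant_cloud, "plot_id"))
}
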