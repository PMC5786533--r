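# Plot-level morphologic traits: canopy height percentiles, projected
# canopy area, and trapezoidal-rule plant volume.
#
# Volume follows the line-scan geometry: points are grouped into the
# scans they came from (frame_index), each scan's cross-track height
# profile is integrated by the trapezoidal rule into an area A_i, and
# the per-scan areas are integrated again along the travel direction.

#' Remove near-ground points before trait extraction
#'
#' @param cloud a plant cloud with a `height` column.
#' @param z_min minimum retained height above the ground plane (m);
#'   the default 0.05 m suppresses residual ground returns and litter.
#' @return the filtered cloud.
#' @export
height_filter <- function(cloud, z_min = 0.05) {
  stopifnot(!is.null(cloud$height))
  out <- cloud[cloud$height >= z_min, ]
  rownames(out) <- NULL
  structure(as_point_cloud(out), plot_bounds = attr(cloud, "plot_bounds"),
            plot_id = attr(cloud, "plot_id"))
}

#' Canopy height percentiles
#'
#' Heights above the fitted ground plane are summarised at the requested
#' percentiles using linear interpolation between order statistics
#' (`quantile` type 7); the 100th percentile is the maximum canopy
#' height (apex distance from the plane).
#'
#' @param cloud a non-empty plant cloud with a `height` column.
#' @param percentiles levels in (0, 100]; default 85 to 100 in steps
#'   of 3.
#' @return named numeric vector, `"p85"` etc., monotone in the level.
#' @export
canopy_height <- function(cloud, percentiles = c(85, 88, 91, 94, 97, 100)) {
  if (nrow(cloud) == 0) stop("empty cloud", call. = FALSE)
  stopifnot(!is.null(cloud$height), all(percentiles > 0 & percentiles <= 100))
  q <- quantile(cloud$height, probs = percentiles / 100, type = 7,
                names = FALSE)
  setNames(q, paste0("p", percentiles))
}

#' Projected canopy area and bounding box
#'
#' Points are projected onto the ground plane; the canopy boundary is
#' traced either as an alpha shape (concave hull; default, with alpha
#' five times the median nearest-neighbour spacing unless given) whose
#' ring areas are summed by the shoelace formula, or as the occupied
#' cells of a regular grid.  The bounding box is the axis-aligned extent
#' in the plot frame.
#'
#' @param cloud a cloud with >= 3 non-collinear points.
#' @param method `"alpha"` (concave boundary) or `"grid"`.
#' @param param alpha radius (m) for `"alpha"`, cell size (m) for
#'   `"grid"`; `NULL` picks the default (grid cell 0.02 m).
#' @return list with `pca` (m^2), `bbox` (`length` along x, `width`
#'   along y), `boundary` (for the alpha method, a list of closed ring
#'   matrices) and `method`.
#' @export
projected_area <- function(cloud, method = c("alpha", "grid"), param = NULL) {
  method <- match.arg(method)
  xy <- unique(cbind(cloud$x, cloud$y))
  if (nrow(xy) < 3) stop("need at least 3 distinct projected points",
                         call. = FALSE)
  if (collinear2(xy)) stop("projected points are collinear", call. = FALSE)
  bbox <- c(length = diff(range(xy[, 1])), width = diff(range(xy[, 2])))
  if (method == "grid") {
    cell <- if (is.null(param)) 0.02 else param
    ix <- floor(xy[, 1] / cell); iy <- floor(xy[, 2] / cell)
    pca <- length(unique(ix + 1i * iy)) * cell^2
    return(list(pca = pca, bbox = bbox, boundary = NULL, method = "grid"))
  }
  alpha <- if (is.null(param)) 5 * median_nn_spacing(xy) else param
  res <- alpha_shape_area(xy, alpha)
  if (is.na(res$area)) {
    warning("alpha-shape boundary assembly failed; falling back to grid")
    g <- projected_area(cloud, "grid")
    return(list(pca = g$pca, bbox = bbox, boundary = NULL, method = "grid"))
  }
  list(pca = res$area, bbox = bbox, boundary = res$rings, method = "alpha")
}

collinear2 <- function(xy) {
  v <- sweep(xy, 2, xy[1, ])
  cr <- abs(v[, 1] * v[2, 2] - v[, 2] * v[2, 1])
  all(cr < 1e-12 * max(1, max(abs(xy))))
}

# median nearest-neighbour distance, estimated on <= 500 sampled points
median_nn_spacing <- function(xy) {
  n <- nrow(xy)
  idx <- if (n > 500) round(seq(1, n, length.out = 500)) else seq_len(n)
  d <- vapply(idx, function(i) {
    dd <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    min(dd[-i])
  }, numeric(1))
  median(d)
}

# Alpha-shape area: detect boundary edges (Rcpp), assemble them into
# closed rings, then sum shoelace areas with even-odd hole handling.
# Dense interiors are thinned to one point per (alpha/4) cell first;
# interior points cannot carry boundary edges, so only edge jitter at
# sub-cell scale is affected.
alpha_shape_area <- function(xy, alpha) {
  extent <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  cell <- min(alpha / 4, extent / 64)
  if (cell > 0) {
    key <- floor(xy[, 1] / cell) + 1i * floor(xy[, 2] / cell)
    xy <- xy[!duplicated(key), , drop = FALSE]
  }
  ed <- cpp_alpha_edges(xy[, 1], xy[, 2], alpha)
  if (nrow(ed) < 3) return(list(area = NA_real_, rings = NULL))
  rings <- assemble_rings(ed)
  if (is.null(rings)) return(list(area = NA_real_, rings = NULL))
  polys <- lapply(rings, function(r) xy[r, , drop = FALSE])
  areas <- vapply(polys, shoelace, numeric(1))
  # even-odd nesting: a ring inside an odd number of other rings is a hole
  depth <- vapply(seq_along(polys), function(i) {
    p <- polys[[i]][1, ]
    sum(vapply(seq_along(polys), function(j) {
      j != i && point_in_poly(p[1], p[2], polys[[j]])
    }, logical(1)))
  }, numeric(1))
  area <- sum(abs(areas) * ifelse(depth %% 2 == 0, 1, -1))
  list(area = max(area, 0), rings = polys)
}

# walk boundary edges into closed vertex rings; NULL when a chain fails
# to close (non-manifold configuration)
assemble_rings <- function(edges) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  rings <- list()
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (!is.null(used[[ekey(a, b)]])) next
    used[[ekey(a, b)]] <- TRUE
    ring <- c(a, b)
    cur <- b; prev <- a
    repeat {
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      nxt <- nxt[vapply(nxt, function(v) is.null(used[[ekey(cur, v)]]),
                        logical(1))]
      if (length(nxt) == 0) {
        if (cur == a) break                # closed
        return(NULL)                       # open chain
      }
      v <- nxt[1]
      used[[ekey(cur, v)]] <- TRUE
      if (v == a) break
      ring <- c(ring, v)
      prev <- cur; cur <- v
    }
    if (length(ring) >= 3) rings[[length(rings) + 1]] <- ring
  }
  if (length(rings) == 0) NULL else rings
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

point_in_poly <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  crosses <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crosses) %% 2 == 1
}

#' Area under one scan's height profile (trapezoidal rule)
#'
#' For a scan with samples `(y_j, z_j)` ordered by the cross-track
#' coordinate, `A = sum_j (y_{j+1} - y_j) (z_{j+1} + z_j) / 2`.  The rule
#' is exact for piecewise-linear profiles sampled at their knots.
#'
#' @param y cross-track coordinates (m), sorted ascending.
#' @param z heights (m), same length.
#' @return area (m^2); scans with fewer than 2 samples return 0.
#' @export
scan_area <- function(y, z) {
  stopifnot(length(y) == length(z))
  n <- length(y)
  if (n < 2) return(0)
  if (is.unsorted(y)) stop("scan samples must be sorted by y", call. = FALSE)
  sum(diff(y) * (z[-1] + z[-n]) / 2)
}

#' Plant volume from per-scan areas (trapezoidal rule)
#'
#' `PV = sum_i (l_{i+1} - l_i) (A_{i+1} + A_i) / 2` over scans ordered by
#' their along-track position `l`.
#'
#' @param l along-track scan positions (m), sorted ascending.
#' @param A per-scan profile areas (m^2).
#' @return volume (m^3); fewer than 2 scans return 0 with a warning.
#' @export
plant_volume <- function(l, A) {
  stopifnot(length(l) == length(A))
  n <- length(l)
  if (n < 2) {
    warning("fewer than 2 scans; volume undefined, returning 0")
    return(0)
  }
  if (is.unsorted(l)) stop("scans must be sorted by l", call. = FALSE)
  sum(diff(l) * (A[-1] + A[-n]) / 2)
}

#' Rebuild per-scan height profiles from a plot cloud
#'
#' Points are grouped by `frame_index`; each scan's along-track position
#' is the mean x of its points, and samples are ordered by `beam_order`
#' (falling back to a y-sort for imported clouds without beam order).
#'
#' @param cloud a plant cloud with `height` and `frame_index` columns.
#' @return list of scans, each a list `l`, `y`, `z`, `A`.
#' @export
scan_profiles <- function(cloud) {
  stopifnot(!is.null(cloud$height), !is.null(cloud$frame_index))
  parts <- split(seq_len(nrow(cloud)), cloud$frame_index)
  scans <- lapply(parts, function(ii) {
    o <- if (!is.null(cloud$beam_order)) order(cloud$beam_order[ii])
         else order(cloud$y[ii])
    y <- cloud$y[ii][o]; z <- cloud$height[ii][o]
    if (is.unsorted(y)) { o2 <- order(y); y <- y[o2]; z <- z[o2] }
    list(l = mean(cloud$x[ii]), y = y, z = z, A = scan_area(y, z))
  })
  scans[order(vapply(scans, `[[`, numeric(1), "l"))]
}

#' Extract all morphologic traits of one plot
#'
#' Applies the height filter, then computes canopy height percentiles,
#' projected canopy area with bounding box, and trapezoidal-rule plant
#' volume from the per-scan profiles.
#'
#' @param plot_cloud a denoised plant cloud with `height` and
#'   `frame_index` columns (e.g. from [cluster_denoise()]).
#' @param plot_id plot identifier; defaults to the cloud's attribute.
#' @param date observation date label (optional).
#' @param dap days after planting (optional).
#' @param z_min height filter threshold (m).
#' @param percentiles canopy height percentile levels.
#' @param pca_method,pca_param passed to [projected_area()].
#' @return one-row data frame (a trait record): `plot_id, date, dap,
#'   n_points, ch_p85 ... ch_p100, max_ch, pca, bbox_length, bbox_width,
#'   pv`.  An empty (post-filter) plot yields `n_points = 0` and `NA`
#'   traits.
#' @export
extract_traits <- function(plot_cloud, plot_id = NULL, date = NA, dap = NA,
                           z_min = 0.05,
                           percentiles = c(85, 88, 91, 94, 97, 100),
                           pca_method = "alpha", pca_param = NULL) {
  if (is.null(plot_id))
    plot_id <- attr(plot_cloud, "plot_id") %||% "plot"
  cl <- height_filter(plot_cloud, z_min)
  ch_names <- paste0("ch_p", percentiles)
  base <- data.frame(plot_id = plot_id, date = date, dap = dap,
                     n_points = nrow(cl))
  if (nrow(cl) == 0) {
    empty <- as.data.frame(as.list(setNames(rep(NA_real_, length(ch_names) + 5),
      c(ch_names, "max_ch", "pca", "bbox_length", "bbox_width", "pv"))))
    return(cbind(base, empty))
  }
  ch <- canopy_height(cl, percentiles)
  pa <- projected_area(cl, pca_method, pca_param)
  scans <- scan_profiles(cl)
  pv <- if (length(scans) >= 2) {
    plant_volume(vapply(scans, `[[`, numeric(1), "l"),
                 vapply(scans, `[[`, numeric(1), "A"))
  } else 0
  rec <- cbind(base, as.data.frame(as.list(setNames(ch, ch_names))),
               data.frame(max_ch = max(cl$height), pca = pa$pca,
                          bbox_length = unname(pa$bbox["length"]),
                          bbox_width = unname(pa$bbox["width"]), pv = pv))
  rownames(rec) <- NULL
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
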