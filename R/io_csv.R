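# CSV interchange formats.  Dialect is pinned: comma separator, '.'
# decimal, LF line endings, UTF-8, numbers at 9 significant digits.

fmt_num <- function(x) trimws(formatC(x, digits = 9, format = "g"))

#' Read / write a GPS fix stream
#'
#' Columns `t, x, y, z` (seconds and metres); timestamps must be
#' strictly increasing.
#'
#' @param path file path.
#' @param gps data frame `t, x, y, z`.
#' @return `read_gps_csv`: the fix data frame (possibly empty).
#' @export
read_gps_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = "numeric"))
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(sprintf("GPS CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  df <- df[, need]
  if (nrow(df) > 1) {
    bad <- which(diff(df$t) <= 0)
    if (length(bad))
      stop(sprintf("GPS timestamps not strictly increasing at row %d",
                   bad[1] + 1), call. = FALSE)
  }
  df
}

#' @rdname read_gps_csv
#' @export
write_gps_csv <- function(gps, path) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(gps)))
  dt <- data.table::as.data.table(lapply(gps[, c("t", "x", "y", "z")], fmt_num))
  data.table::fwrite(dt, path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read / write a LiDAR frame stream (long format)
#'
#' Columns `t, frame_id, angle_deg, range_m`, one row per beam; beams of
#' a frame appear in scan order.  Negative ranges are rejected;
#' inconsistent beam counts across frames are tolerated (and reported
#' via the `beam_counts` attribute).
#'
#' @param path file path.
#' @param frames long data frame `t, frame_id, angle_deg, range_m`.
#' @return `read_frames_csv`: the frame data frame ordered by
#'   `frame_id`.
#' @export
read_frames_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("t", "frame_id", "angle_deg", "range_m")
  if (!all(need %in% names(df)))
    stop(sprintf("frame CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  df <- df[, need]
  if (nrow(df) && any(!is.finite(df$range_m) | df$range_m < 0))
    stop("negative or non-finite beam range", call. = FALSE)
  df <- df[order(df$frame_id), ]
  rownames(df) <- NULL
  attr(df, "beam_counts") <- table(df$frame_id)
  df
}

#' @rdname read_frames_csv
#' @export
write_frames_csv <- function(frames, path) {
  need <- c("t", "frame_id", "angle_deg", "range_m")
  stopifnot(all(need %in% names(frames)))
  dt <- data.table::data.table(
    t = fmt_num(frames$t), frame_id = frames$frame_id,
    angle_deg = fmt_num(frames$angle_deg), range_m = fmt_num(frames$range_m))
  data.table::fwrite(dt, path, quote = FALSE, eol = "\n")
  invisible(path)
}

# canonical cloud CSV column order; optional columns appended when present
cloud_cols <- function(cloud) {
  fixed <- c("x", "y", "z", "frame_index", "beam_order")
  opt <- intersect(c("range", "height", "component"), names(cloud))
  c(intersect(fixed, names(cloud)), opt)
}

#' Read / write a point cloud as CSV
#'
#' Fixed column order `x, y, z, frame_index, beam_order`, with optional
#' `range`, `height`, `component` columns appended when present.
#'
#' @param path file path.
#' @param cloud a `point_cloud` data frame.
#' @return `read_cloud_csv`: the cloud.
#' @export
read_cloud_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("cloud CSV must have x, y, z columns", call. = FALSE)
  for (col in c("frame_index", "beam_order", "component"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  as_point_cloud(df)
}

#' @rdname read_cloud_csv
#' @export
write_cloud_csv <- function(cloud, path) {
  cols <- cloud_cols(cloud)
  dt <- data.table::as.data.table(lapply(setNames(cols, cols), function(cn) {
    v <- cloud[[cn]]
    if (cn %in% c("frame_index", "beam_order", "component")) v else fmt_num(v)
  }))
  data.table::fwrite(dt, path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read / write a trait table as CSV
#'
#' The interchange format between the trait-extraction and
#' growth-analysis stages: one row per plot per date, columns as
#' produced by [extract_traits()] (plus optional `cultivar`).
#'
#' @param path file path.
#' @param traits trait table.
#' @return `read_traits_csv`: the table.
#' @export
read_traits_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' @rdname read_traits_csv
#' @export
write_traits_csv <- function(traits, path) {
  data.table::fwrite(data.table::as.data.table(traits), path,
                     quote = FALSE, eol = "\n")
  invisible(path)
}
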