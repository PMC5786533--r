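# PLY and PCD point-cloud files with the pipeline's per-vertex
# metadata (frame_index, beam_order, and optional range / height /
# component channels) carried as extra vertex properties.
#
# PLY: binary_little_endian 1.0 by default, ascii on request; x/y/z and
# float channels stored as float64 so round-trips are lossless.
# PCD:  version 0.7, same channels, ascii or binary.

cloud_channels <- function(cloud) {
  chans <- list(x = "double", y = "double", z = "double")
  for (cn in c("frame_index", "beam_order", "component"))
    if (cn %in% names(cloud)) chans[[cn]] <- "int"
  for (cn in c("range", "height"))
    if (cn %in% names(cloud)) chans[[cn]] <- "double"
  chans
}

#' Write a point cloud to PLY, PCD or CSV
#'
#' @param cloud a `point_cloud` data frame (columns `x, y, z` plus
#'   optional `frame_index, beam_order, range, height, component`).
#' @param path output file.
#' @param format `"ply"`, `"pcd"` or `"csv"`; default from the file
#'   extension.
#' @param binary write binary little-endian payload (default `TRUE` for
#'   PLY/PCD; ignored for CSV).
#' @return the path, invisibly.
#' @export
write_cloud <- function(cloud, path,
                        format = tools::file_ext(path), binary = TRUE) {
  format <- tolower(format)
  switch(format,
    ply = write_ply(cloud, path, binary),
    pcd = write_pcd(cloud, path, binary),
    csv = write_cloud_csv(cloud, path),
    stop(sprintf("unknown cloud format '%s'", format), call. = FALSE))
  invisible(path)
}

#' Read a point cloud written by [write_cloud()]
#'
#' @param path input file.
#' @param format `"ply"`, `"pcd"` or `"csv"`; default from the file
#'   extension.
#' @return a `point_cloud` data frame.
#' @export
read_cloud <- function(path, format = tools::file_ext(path)) {
  format <- tolower(format)
  switch(format,
    ply = read_ply(path),
    pcd = read_pcd(path),
    csv = read_cloud_csv(path),
    stop(sprintf("unknown cloud format '%s'", format), call. = FALSE))
}

ply_type <- c(double = "double", int = "int")

write_ply <- function(cloud, path, binary = TRUE) {
  chans <- cloud_channels(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment canopyscan point cloud",
           sprintf("element vertex %d", nrow(cloud)),
           sprintf("property %s %s", unlist(ply_type[unlist(chans)]),
                   names(chans)),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (nrow(cloud) == 0) return(invisible(path))
  if (binary) {
    # interleave channels row-wise
    raws <- lapply(names(chans), function(cn) {
      v <- cloud[[cn]]
      if (chans[[cn]] == "int")
        writeBin(as.integer(v), raw(), size = 4, endian = "little")
      else writeBin(as.double(v), raw(), size = 8, endian = "little")
    })
    widths <- vapply(chans, function(ty) if (ty == "int") 4L else 8L,
                     integer(1))
    n <- nrow(cloud)
    row_raw <- raw(sum(widths) * n)
    off <- 0L
    starts <- cumsum(c(0L, widths[-length(widths)]))
    for (k in seq_along(raws)) {
      w <- widths[k]
      src <- matrix(raws[[k]], nrow = w)
      idx <- rep((seq_len(n) - 1L) * sum(widths) + starts[k], each = w) +
        seq_len(w)
      row_raw[idx] <- as.vector(src)
    }
    writeBin(row_raw, con)
  } else {
    cols <- lapply(names(chans), function(cn) {
      v <- cloud[[cn]]
      if (chans[[cn]] == "int") trimws(format(as.integer(v), scientific = FALSE))
      else trimws(formatC(v, digits = 17, format = "g"))
    })
    writeChar(paste0(paste(do.call(paste, cols), collapse = "\n"), "\n"),
              con, eos = NULL)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated PLY header", call. = FALSE)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format (\\S+).*", "\\1", grep("^format ", hdr, value = TRUE))
  nv <- as.integer(sub("^element vertex (\\d+).*", "\\1",
                       grep("^element vertex", hdr, value = TRUE)))
  props <- grep("^property ", hdr, value = TRUE)
  ptype <- sub("^property (\\S+) .*", "\\1", props)
  pname <- sub("^property \\S+ (\\S+)$", "\\1", props)
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(txt)]
    df <- if (nv == 0) {
      as.data.frame(setNames(rep(list(numeric()), length(pname)), pname))
    } else {
      vals <- do.call(rbind, strsplit(trimws(txt[seq_len(nv)]), "\\s+"))
      as.data.frame(setNames(lapply(seq_along(pname), function(k) {
        v <- as.numeric(vals[, k])
        if (ptype[k] == "int") as.integer(v) else v
      }), pname))
    }
  } else if (fmt == "binary_little_endian") {
    widths <- ifelse(ptype == "int", 4L, 8L)
    rowbytes <- sum(widths)
    payload <- readBin(con, raw(), n = nv * rowbytes)
    starts <- cumsum(c(0L, widths[-length(widths)]))
    df <- as.data.frame(setNames(lapply(seq_along(pname), function(k) {
      if (nv == 0)
        return(if (ptype[k] == "int") integer() else numeric())
      idx <- rep((seq_len(nv) - 1L) * rowbytes + starts[k], each = widths[k]) +
        seq_len(widths[k])
      bytes <- payload[idx]
      if (ptype[k] == "int")
        readBin(bytes, integer(), n = nv, size = 4, endian = "little")
      else readBin(bytes, double(), n = nv, size = 8, endian = "little")
    }), pname))
  } else stop(sprintf("unsupported PLY format '%s'", fmt), call. = FALSE)
  as_point_cloud(df)
}

write_pcd <- function(cloud, path, binary = TRUE) {
  chans <- cloud_channels(cloud)
  nm <- names(chans)
  size <- vapply(chans, function(ty) if (ty == "int") 4L else 8L, integer(1))
  type <- vapply(chans, function(ty) if (ty == "int") "I" else "F",
                 character(1))
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(nm, collapse = " ")),
           paste("SIZE", paste(size, collapse = " ")),
           paste("TYPE", paste(type, collapse = " ")),
           paste("COUNT", paste(rep(1L, length(nm)), collapse = " ")),
           sprintf("WIDTH %d", nrow(cloud)),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", nrow(cloud)),
           sprintf("DATA %s", if (binary) "binary" else "ascii"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (nrow(cloud) == 0) return(invisible(path))
  if (binary) {
    n <- nrow(cloud)
    rowbytes <- sum(size)
    starts <- cumsum(c(0L, size[-length(size)]))
    out <- raw(rowbytes * n)
    for (k in seq_along(nm)) {
      v <- cloud[[nm[k]]]
      bytes <- if (chans[[nm[k]]] == "int")
        writeBin(as.integer(v), raw(), size = 4, endian = "little")
      else writeBin(as.double(v), raw(), size = 8, endian = "little")
      idx <- rep((seq_len(n) - 1L) * rowbytes + starts[k], each = size[k]) +
        seq_len(size[k])
      out[idx] <- bytes
    }
    writeBin(out, con)
  } else {
    cols <- lapply(nm, function(cn) {
      v <- cloud[[cn]]
      if (chans[[cn]] == "int") trimws(format(as.integer(v), scientific = FALSE))
      else trimws(formatC(v, digits = 17, format = "g"))
    })
    writeChar(paste0(paste(do.call(paste, cols), collapse = "\n"), "\n"),
              con, eos = NULL)
  }
  invisible(path)
}

read_pcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated PCD header", call. = FALSE)
    hdr <- c(hdr, line)
    if (grepl("^DATA ", line)) break
  }
  get <- function(key) strsplit(sub(paste0("^", key, " "), "",
                                    grep(paste0("^", key, " "), hdr,
                                         value = TRUE)), " ")[[1]]
  nm <- get("FIELDS")
  size <- as.integer(get("SIZE"))
  type <- get("TYPE")
  np <- as.integer(get("POINTS"))
  mode <- get("DATA")
  if (mode == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(txt)]
    df <- if (np == 0) {
      as.data.frame(setNames(rep(list(numeric()), length(nm)), nm))
    } else {
      vals <- do.call(rbind, strsplit(trimws(txt[seq_len(np)]), "\\s+"))
      as.data.frame(setNames(lapply(seq_along(nm), function(k) {
        v <- as.numeric(vals[, k])
        if (type[k] == "I") as.integer(v) else v
      }), nm))
    }
  } else if (mode == "binary") {
    rowbytes <- sum(size)
    payload <- readBin(con, raw(), n = np * rowbytes)
    starts <- cumsum(c(0L, size[-length(size)]))
    df <- as.data.frame(setNames(lapply(seq_along(nm), function(k) {
      if (np == 0) return(if (type[k] == "I") integer() else numeric())
      idx <- rep((seq_len(np) - 1L) * rowbytes + starts[k],
                 each = size[k]) + seq_len(size[k])
      bytes <- payload[idx]
      if (type[k] == "I")
        readBin(bytes, integer(), n = np, size = size[k], endian = "little")
      else readBin(bytes, double(), n = np, size = size[k], endian = "little")
    }), nm))
  } else stop(sprintf("unsupported PCD data mode '%s'", mode), call. = FALSE)
  as_point_cloud(df)
}
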