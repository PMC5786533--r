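# Run configuration: a single YAML file drives every pipeline stage so a
# run is reproducible from config alone.

#' Default run configuration
#'
#' Returns the fully populated configuration list; [read_config()]
#' merges a user YAML file over these defaults.  Sections:
#' `seed`; `scene` (ground_z, shapes, weeds, enclosure_halfwidth);
#' `pass` (speed, f_gps, f_lidar, aperture_deg, resolution_deg,
#' sensor_height, range_noise_sd, max_range, path);
#' `sensor` (d_offset, enclosure_range_bounds, clock_offset);
#' `layout` (n_rows, n_cols, plot_width, inter_row, inter_col, origin);
#' `segmentation` (ransac: dist_threshold, n_iter; cluster: tolerance,
#' min_size, margin_frac);
#' `traits` (z_min, percentiles, pca_method);
#' `growth` (T, truncate_at_max).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    scene = list(
      ground_z = 0,
      enclosure_halfwidth = NULL,
      shapes = list(list(kind = "hemisphere", center = c(2, 0),
                         dims = list(r = 1))),
      weeds = list()),
    pass = list(speed = 0.5, f_gps = 5, f_lidar = 50, aperture_deg = 190,
                resolution_deg = 1 / 3, sensor_height = 2.4,
                range_noise_sd = 0.005, max_range = 80,
                path = list(from = c(0, 0), to = c(4, 0))),
    sensor = list(d_offset = c(0, 0, 0),
                  enclosure_range_bounds = c(0, 79), clock_offset = 0),
    layout = list(n_rows = 1, n_cols = 1, plot_width = 3.05,
                  inter_row = 1.52, inter_col = 1.83, origin = c(0, 0)),
    segmentation = list(ransac = list(dist_threshold = 0.03, n_iter = 1000),
                        cluster = list(tolerance = 0.1, min_size = 30,
                                       margin_frac = 0.1)),
    traits = list(z_min = 0.05,
                  percentiles = c(85, 88, 91, 94, 97, 100),
                  pca_method = "alpha"),
    growth = list(T = 45, truncate_at_max = FALSE))
}

#' Read and validate a run configuration
#'
#' @param path YAML file; missing keys fall back to [default_config()].
#' @param overrides named list merged over the file (deepest wins).
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file '%s' not found", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- deep_merge(cfg, user)
  }
  cfg <- deep_merge(cfg, overrides)
  validate_config(cfg)
  cfg
}

deep_merge <- function(base, over) {
  if (!is.list(over)) return(over)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
                      !is.null(names(over[[nm]])))
      deep_merge(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop(paste("config:", msg),
                                             call. = FALSE)
  chk(is.numeric(cfg$seed), "seed must be numeric")
  p <- cfg$pass
  chk(p$speed > 0, "pass.speed must be positive")
  a <- p$f_lidar / p$f_gps
  chk(abs(a - round(a)) < 1e-9, "pass.f_lidar must be a multiple of f_gps")
  nb <- p$aperture_deg / p$resolution_deg
  chk(abs(nb - round(nb)) < 1e-6,
      "pass.aperture_deg / resolution_deg must be an integer")
  chk(p$sensor_height > 0, "pass.sensor_height must be positive")
  chk(p$range_noise_sd >= 0, "pass.range_noise_sd must be >= 0")
  chk(length(p$path$from) == 2 && length(p$path$to) == 2,
      "pass.path needs 2D from/to")
  s <- cfg$sensor
  chk(length(s$d_offset) == 3, "sensor.d_offset must be length 3")
  chk(length(s$enclosure_range_bounds) == 2 &&
        s$enclosure_range_bounds[1] < s$enclosure_range_bounds[2],
      "sensor.enclosure_range_bounds must be an increasing pair")
  l <- cfg$layout
  chk(all(c(l$n_rows, l$n_cols) >= 1) &&
        all(c(l$plot_width, l$inter_row, l$inter_col) > 0),
      "layout spacings must be positive")
  seg <- cfg$segmentation
  chk(seg$ransac$dist_threshold > 0 && seg$ransac$n_iter >= 1,
      "segmentation.ransac parameters invalid")
  chk(seg$cluster$tolerance > 0 && seg$cluster$min_size >= 1,
      "segmentation.cluster parameters invalid")
  tr <- cfg$traits
  chk(tr$z_min >= 0, "traits.z_min must be >= 0")
  chk(all(tr$percentiles > 0 & tr$percentiles <= 100),
      "traits.percentiles must lie in (0, 100]")
  chk(tr$pca_method %in% c("alpha", "grid"), "traits.pca_method unknown")
  invisible(cfg)
}

# config -> constructor helpers
scene_from_config <- function(cfg) {
  sc <- cfg$scene
  shapes <- lapply(sc$shapes, function(s)
    canopy_shape(s$kind, s$center[[1]], s$center[[2]], s$dims))
  weeds <- lapply(sc$weeds, function(w)
    list(center = as.numeric(unlist(w$center)), radius = w$radius,
         z = w$z))
  build_scene(shapes, ground_z = sc$ground_z %||% 0, weeds = weeds,
              enclosure_halfwidth = sc$enclosure_halfwidth)
}

pass_from_config <- function(cfg) {
  p <- cfg$pass
  pass_config(speed = p$speed, f_gps = p$f_gps, f_lidar = p$f_lidar,
              aperture_deg = p$aperture_deg,
              resolution_deg = p$resolution_deg,
              sensor_height = p$sensor_height,
              range_noise_sd = p$range_noise_sd, max_range = p$max_range,
              seed = cfg$seed)
}

sensor_from_config <- function(cfg) {
  sensor_config(f_gps = cfg$pass$f_gps, f_lidar = cfg$pass$f_lidar,
                sensor_height = cfg$pass$sensor_height,
                d_offset = as.numeric(unlist(cfg$sensor$d_offset)),
                enclosure_range_bounds =
                  as.numeric(unlist(cfg$sensor$enclosure_range_bounds)),
                max_range = cfg$pass$max_range,
                clock_offset = cfg$sensor$clock_offset %||% 0)
}

layout_from_config <- function(cfg) {
  l <- cfg$layout
  plot_layout(l$n_rows, l$n_cols, l$plot_width, l$inter_row, l$inter_col,
              as.numeric(unlist(l$origin)))
}
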