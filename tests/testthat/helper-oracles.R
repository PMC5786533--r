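# Shared fixtures and independent oracles used across the suite.

# --- brute-force oracles -------------------------------------------------

# naive all-pairs union-find connected components (single linkage)
brute_components <- function(pts, tol) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2) {
    d <- as.matrix(dist(pts))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# exhaustive best 3-point plane by inlier count (tiny instances only)
brute_best_plane_inliers <- function(X, thr) {
  n <- nrow(X)
  best <- 0L
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    nv <- c(
      (X[j, 2] - X[i, 2]) * (X[k, 3] - X[i, 3]) -
        (X[j, 3] - X[i, 3]) * (X[k, 2] - X[i, 2]),
      (X[j, 3] - X[i, 3]) * (X[k, 1] - X[i, 1]) -
        (X[j, 1] - X[i, 1]) * (X[k, 3] - X[i, 3]),
      (X[j, 1] - X[i, 1]) * (X[k, 2] - X[i, 2]) -
        (X[j, 2] - X[i, 2]) * (X[k, 1] - X[i, 1]))
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-12) next
    nv <- nv / nn
    d <- -sum(nv * X[i, ])
    best <- max(best, sum(abs(X %*% nv + d) <= thr))
  }
  best
}

# --- standard simulated scenes (cached: built once per test run) ---------

hemi_scene <- function() build_scene(
  list(canopy_shape("hemisphere", 2, 0, list(r = 1))))

.pipeline_cache <- new.env(parent = emptyenv())

# full pipeline over a scene; returns plant cloud + trait record
run_pipeline <- function(scene, cfg = pass_config(),
                         path = list(from = c(0, 0), to = c(4, 0)),
                         key = NULL, ransac_seed = 2) {
  if (!is.null(key) && !is.null(.pipeline_cache[[key]]))
    return(.pipeline_cache[[key]])
  sim <- simulate_pass(scene, cfg, path)
  cloud <- reconstruct_cloud(sim$gps, sim$frames, sensor_config())
  plane <- fit_ground_ransac(cloud, seed = ransac_seed)
  plant <- remove_ground(cloud, plane)$plant
  plant <- cluster_denoise(plant)
  res <- list(sim = sim, cloud = cloud, plane = plane, plant = plant,
              traits = extract_traits(plant, plot_id = "sim"))
  if (!is.null(key)) .pipeline_cache[[key]] <- res
  res
}

# distance of points to the nearest analytic surface of the hemisphere
# scene (ground plane z = 0 or dome x^2 + y^2 + z^2 = r^2 about center)
hemi_surface_dist <- function(cloud, cx = 2, cy = 0, r = 1) {
  d_ground <- abs(cloud$z)
  d_dome <- abs(sqrt((cloud$x - cx)^2 + (cloud$y - cy)^2 + cloud$z^2) - r)
  pmin(d_ground, d_dome)
}
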