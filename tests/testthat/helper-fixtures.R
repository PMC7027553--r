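# Builders used across test files.

# zero-length-safe id maker (paste0 recycles a scalar against length 0)
ids <- function(prefix, n) {
  if (n == 0L) character(0) else paste0(prefix, seq_len(n))
}

# Minimal valid study-table data.frame (sd columns populated).
make_table <- function(n = 3, seed = 1) {
  set.seed(seed)
  n <- as.integer(n)
  data.frame(
    study_id = ids("s", n),
    dataset_id = ids("d", n),
    response = rep("N mineralization", n),
    mean_w = rnorm(n, 12, 2), sd_w = runif(n, 0.5, 2),
    n_w = rep(5L, n),
    mean_c = rnorm(n, 10, 2), sd_c = runif(n, 0.5, 2),
    n_c = rep(5L, n),
    latitude_deg = runif(n, 55, 70), mat_c = runif(n, -8, 4),
    map_mm = runif(n, 300, 900), depth_cm = rep(5, n),
    delta_t = runif(n, 0.5, 3), duration_yr = runif(n, 1, 10),
    moisture_effect = rnorm(n, -5, 5),
    control_cluster = rep(NA_character_, n),
    stringsAsFactors = FALSE)
}

# Effect table built directly from (y, v, cluster, n) vectors, bypassing
# arm-level simulation; used to test the inference layer in isolation.
make_effects <- function(y, v, cluster = NULL, n_w = 5L, n_c = 5L,
                         response = "DON") {
  k <- length(y)
  if (is.null(cluster)) cluster <- ids("c", k)
  out <- data.frame(
    y = y, v = v, study_id = ids("s", k),
    dataset_id = ids("d", k),
    response = rep_len(response, k),
    n_w = rep_len(n_w, k), n_c = rep_len(n_c, k),
    control_cluster = cluster,
    depth_bin = rep("D5", k), latitude_band = rep("HIGH_N", k),
    biome = rep("TUNDRA", k),
    delta_t = rep(2, k), duration_yr = rep(5, k),
    moisture_effect = rep(-5, k),
    stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

# Closed-form inverse-variance weighted mean and SE (diagonal oracle).
ivw_oracle <- function(y, v) {
  w <- 1 / v
  c(est = sum(w * y) / sum(w), se = sqrt(1 / sum(w)))
}

# Explicit GLS oracle by direct matrix inversion (full-V oracle).
gls_oracle <- function(y, V) {
  Vi <- solve(V)
  one <- rep(1, length(y))
  b <- as.numeric(t(one) %*% Vi %*% one)
  c(est = as.numeric(t(one) %*% Vi %*% y) / b, se = sqrt(1 / b))
}
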