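#' Define a simulation scenario for synthetic study tables
#'
#' The generator emulates a compiled warming-experiment dataset: about a
#' hundred warmed-versus-control comparisons with small replicate numbers
#' (3-10 per arm), warming magnitudes of ca. 0-4 deg C, experiment lengths
#' from a few weeks up to 22 yr, sites spread over tundra, boreal,
#' temperate, and grassland climates mostly above 50 N, and occasional
#' reuse of one control group by several comparisons.
#'
#' @param k_studies Number of comparisons to generate.
#' @param responses Response-variable labels to sample from.
#' @param true_smd True standardized effect per (response, biome): either a
#'   single number applied everywhere, a named vector by response, or a
#'   named list `response -> c(TUNDRA = ..., ...)`. Missing entries
#'   default to 0.
#' @param moderator_slopes Named numeric vector of linear shifts of the
#'   true SMD per centered moderator unit, e.g.
#'   `c(delta_t = 0.3)`; moderators are centered at their range midpoints.
#' @param n_range Integer pair, per-arm replicate range (default 3-10).
#' @param delta_t_range Warming magnitude range, deg C (default 0-4).
#' @param duration_range Experiment length range, yr (default 0.05-22,
#'   drawn log-uniformly).
#' @param shared_control_prob Probability that a comparison reuses an
#'   existing control cluster from the same study (default 0.3).
#' @param moisture_cor Correlation between warming magnitude and the
#'   soil-moisture moderator (default -0.4: warming tends to dry soils).
#' @param sd_scale Multiplier on within-arm SDs (default 1; arm SDs are
#'   20-50% of the control mean before scaling).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(k_studies = 100,
                         responses = c("N mineralization", "DON",
                                       "root N", "fungal biomass"),
                         true_smd = 0,
                         moderator_slopes = c(delta_t = 0, duration_yr = 0,
                                              moisture_effect = 0),
                         n_range = c(3L, 10L),
                         delta_t_range = c(0, 4),
                         duration_range = c(0.05, 22),
                         shared_control_prob = 0.3,
                         moisture_cor = -0.4,
                         sd_scale = 1,
                         seed = 1L) {
  if (k_studies < 0) stop("k_studies must be >= 0", call. = FALSE)
  if (n_range[1] < 2 || n_range[2] < n_range[1]) {
    stop("n_range must be non-degenerate with at least 2 per arm",
         call. = FALSE)
  }
  if (diff(delta_t_range) <= 0 || diff(duration_range) <= 0) {
    stop("moderator ranges must be non-degenerate", call. = FALSE)
  }
  if (shared_control_prob < 0 || shared_control_prob > 1) {
    stop("shared_control_prob must be in [0, 1]", call. = FALSE)
  }
  if (sd_scale <= 0) stop("sd_scale must be positive", call. = FALSE)
  structure(list(
    k_studies = as.integer(k_studies), responses = responses,
    true_smd = true_smd, moderator_slopes = moderator_slopes,
    n_range = as.integer(n_range), delta_t_range = delta_t_range,
    duration_range = duration_range,
    shared_control_prob = shared_control_prob,
    moisture_cor = moisture_cor, sd_scale = sd_scale,
    seed = as.integer(seed)), class = "sim_scenario")
}

# size-safe single draw (sample() expands a scalar integer to 1:x)
.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1, prob = prob)]

.lookup_true_smd <- function(true_smd, response, biome) {
  if (is.list(true_smd)) {
    x <- true_smd[[response]]
    if (is.null(x)) return(0)
    if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
    v <- x[[biome]]
    return(if (is.null(v) || is.na(v)) 0 else as.numeric(v))
  }
  if (!is.null(names(true_smd))) {
    v <- true_smd[response]
    return(if (is.na(v)) 0 else as.numeric(v))
  }
  as.numeric(true_smd[1])
}

# site climate consistent with the default biome classifier
.draw_site <- function(biome) {
  switch(biome,
    TUNDRA = {
      mat <- stats::runif(1, -12, -5.5)
      map <- stats::runif(1, 120, 700)
      lat <- stats::runif(1, 55, 78)
    },
    BOREAL = {
      mat <- stats::runif(1, -4.5, 2.5)
      thr <- 350 + 30 * (mat + 5)
      map <- stats::runif(1, thr + 30, thr + 600)
      lat <- stats::runif(1, 48, 68)
    },
    TEMPERATE = {
      mat <- stats::runif(1, 3.2, 5)
      thr <- 350 + 30 * (mat + 5)
      map <- stats::runif(1, thr + 30, thr + 700)
      lat <- stats::runif(1, 38, 55)
    },
    GRASSLAND = {
      mat <- stats::runif(1, -4.5, 4.5)
      thr <- 350 + 30 * (mat + 5)
      map <- stats::runif(1, 60, thr - 30)
      lat <- stats::runif(1, 30, 48)
    })
  # a few high-southern-latitude sites for the latitude bands
  if (stats::runif(1) < 0.04) lat <- -stats::runif(1, 52, 75)
  c(mat = mat, map = map, lat = lat)
}

#' Generate a synthetic study table
#'
#' Draws, for each comparison, a biome-consistent site climate, per-arm
#' replicate numbers, moderators (warming magnitude, log-uniform duration,
#' moisture change correlated with warming), a true standardized effect
#' `delta = true_smd[response, biome] + sum(slopes * centered moderators)`,
#' and then arm summary statistics from their sampling distributions: arm
#' means are normal around the true means, arm SDs are scaled-chi
#' draws at the drawn n. With probability `shared_control_prob` a
#' comparison joins an existing control cluster of the same study, reusing
#' that cluster's control draw and site verbatim. The output always passes
#' [normalize_study_table()] validation.
#'
#' @param scenario A [sim_scenario()].
#' @return A labeled-ready `study_table`.
#' @export
generate_study_table <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  k <- scenario$k_studies
  cols <- c("study_id", "dataset_id", "response", "mean_w", "sd_w", "n_w",
            "mean_c", "sd_c", "n_c", "latitude_deg", "mat_c", "map_mm",
            "depth_cm", "delta_t", "duration_yr", "moisture_effect",
            "control_cluster")
  if (k == 0L) {
    df <- data.frame(study_id = character(0), dataset_id = character(0),
                     response = character(0), mean_w = numeric(0),
                     sd_w = numeric(0), n_w = integer(0),
                     mean_c = numeric(0), sd_c = numeric(0),
                     n_c = integer(0), latitude_deg = numeric(0),
                     mat_c = numeric(0), map_mm = numeric(0),
                     depth_cm = numeric(0), delta_t = numeric(0),
                     duration_yr = numeric(0), moisture_effect = numeric(0),
                     control_cluster = character(0),
                     stringsAsFactors = FALSE)
    return(normalize_study_table(df))
  }
  biome_pool <- c("TUNDRA", "BOREAL", "TEMPERATE", "GRASSLAND")
  dt_mid <- mean(scenario$delta_t_range)
  dur_mid <- exp(mean(log(scenario$duration_range)))
  rows <- vector("list", k)
  clusters <- list()  # open clusters: draws reusable as shared controls
  for (i in seq_len(k)) {
    response <- .sample1(scenario$responses)
    join <- length(clusters) > 0 &&
      stats::runif(1) < scenario$shared_control_prob
    if (join) {
      cl <- clusters[[sample.int(length(clusters), 1)]]
    } else {
      biome <- .sample1(biome_pool, prob = c(0.3, 0.25, 0.2, 0.25))
      site <- .draw_site(biome)
      dt <- stats::runif(1, scenario$delta_t_range[1],
                         scenario$delta_t_range[2])
      rho <- scenario$moisture_cor
      zdt <- (dt - dt_mid) / (diff(scenario$delta_t_range) / sqrt(12))
      moist <- -5 + 10 * (rho * zdt + sqrt(1 - rho^2) * stats::rnorm(1))
      dur <- exp(stats::runif(1, log(scenario$duration_range[1]),
                              log(scenario$duration_range[2])))
      n_c <- .sample1(scenario$n_range[1]:scenario$n_range[2])
      mu_c <- stats::rlnorm(1, meanlog = 2, sdlog = 0.8)
      sigma <- scenario$sd_scale * mu_c * stats::runif(1, 0.2, 0.5)
      xbar_c <- stats::rnorm(1, mu_c, sigma / sqrt(n_c))
      s_c <- sigma * sqrt(stats::rchisq(1, n_c - 1) / (n_c - 1))
      cl <- list(id = sprintf("cl%04d", i), study = sprintf("study%03d", i),
                 biome = biome, site = site, dt = dt, moist = moist,
                 dur = dur, n_c = n_c, mu_c = mu_c, sigma = sigma,
                 xbar_c = xbar_c, s_c = s_c,
                 depth = .sample1(c(5, 10, 15, 20, NA),
                                  prob = c(0.3, 0.3, 0.15, 0.15, 0.1)))
      clusters[[length(clusters) + 1L]] <- cl
    }
    delta <- .lookup_true_smd(scenario$true_smd, response, cl$biome) +
      sum(scenario$moderator_slopes[c("delta_t", "duration_yr",
                                      "moisture_effect")] *
            c(cl$dt - dt_mid, cl$dur - dur_mid, cl$moist - (-5)),
          na.rm = TRUE)
    n_w <- .sample1(scenario$n_range[1]:scenario$n_range[2])
    mu_w <- cl$mu_c + delta * cl$sigma
    xbar_w <- stats::rnorm(1, mu_w, cl$sigma / sqrt(n_w))
    s_w <- cl$sigma * sqrt(stats::rchisq(1, n_w - 1) / (n_w - 1))
    rows[[i]] <- data.frame(
      study_id = cl$study, dataset_id = sprintf("ds%04d", i),
      response = response, mean_w = xbar_w, sd_w = s_w, n_w = n_w,
      mean_c = cl$xbar_c, sd_c = cl$s_c, n_c = cl$n_c,
      latitude_deg = unname(cl$site["lat"]), mat_c = unname(cl$site["mat"]),
      map_mm = unname(cl$site["map"]), depth_cm = cl$depth,
      delta_t = cl$dt, duration_yr = cl$dur, moisture_effect = cl$moist,
      control_cluster = cl$id, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)[, cols]
  normalize_study_table(df)
}

#' Printed arm summaries from worked examples in the source studies
#'
#' Small fixture of control/warmed arm values as printed in the underlying
#' field studies (gross N mineralization and DON from a Siberian tundra
#' warming experiment; root N concentration, root biomass, and root N
#' content from a Qinghai-Tibetan alpine meadow; fungal biomass from a
#' subarctic tundra heath). The printed dispersion symbol (mean +/- x) is
#' stored agnostically as `disp_*`; whether it is an SD or an SE, and the
#' arm n (not printed), are for the caller to supply when deriving effect
#' sizes.
#'
#' @param name One of `biasi_nmin`, `biasi_don`, `chang_rootconc`,
#'   `chang_rootbiomass`, `chang_rootN`, `rousk_fungal`; omit for the full
#'   table.
#' @return A one-row `data.frame` (`name`, `mean_c`, `disp_c`, `mean_w`,
#'   `disp_w`, `units`), or all rows when `name` is missing.
#' @export
make_worked_example <- function(name) {
  path <- system.file("extdata", "worked_examples.csv",
                      package = "coldmeta", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (missing(name)) return(tab)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown worked example '%s'; known: %s", name,
                 paste(tab$name, collapse = ", ")), call. = FALSE)
  }
  rownames(row) <- NULL
  row
}
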