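#' Run the full meta-analysis pipeline
#'
#' Reads (or accepts) a study table, attaches stratum labels, computes
#' effect sizes and the shared-control covariance, pools each response
#' overall and by depth, latitude band, and biome, meta-regresses each
#' response on the available moderators, and writes flat CSV outputs plus
#' a JSON run manifest (input hash, config snapshot, seed, version,
#' per-stage row counts). Deterministic given inputs, config, and seed.
#'
#' @param studies A CSV path or a `study_table` data frame.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for every bootstrap in the run.
#' @param B Bootstrap iterations (default 10000).
#' @param min_k Study-count threshold for subgroup testing (strict >).
#' @param exceptions Responses always subgroup-tested.
#' @param biome_config Biome boundary configuration.
#' @param vcov_formula Shared-control covariance convention
#'   (see [build_vcov()]).
#' @param moderators Moderators for the per-response meta-regression.
#' @param interactions Include pairwise moderator interactions.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `fits`, `subgroups`, `metareg`,
#'   `effects`, `rejects`, and `manifest`; files written to `outdir`:
#'   effects.csv, vcov.csv, fits.csv, metareg.csv, rejects.csv,
#'   manifest.json.
#' @export
run_pipeline <- function(studies, outdir, seed, B = 10000, min_k = 10,
                         exceptions = c("N fixation", "N2O emission"),
                         biome_config = default_biome_config(),
                         vcov_formula = "average_total",
                         moderators = c("delta_t", "duration_yr",
                                        "moisture_effect"),
                         interactions = TRUE, quiet = FALSE) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  input_hash <- NA_character_
  if (is.character(studies)) {
    input_hash <- unname(tools::md5sum(studies))
    say("reading %s", studies)
    studies <- read_study_table(studies)
  } else {
    studies <- normalize_study_table(as.data.frame(studies))
  }
  n_read <- nrow(studies)
  labeled <- label_records(studies, biome_config)
  effects <- compute_effects(labeled)
  rej <- rejects(effects)
  say("effects: %d computed, %d rejected", nrow(effects), nrow(rej))
  V <- build_vcov(effects, formula = vcov_formula)

  fits <- list(); metareg_rows <- list()
  for (resp in unique(effects$response)) {
    i <- which(effects$response == resp)
    sub <- effects[i, , drop = FALSE]
    Vi <- unclass(V)[i, i, drop = FALSE]
    fit <- fit_fixed_effect(sub, Vi, B = B, seed = seed, response = resp)
    fits[[length(fits) + 1L]] <- data.frame(
      response = resp, factor = "overall", level = "overall", k = fit$k,
      estimate = fit$estimate, se = fit$se, ci_low = fit$ci_low,
      ci_high = fit$ci_high, ci_method = fit$ci_method,
      significant = if (is.na(fit$significant)) NA else fit$significant,
      stringsAsFactors = FALSE)
    mods <- moderators[vapply(moderators, function(m)
      sum(stats::complete.cases(sub[[m]])) > 0, logical(1))]
    p_design <- 1 + length(mods) +
      if (interactions && length(mods) >= 2) choose(length(mods), 2) else 0
    if (length(mods) && fit$k > p_design) {
      mr <- tryCatch(
        meta_regress(sub, Vi, moderators = mods,
                     interactions = interactions),
        error = function(e) NULL)
      if (!is.null(mr)) {
        metareg_rows[[length(metareg_rows) + 1L]] <- data.frame(
          response = resp, term = mr$terms, beta = mr$beta, se = mr$se,
          z = mr$z, p = mr$p, flag = marginal_flags(mr), k = mr$k,
          n_dropped = mr$n_dropped, stringsAsFactors = FALSE)
      }
    }
  }
  fits_df <- do.call(rbind, fits)
  sub_df <- do.call(rbind, lapply(
    c("depth_bin", "latitude_band", "biome"),
    function(f) suppressMessages(
      subgroup_analysis(effects, V, factor = f, min_k = min_k,
                        exceptions = exceptions, B = B, seed = seed))))
  all_fits <- rbind(fits_df, sub_df)
  metareg_df <- if (length(metareg_rows)) do.call(rbind, metareg_rows) else
    data.frame(response = character(0), term = character(0),
               beta = numeric(0), se = numeric(0), z = numeric(0),
               p = numeric(0), flag = character(0), k = integer(0),
               n_dropped = integer(0), stringsAsFactors = FALSE)

  utils::write.csv(as.data.frame(effects),
                   file.path(outdir, "effects.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(V)),
                   file.path(outdir, "vcov.csv"), row.names = FALSE)
  utils::write.csv(all_fits, file.path(outdir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(metareg_df, file.path(outdir, "metareg.csv"),
                   row.names = FALSE)
  utils::write.csv(rej, file.path(outdir, "rejects.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "coldmeta",
    version = as.character(utils::packageVersion("coldmeta")),
    input_md5 = input_hash,
    seed = seed, B = B, min_k = min_k, exceptions = exceptions,
    vcov_formula = vcov_formula,
    biome_config = unclass(biome_config),
    moderators = moderators, interactions = interactions,
    counts = list(read = n_read, analyzed = nrow(effects),
                  rejected = nrow(rej)),
    outputs = c("effects.csv", "vcov.csv", "fits.csv", "metareg.csv",
                "rejects.csv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %d fit rows, %d meta-regression rows to %s",
      nrow(all_fits), nrow(metareg_df), outdir)
  invisible(list(fits = all_fits, metareg = metareg_df, effects = effects,
                 rejects = rej, V = V, manifest = manifest))
}
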