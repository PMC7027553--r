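#' @keywords internal
"_PACKAGE"

.required_cols <- c("study_id", "dataset_id", "response",
                    "mean_w", "n_w", "mean_c", "n_c",
                    "latitude_deg", "mat_c", "map_mm")
.numeric_cols <- c("mean_w", "sd_w", "se_w", "n_w",
                   "mean_c", "sd_c", "se_c", "n_c",
                   "latitude_deg", "mat_c", "map_mm", "depth_cm",
                   "delta_t", "duration_yr", "moisture_effect")
.optional_cols <- c("sd_w", "se_w", "sd_c", "se_c", "depth_cm",
                    "delta_t", "duration_yr", "moisture_effect",
                    "control_cluster")

#' Read a study-level summary table
#'
#' Reads a CSV with one row per warmed-versus-control comparison: arm means,
#' dispersions (SD or SE), sample sizes, site metadata (latitude, MAT, MAP,
#' soil depth), moderators (warming magnitude `delta_t` in deg C, experiment
#' `duration_yr`, `moisture_effect`), and a `control_cluster` id shared by
#' rows that reuse one control group. Empty cells are missing; the decimal
#' separator is ".".
#'
#' @param path CSV file path.
#' @param normalize If `TRUE` (default), SE columns are converted to SDs via
#'   [se_to_sd()] and the table is validated with [normalize_study_table()].
#' @return A `data.frame` of class `study_table`.
#' @export
read_study_table <- function(path, normalize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(.required_cols, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in .optional_cols) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  }
  for (col in .numeric_cols) {
    x <- df[[col]]
    if (is.character(x)) {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                     col, bad[1], x[bad[1]]), call. = FALSE)
      }
      df[[col]] <- conv
    } else {
      df[[col]] <- as.numeric(x)
    }
  }
  df$control_cluster <- as.character(df$control_cluster)
  if (normalize) df <- normalize_study_table(df)
  class(df) <- c("study_table", "data.frame")
  df
}

#' Validate and normalize a study table
#'
#' Enforces the schema contract: exactly one of (sd, se) per arm before
#' normalization (SE is converted to SD as `se * sqrt(n)`); positive
#' integer arm sizes with `n_w + n_c >= 3`; unique
#' (`dataset_id`, `response`, `depth_cm`) keys; and identical control-arm
#' summaries within each `control_cluster`. Rows without a
#' `control_cluster` get a singleton cluster id.
#'
#' @param df A study-table `data.frame`.
#' @return The normalized `study_table`.
#' @export
normalize_study_table <- function(df) {
  n <- nrow(df)
  for (col in .optional_cols) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA, n)
  }
  if (n == 0L) {
    df$control_cluster <- character(0)
    df$se_w <- NULL; df$se_c <- NULL
    class(df) <- unique(c("study_table", class(df)))
    return(df)
  }
  for (arm in c("w", "c")) {
    sd_col <- paste0("sd_", arm); se_col <- paste0("se_", arm)
    n_col <- paste0("n_", arm)
    has_sd <- !is.na(df[[sd_col]]); has_se <- !is.na(df[[se_col]])
    both <- which(has_sd & has_se); neither <- which(!has_sd & !has_se)
    if (length(both)) {
      stop(sprintf("row %d: both %s and %s present (exactly one expected)",
                   both[1], sd_col, se_col), call. = FALSE)
    }
    if (length(neither)) {
      stop(sprintf("row %d: neither %s nor %s present",
                   neither[1], sd_col, se_col), call. = FALSE)
    }
    if (any(has_se)) {
      df[[sd_col]][has_se] <- se_to_sd(df[[se_col]][has_se],
                                       df[[n_col]][has_se])
    }
    if (any(df[[sd_col]] < 0)) {
      stop(sprintf("row %d: negative %s", which(df[[sd_col]] < 0)[1], sd_col),
           call. = FALSE)
    }
    bad_n <- which(is.na(df[[n_col]]) | df[[n_col]] < 1 |
                     df[[n_col]] != floor(df[[n_col]]))
    if (length(bad_n)) {
      stop(sprintf("row %d: %s must be an integer >= 1", bad_n[1], n_col),
           call. = FALSE)
    }
  }
  df$se_w <- NULL; df$se_c <- NULL
  key <- paste(df$dataset_id, df$response, df$depth_cm, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate (dataset_id, response, depth) key",
                 dup[1]), call. = FALSE)
  }
  cc <- as.character(df$control_cluster)
  solo <- is.na(cc)
  cc[solo] <- paste0("solo:", df$dataset_id[solo], ":", df$response[solo],
                     ":", seq_len(n)[solo])
  df$control_cluster <- cc
  for (cl in unique(cc)) {
    i <- which(cc == cl)
    if (length(i) > 1L) {
      same <- length(unique(df$mean_c[i])) == 1L &&
        length(unique(df$sd_c[i])) == 1L &&
        length(unique(df$n_c[i])) == 1L
      if (!same) {
        stop(sprintf(
          "control cluster '%s': rows do not share identical control arms",
          cl), call. = FALSE)
      }
    }
  }
  class(df) <- unique(c("study_table", class(df)))
  df
}

#' Write a study table to CSV
#'
#' The written file round-trips through [read_study_table()]: reading it
#' back reproduces the normalized records.
#'
#' @param records A `study_table`.
#' @param path Output CSV path.
#' @export
write_study_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
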