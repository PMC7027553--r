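#' Pooled standard deviation of two arms
#'
#' Degrees-of-freedom-weighted combination of the warmed and control arm
#' SDs: `sqrt(((n_w - 1) sd_w^2 + (n_c - 1) sd_c^2) / (n_w + n_c - 2))`.
#'
#' @param sd_w,sd_c Arm standard deviations, non-negative, not both zero.
#' @param n_w,n_c Arm sample sizes with `n_w + n_c >= 3`.
#' @return Pooled SD (positive).
#' @export
pooled_sd <- function(sd_w, n_w, sd_c, n_c) {
  if (any(sd_w < 0) || any(sd_c < 0)) {
    stop("arm SDs must be non-negative", call. = FALSE)
  }
  if (any(n_w + n_c < 3)) {
    stop("n_w + n_c must be at least 3 (pooled SD needs >= 1 df)",
         call. = FALSE)
  }
  if (any(sd_w == 0 & sd_c == 0)) {
    stop("both arm SDs are zero: effect size undefined", call. = FALSE)
  }
  sqrt(((n_w - 1) * sd_w^2 + (n_c - 1) * sd_c^2) / (n_w + n_c - 2))
}

#' Standardized mean difference
#'
#' `(mean_w - mean_c) / sp`, the warmed-minus-control mean difference in
#' pooled-SD units (Cohen's d; no small-sample correction by default, see
#' [compute_effects()]).
#'
#' @param mean_w,mean_c Arm means.
#' @param sp Pooled standard deviation, positive.
#' @return The SMD (unitless).
#' @export
smd <- function(mean_w, mean_c, sp) {
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("pooled SD must be positive and finite", call. = FALSE)
  }
  (mean_w - mean_c) / sp
}

#' Large-sample variance of a standardized mean difference
#'
#' `1/n_w + 1/n_c + y^2 / (2 (n_w + n_c))`, with the total sample size in
#' the curvature term.
#'
#' @param y The SMD.
#' @param n_w,n_c Arm sample sizes (>= 1).
#' @return Sampling variance (positive).
#' @export
smd_variance <- function(y, n_w, n_c) {
  if (any(n_w < 1) || any(n_c < 1)) {
    stop("arm sizes must be >= 1", call. = FALSE)
  }
  1 / n_w + 1 / n_c + y^2 / (2 * (n_w + n_c))
}

#' Percent change between control and warmed means
#'
#' `100 * (mean_w - mean_c) / mean_c`. Display rounding is left to the
#' caller; the return value is unrounded.
#'
#' @param mean_c Control mean, non-zero.
#' @param mean_w Warmed mean.
#' @return Percent change.
#' @examples
#' percent_change(0.23, 0.34)  # ~ +48
#' @export
percent_change <- function(mean_c, mean_w) {
  if (any(mean_c == 0)) {
    stop("percent change undefined for zero control mean", call. = FALSE)
  }
  100 * (mean_w - mean_c) / mean_c
}

#' Compute effect sizes from a labeled study table
#'
#' One SMD and sampling variance per record. Rows that violate a
#' precondition (too few degrees of freedom, both arm SDs zero) are not
#' fatal: they are skipped and collected in the `"rejects"` attribute with
#' the failure reason, because compiled study tables are heterogeneous.
#'
#' @param records A normalized (and usually labeled) `study_table`.
#' @param hedges If `TRUE`, apply the small-sample bias correction
#'   `J = 1 - 3 / (4 (n_w + n_c - 2) - 1)` to `y` before computing `v`.
#'   Off by default.
#' @return A `data.frame` of class `effect_table` with columns `y`, `v`,
#'   ids, labels, arm sizes, moderators, and `control_cluster`; rejected
#'   rows in `attr(, "rejects")`.
#' @export
compute_effects <- function(records, hedges = FALSE) {
  keep_cols <- intersect(
    c("study_id", "dataset_id", "response", "n_w", "n_c",
      "control_cluster", "depth_bin", "latitude_band", "biome",
      "delta_t", "duration_yr", "moisture_effect"),
    names(records))
  rejects <- data.frame(row = integer(0), dataset_id = character(0),
                        response = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  n <- nrow(records)
  if (n == 0L) {
    out <- cbind(data.frame(y = numeric(0), v = numeric(0)),
                 records[, keep_cols, drop = FALSE])
    attr(out, "rejects") <- rejects
    class(out) <- c("effect_table", "data.frame")
    return(out)
  }
  y <- v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sp <- pooled_sd(records$sd_w[i], records$n_w[i],
                      records$sd_c[i], records$n_c[i])
      yi <- smd(records$mean_w[i], records$mean_c[i], sp)
      if (hedges) {
        yi <- yi * (1 - 3 / (4 * (records$n_w[i] + records$n_c[i] - 2) - 1))
      }
      c(yi, smd_variance(yi, records$n_w[i], records$n_c[i]))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejects <- rbind(rejects, data.frame(
        row = i, dataset_id = records$dataset_id[i],
        response = records$response[i], reason = res,
        stringsAsFactors = FALSE))
    } else {
      y[i] <- res[1]; v[i] <- res[2]
    }
  }
  ok <- !is.na(v)
  out <- cbind(data.frame(y = y[ok], v = v[ok]),
               as.data.frame(records)[ok, keep_cols, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Rejected rows of an effect-size computation
#'
#' @param effects An `effect_table` from [compute_effects()].
#' @return The rejects `data.frame` (row, ids, reason).
#' @export
rejects <- function(effects) {
  r <- attr(effects, "rejects")
  if (is.null(r)) {
    r <- data.frame(row = integer(0), dataset_id = character(0),
                    response = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  }
  r
}

#' Shared-control variance-covariance matrix of effect sizes
#'
#' Effect sizes computed against the same control group are correlated.
#' The matrix has `v_i` on the diagonal and, for effects i != j within one
#' control cluster, `1/n_c + y_i y_j / (2 * ntilde)`, zero elsewhere. With
#' `formula = "average_total"` (default) `ntilde = n_c + (n_w_i + n_w_j)/2`,
#' the average total sample size of the two comparisons, matching the
#' total-n convention of [smd_variance()]; `"add_both"` uses
#' `ntilde = n_c + n_w_i + n_w_j`. If the result is numerically not
#' positive semi-definite, a diagonal jitter of at most 1e-10 is applied
#' and reported via `message()`.
#'
#' @param effects An `effect_table`.
#' @param formula Off-diagonal sample-size convention (see above).
#' @return A symmetric matrix of class `effect_vcov` with attributes
#'   `clusters` (the cluster id per row) and `jitter`.
#' @export
build_vcov <- function(effects, formula = c("average_total", "add_both")) {
  formula <- match.arg(formula)
  k <- nrow(effects)
  V <- diag(effects$v, nrow = k)
  cc <- effects$control_cluster
  for (cl in unique(cc)) {
    idx <- which(cc == cl)
    if (length(idx) < 2L) next
    if (length(unique(effects$n_c[idx])) != 1L) {
      stop(sprintf("control cluster '%s': inconsistent control arm sizes",
                   cl), call. = FALSE)
    }
    nc <- effects$n_c[idx[1]]
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ntilde <- if (formula == "average_total") {
          nc + (effects$n_w[i] + effects$n_w[j]) / 2
        } else {
          nc + effects$n_w[i] + effects$n_w[j]
        }
        V[i, j] <- V[j, i] <- 1 / nc +
          effects$y[i] * effects$y[j] / (2 * ntilde)
      }
    }
  }
  jitter <- 0
  if (k > 0L) {
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) {
      jitter <- min(1e-10, -min(ev) * (1 + 1e-6))
      diag(V) <- diag(V) + jitter
      message(sprintf("covariance matrix repaired with diagonal jitter %g",
                      jitter))
    }
  }
  dimnames(V) <- list(effects$dataset_id, effects$dataset_id)
  attr(V, "clusters") <- cc
  attr(V, "jitter") <- jitter
  class(V) <- c("effect_vcov", class(V))
  V
}
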