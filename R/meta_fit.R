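.as_vcov <- function(effects, V) {
  if (is.null(V)) V <- build_vcov(effects)
  V <- unclass(V)
  if (!is.matrix(V) || nrow(V) != nrow(effects) || ncol(V) != nrow(effects)) {
    stop("covariance matrix dimension does not match the effect set",
         call. = FALSE)
  }
  V
}

# 1'V^-1 y and 1'V^-1 1 via Cholesky; the GLS pooled mean is their ratio.
.gls_sums <- function(y, V, clusters = NULL) {
  R <- tryCatch(chol(V), error = function(e) {
    cl <- if (is.null(clusters)) "unknown" else
      paste(unique(clusters), collapse = ", ")
    stop(sprintf("singular covariance matrix (clusters: %s)", cl),
         call. = FALSE)
  })
  u <- backsolve(R, forwardsolve(t(R), y))
  w <- backsolve(R, forwardsolve(t(R), rep(1, length(y))))
  c(a = sum(u), b = sum(w))
}

#' Fixed-effect pooled estimate by generalized least squares
#'
#' Pools effect sizes under a common-true-effect model:
#' `estimate = (1' V^-1 y) / (1' V^-1 1)`, `se = sqrt(1 / (1' V^-1 1))`,
#' with z and two-sided normal p. With a diagonal `V` this is exactly the
#' inverse-variance weighted mean. The confidence-interval method follows
#' the study-count rule: no CI for a single effect, BCa bootstrap for
#' 1 < k < 15, Wald otherwise; `ci_method = "auto"` applies the rule,
#' or force one explicitly.
#'
#' @param effects An `effect_table` (columns `y`, `v`, `control_cluster`).
#' @param V Covariance matrix from [build_vcov()]; built from `effects`
#'   when `NULL`.
#' @param ci_method `"auto"`, `"wald"`, `"bca"`, or `"none"`.
#' @param level Confidence level (default 0.95).
#' @param B Bootstrap iterations for BCa (default 10000).
#' @param seed Integer seed, required whenever the BCa route is taken.
#' @param stratum,response Optional labels carried into the result.
#' @return A `meta_fit` list: `estimate`, `se`, `ci_low`, `ci_high`, `z`,
#'   `p`, `k`, `ci_method`, `significant`.
#' @export
fit_fixed_effect <- function(effects, V = NULL,
                             ci_method = c("auto", "wald", "bca", "none"),
                             level = 0.95, B = 10000, seed = NULL,
                             stratum = "overall", response = NA_character_) {
  ci_method <- match.arg(ci_method)
  k <- nrow(effects)
  if (k == 0L) stop("no effects to pool", call. = FALSE)
  V <- .as_vcov(effects, V)
  if (k == 1L) {
    est <- effects$y[1]; se <- sqrt(V[1, 1])
    fit <- list(estimate = est, se = se, ci_low = NA_real_,
                ci_high = NA_real_, z = est / se,
                p = 2 * stats::pnorm(-abs(est / se)), k = 1L,
                ci_method = "NONE", level = level, significant = NA,
                stratum = stratum, response = response)
    class(fit) <- "meta_fit"
    return(fit)
  }
  s <- .gls_sums(effects$y, V, effects$control_cluster)
  est <- s[["a"]] / s[["b"]]
  se <- sqrt(1 / s[["b"]])
  if (ci_method == "auto") ci_method <- if (k < 15) "bca" else "wald"
  if (ci_method == "bca") {
    ci <- bca_ci(effects, V, level = level, B = B, seed = seed)
    method <- "BCA"
  } else if (ci_method == "wald") {
    ci <- wald_ci(est, se, level)
    method <- "WALD"
  } else {
    ci <- c(NA_real_, NA_real_)
    method <- "NONE"
  }
  z <- est / se
  fit <- list(estimate = est, se = se, ci_low = ci[1], ci_high = ci[2],
              z = z, p = 2 * stats::pnorm(-abs(z)), k = k,
              ci_method = method, level = level,
              significant = if (method == "NONE") NA else
                (ci[1] > 0 || ci[2] < 0),
              stratum = stratum, response = response)
  class(fit) <- "meta_fit"
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis (k = %d%s%s)\n", x$k,
              if (!is.na(x$response)) paste0(", response: ", x$response)
              else "",
              if (!identical(x$stratum, "overall"))
                paste0(", stratum: ", x$stratum) else ""))
  cat(sprintf("  SMD = %.4f (SE %.4f), z = %.3f, p = %.4g\n",
              x$estimate, x$se, x$z, x$p))
  if (x$ci_method == "NONE") {
    cat("  CI: not available (single study)\n")
  } else {
    cat(sprintf("  %g%% CI [%s]: (%.4f, %.4f)%s\n", 100 * x$level,
                x$ci_method, x$ci_low, x$ci_high,
                if (isTRUE(x$significant)) " *" else ""))
  }
  invisible(x)
}

#' Wald confidence interval
#'
#' `estimate -/+ z_(1-(1-level)/2) * se`, symmetric about the estimate.
#'
#' @param estimate Point estimate.
#' @param se Standard error, positive.
#' @param level Confidence level in (0, 1).
#' @return `c(low, high)`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)",
                                     call. = FALSE)
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate - zq * se, estimate + zq * se)
}

#' BCa bootstrap confidence interval for the pooled effect
#'
#' Bias-corrected and accelerated percentile bootstrap of the fixed-effect
#' GLS estimate. The resampling unit is the shared-control cluster, drawn
#' with replacement, so the dependence encoded in the covariance matrix is
#' preserved; each drawn cluster carries its own covariance block, and the
#' block-diagonal GLS estimate decomposes into per-cluster sums, which is
#' how the resamples are computed (an exact reformulation, fully
#' vectorized). The bias correction z0 uses the strictly-below convention
#' with ties at the point estimate counted half; the acceleration `a` comes
#' from a leave-one-cluster-out jackknife.
#'
#' @param effects An `effect_table` with k >= 2 rows.
#' @param V Covariance matrix (built when `NULL`).
#' @param level Confidence level.
#' @param B Bootstrap iterations, >= 100.
#' @param seed Integer seed (required: every bootstrap run is logged
#'   against its seed).
#' @return `c(low, high)` with attributes `z0`, `accel`, `B`, `seed`.
#' @export
bca_ci <- function(effects, V = NULL, level = 0.95, B = 10000, seed) {
  k <- nrow(effects)
  if (k < 2L) stop("BCa bootstrap needs at least 2 effects", call. = FALSE)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the bootstrap", call. = FALSE)
  }
  V <- .as_vcov(effects, V)
  cc <- effects$control_cluster
  cl_ids <- unique(cc)
  m <- length(cl_ids)
  # per-cluster GLS sums: a_c = 1'Vc^-1 y_c, b_c = 1'Vc^-1 1
  ab <- vapply(cl_ids, function(cl) {
    i <- which(cc == cl)
    .gls_sums(effects$y[i], V[i, i, drop = FALSE], cc[i])
  }, numeric(2))
  a_c <- ab[1, ]; b_c <- ab[2, ]
  theta_hat <- sum(a_c) / sum(b_c)
  if (m < 2L) {
    warning("only one shared-control cluster: returning point interval")
    return(structure(c(theta_hat, theta_hat), z0 = 0, accel = 0,
                     B = B, seed = seed))
  }
  set.seed(seed)
  idx <- matrix(sample.int(m, m * B, replace = TRUE), nrow = B)
  num <- matrix(a_c[idx], nrow = B)
  den <- matrix(b_c[idx], nrow = B)
  theta_star <- rowSums(num) / rowSums(den)
  if (max(theta_star) - min(theta_star) < 1e-14) {
    warning("degenerate bootstrap distribution: returning point interval")
    return(structure(c(theta_hat, theta_hat), z0 = 0, accel = 0,
                     B = B, seed = seed))
  }
  p0 <- (sum(theta_star < theta_hat) +
           0.5 * sum(theta_star == theta_hat)) / B
  p0 <- min(max(p0, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(p0)
  # leave-one-cluster-out jackknife acceleration
  theta_jack <- (sum(a_c) - a_c) / (sum(b_c) - b_c)
  dj <- mean(theta_jack) - theta_jack
  denom <- sum(dj^2)^1.5
  accel <- if (denom > 0) sum(dj^3) / (6 * denom) else 0
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - accel * (z0 + zalpha)))
  # type 6 places the p-th endpoint at order-statistic index (B + 1) p,
  # the convention of the standard bootstrap implementations
  ci <- unname(stats::quantile(theta_star, probs = adj, type = 6))
  structure(ci, z0 = z0, accel = accel, B = B, seed = seed)
}

#' Significance under the CI-excludes-zero rule
#'
#' An effect is significant when its confidence interval does not overlap
#' zero. For a single-study fit (no CI) significance is not evaluable and
#' `NA` is returned with a message.
#'
#' @param fit A `meta_fit`.
#' @return `TRUE`, `FALSE`, or `NA` (not evaluable).
#' @export
significance <- function(fit) {
  if (fit$ci_method == "NONE") {
    message("single study: significance not evaluable")
    return(NA)
  }
  fit$ci_low > 0 || fit$ci_high < 0
}

#' Subgroup analysis by depth, latitude band, or biome
#'
#' Per the study-count rule, a response is tested across strata only when
#' it has more than `min_k` effects, unless it is on the exception list
#' (defaults: N fixation and N2O emission, which are always tested).
#' Each stratum level with at least one effect is pooled separately; the
#' CI method per level follows the k rule in [fit_fixed_effect()]. Effects
#' with an unknown or missing stratum label are excluded from that factor's
#' comparison only.
#'
#' @param effects A labeled `effect_table` (a single response, or several:
#'   each response is handled separately).
#' @param V Covariance matrix (built when `NULL`).
#' @param factor One of `"depth_bin"`, `"latitude_band"`, `"biome"`.
#' @param min_k Study-count threshold (strict: run when `k > min_k`).
#' @param exceptions Responses always tested regardless of k.
#' @param level,B,seed Passed to [fit_fixed_effect()].
#' @return A `data.frame`, one row per (response, level), with estimate,
#'   SE, CI, CI method, k, and significance; suppressed responses are
#'   reported via `message()` and the `"suppressed"` attribute.
#' @export
subgroup_analysis <- function(effects, V = NULL,
                              factor = c("depth_bin", "latitude_band",
                                         "biome"),
                              min_k = 10,
                              exceptions = c("N fixation", "N2O emission"),
                              level = 0.95, B = 10000, seed = NULL) {
  factor <- match.arg(factor)
  if (!factor %in% names(effects)) {
    stop(sprintf("effects are not labeled with '%s'", factor), call. = FALSE)
  }
  V <- .as_vcov(effects, V)
  out <- list()
  suppressed <- character(0)
  for (resp in unique(effects$response)) {
    ridx <- which(effects$response == resp)
    if (length(ridx) <= min_k && !(resp %in% exceptions)) {
      suppressed <- c(suppressed, resp)
      message(sprintf(
        "response '%s': k = %d <= %d and not on the exception list; %s",
        resp, length(ridx), min_k, "subgroup analysis suppressed"))
      next
    }
    lab <- effects[[factor]][ridx]
    keep <- !is.na(lab) & lab != "UNKNOWN"
    for (lev in unique(lab[keep])) {
      i <- ridx[keep][lab[keep] == lev]
      fit <- fit_fixed_effect(effects[i, , drop = FALSE],
                              V[i, i, drop = FALSE],
                              level = level, B = B, seed = seed,
                              stratum = lev, response = resp)
      out[[length(out) + 1L]] <- data.frame(
        response = resp, factor = factor, level = lev, k = fit$k,
        estimate = fit$estimate, se = fit$se,
        ci_low = fit$ci_low, ci_high = fit$ci_high,
        ci_method = fit$ci_method,
        significant = if (is.na(fit$significant)) NA else fit$significant,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(response = character(0), factor = character(0),
               level = character(0), k = integer(0), estimate = numeric(0),
               se = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               ci_method = character(0), significant = logical(0),
               stringsAsFactors = FALSE)
  attr(res, "suppressed") <- suppressed
  res
}
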