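#' Meta-regression of effect sizes on study-level moderators
#'
#' Regresses SMDs on warming magnitude (`delta_t`, deg C), experiment
#' duration (`duration_yr`), and soil-moisture change (`moisture_effect`)
#' under the effect covariance: `beta = (X' V^-1 X)^-1 X' V^-1 y` with
#' coefficient covariance `(X' V^-1 X)^-1`, normal z and two-sided p per
#' coefficient. Moderators are mean-centered (over the included rows)
#' before interaction products are formed, which reduces collinearity
#' without changing interaction z statistics. Rows missing any requested
#' moderator are dropped listwise and counted. An intercept-only call
#' (no moderators) reproduces [fit_fixed_effect()] exactly.
#'
#' @param effects An `effect_table` carrying moderator columns.
#' @param V Covariance matrix (built when `NULL`).
#' @param moderators Character subset of
#'   `c("delta_t", "duration_yr", "moisture_effect")` (any effect-table
#'   numeric column is accepted).
#' @param interactions If `TRUE`, add all pairwise products of the
#'   centered moderators.
#' @param center Mean-center moderators (default `TRUE`).
#' @return A `meta_regression_fit`: `terms`, `beta`, `se`, `z`, `p`, `k`,
#'   `n_dropped`, `vcov`, `design_note`.
#' @export
meta_regress <- function(effects, V = NULL,
                         moderators = c("delta_t", "duration_yr",
                                        "moisture_effect"),
                         interactions = FALSE, center = TRUE) {
  V <- .as_vcov(effects, V)
  bad <- setdiff(moderators, names(effects))
  if (length(bad)) {
    stop("unknown moderator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(as.data.frame(effects)[, moderators, drop = FALSE])
  keep <- if (length(moderators)) stats::complete.cases(M) else
    rep(TRUE, nrow(effects))
  n_dropped <- sum(!keep)
  y <- effects$y[keep]
  M <- M[keep, , drop = FALSE]
  V <- V[keep, keep, drop = FALSE]
  k <- length(y)
  if (center && ncol(M)) M <- scale(M, center = TRUE, scale = FALSE)
  X <- cbind(intercept = rep(1, k), M)
  terms <- c("intercept", moderators)
  if (interactions && length(moderators) >= 2) {
    pairs <- utils::combn(moderators, 2)
    for (j in seq_len(ncol(pairs))) {
      nm <- paste(pairs[1, j], pairs[2, j], sep = ":")
      X <- cbind(X, M[, pairs[1, j]] * M[, pairs[2, j]])
      terms <- c(terms, nm)
    }
  }
  colnames(X) <- terms
  p <- ncol(X)
  if (k <= p) {
    stop(sprintf("insufficient data: k = %d effects for %d coefficients",
                 k, p), call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    aliased <- terms[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  R <- tryCatch(chol(V), error = function(e)
    stop("singular covariance matrix in meta-regression", call. = FALSE))
  Xt <- backsolve(R, X, transpose = TRUE)   # R^-T X
  yt <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))
  covb <- solve(XtX)
  se <- sqrt(diag(covb))
  z <- as.vector(beta) / se
  fit <- list(terms = terms, beta = as.vector(beta), se = se, z = z,
              p = 2 * stats::pnorm(-abs(z)), k = k, n_dropped = n_dropped,
              vcov = covb,
              design_note = sprintf(
                "moderators: %s; interactions: %s; centered: %s; dropped %d",
                if (length(moderators)) paste(moderators, collapse = ", ")
                else "(intercept only)",
                interactions, center, n_dropped))
  class(fit) <- "meta_regression_fit"
  fit
}

#' @export
print.meta_regression_fit <- function(x, ...) {
  cat(sprintf("Meta-regression (k = %d, %d rows dropped for missing %s)\n",
              x$k, x$n_dropped, "moderators"))
  tab <- data.frame(term = x$terms, beta = x$beta, se = x$se, z = x$z,
                    p = signif(x$p, 4), flag = marginal_flags(x))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Label coefficients as significant, marginal, or ns
#'
#' `p < alpha` is significant; `alpha <= p < marginal` is marginal
#' (default band 0.05-0.10); otherwise ns.
#'
#' @param fit A `meta_regression_fit` (or anything with a `p` field).
#' @param alpha Significance threshold (default 0.05).
#' @param marginal Marginal threshold (default 0.10).
#' @return Character vector per term.
#' @export
marginal_flags <- function(fit, alpha = 0.05, marginal = 0.10) {
  p <- fit$p
  ifelse(p < alpha, "significant", ifelse(p < marginal, "marginal", "ns"))
}
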