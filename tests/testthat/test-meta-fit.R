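test_that("single-effect fit has no CI and non-evaluable significance", {
  eff <- make_effects(y = 0.7, v = 0.3)
  fit <- fit_fixed_effect(eff)
  expect_equal(fit$estimate, 0.7)
  expect_equal(fit$se, sqrt(0.3))
  expect_equal(fit$ci_method, "NONE")
  expect_true(is.na(fit$significant))
  expect_message(s <- significance(fit), "not evaluable")
  expect_true(is.na(s))
  expect_error(fit_fixed_effect(make_effects(numeric(0), numeric(0))),
               "no effects")
})

test_that("equal-variance diagonal fit is the plain mean", {
  eff <- make_effects(y = c(1, 2, 3), v = c(1, 1, 1))
  fit <- fit_fixed_effect(eff, ci_method = "wald")
  expect_equal(fit$estimate, 2)
  expect_equal(fit$se, 1 / sqrt(3))
})

test_that("diagonal fits equal the inverse-variance oracle to 1e-12", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:30, 1)
    eff <- make_effects(y = rnorm(k), v = runif(k, 0.05, 2))
    fit <- fit_fixed_effect(eff, ci_method = "wald")
    o <- ivw_oracle(eff$y, eff$v)
    expect_equal(fit$estimate, unname(o["est"]), tolerance = 1e-12)
    expect_equal(fit$se, unname(o["se"]), tolerance = 1e-12)
  }
})

test_that("full-covariance fits match an explicit GLS solve to 1e-10", {
  set.seed(32)
  for (i in 1:25) {
    k <- 5
    cl <- c("a", "a", "b", "c", "d")  # one shared-control pair
    eff <- make_effects(y = rnorm(k, 0.3), v = runif(k, 0.2, 1),
                        cluster = cl, n_w = sample(3:8, k, TRUE),
                        n_c = c(6L, 6L, 4L, 5L, 7L))
    V <- build_vcov(eff)
    fit <- fit_fixed_effect(eff, V, ci_method = "wald")
    o <- gls_oracle(eff$y, unclass(V))
    expect_equal(fit$estimate, unname(o["est"]), tolerance = 1e-10)
    expect_equal(fit$se, unname(o["se"]), tolerance = 1e-10)
  }
})

test_that("pooled estimate is invariant to ordering and halved-weight duplication", {
  set.seed(33)
  eff <- make_effects(y = rnorm(8), v = runif(8, 0.1, 1))
  fit <- fit_fixed_effect(eff, ci_method = "wald")
  perm <- sample(8)
  fit_p <- fit_fixed_effect(eff[perm, ], diag(eff$v[perm]),
                            ci_method = "wald")
  expect_equal(fit_p$estimate, fit$estimate, tolerance = 1e-12)
  dup <- rbind(eff, eff)
  dup$v <- dup$v * 2
  dup$control_cluster <- paste0("u", seq_len(nrow(dup)))
  fit_d <- fit_fixed_effect(dup, diag(dup$v), ci_method = "wald")
  expect_equal(fit_d$estimate, fit$estimate, tolerance = 1e-12)
  expect_equal(fit_d$se, fit$se, tolerance = 1e-12)
})

test_that("wald_ci is the symmetric normal interval", {
  expect_equal(wald_ci(0, 1), c(-1, 1) * qnorm(0.975), tolerance = 1e-5)
  expect_equal(wald_ci(2, 0.5), 2 + c(-1, 1) * qnorm(0.975) * 0.5,
               tolerance = 1e-10)
  ci <- wald_ci(0.3, 0.17, level = 0.9)
  expect_equal(diff(ci), 2 * qnorm(0.95) * 0.17)
  expect_equal(mean(ci), 0.3)
  expect_error(wald_ci(0, 1, level = 1), "level")
  expect_error(wald_ci(0, 0), "positive")
})

test_that("significance follows the CI-excludes-zero rule", {
  mk <- function(lo, hi) list(ci_low = lo, ci_high = hi, ci_method = "WALD")
  expect_true(significance(mk(0.1, 0.5)))
  expect_true(significance(mk(-0.571, -0.173)))
  expect_false(significance(mk(-0.2, 0.3)))
})

test_that("CI method selection follows the study-count rule", {
  set.seed(34)
  eff <- make_effects(y = rnorm(20, 0.4), v = runif(20, 0.2, 0.6))
  expect_equal(fit_fixed_effect(eff[1, ])$ci_method, "NONE")
  expect_equal(fit_fixed_effect(eff[1:14, ], seed = 1, B = 200)$ci_method,
               "BCA")
  expect_equal(fit_fixed_effect(eff[1:15, ])$ci_method, "WALD")
  # bootstrap requires an explicit seed
  expect_error(fit_fixed_effect(eff[1:5, ]), "seed")
})

test_that("BCa is deterministic for a fixed seed and degenerates gracefully", {
  set.seed(35)
  eff <- make_effects(y = rnorm(10, 0.5), v = runif(10, 0.2, 0.8))
  ci1 <- bca_ci(eff, B = 500, seed = 99)
  ci2 <- bca_ci(eff, B = 500, seed = 99)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  ci3 <- bca_ci(eff, B = 500, seed = 100)
  expect_false(identical(as.numeric(ci1), as.numeric(ci3)))

  same <- make_effects(y = rep(0.4, 6), v = rep(0.3, 6))
  expect_warning(ci <- bca_ci(same, B = 200, seed = 1), "degenerate")
  expect_equal(as.numeric(ci), c(0.4, 0.4))
  expect_error(bca_ci(eff[1, ], B = 200, seed = 1), "at least 2")
  expect_error(bca_ci(eff, B = 50, seed = 1), "B must be")
})

test_that("BCa endpoints agree with the boot-package oracle on i.i.d. effects", {
  skip_if_not_installed("boot")
  set.seed(36)
  eff <- make_effects(y = rnorm(25, 0.5, 0.6), v = runif(25, 0.2, 0.8))
  mine <- bca_ci(eff, B = 4000, seed = 7)
  stat <- function(d, i) sum(d$y[i] / d$v[i]) / sum(1 / d$v[i])
  bt <- boot::boot(as.data.frame(eff), stat, R = 4000)
  set.seed(8)
  oracle <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  width <- diff(oracle)
  expect_lt(abs(mine[1] - oracle[1]), 0.15 * width)
  expect_lt(abs(mine[2] - oracle[2]), 0.15 * width)
})

test_that("BCa and Wald intervals converge for large symmetric samples", {
  set.seed(37)
  eff <- make_effects(y = rnorm(50, 0.3, sqrt(0.3)), v = rep(0.3, 50))
  fit <- fit_fixed_effect(eff, ci_method = "wald")
  w <- c(fit$ci_low, fit$ci_high)
  b <- bca_ci(eff, B = 4000, seed = 5)
  expect_lt(max(abs(as.numeric(b) - w)), 0.10 * diff(w))
})

test_that("shared-control clusters are resampled jointly", {
  set.seed(38)
  cl <- rep(c("a", "b", "c", "d", "e"), each = 2)
  eff <- make_effects(y = rnorm(10, 0.5), v = runif(10, 0.3, 0.6),
                      cluster = cl, n_c = rep(5L, 10))
  V <- build_vcov(eff)
  ci <- bca_ci(eff, V, B = 500, seed = 42)
  expect_true(is.finite(ci[1]) && ci[1] < ci[2])
  # a lone cluster cannot be bootstrapped: point interval with warning
  solo <- make_effects(y = c(0.2, 0.6), v = c(0.3, 0.3),
                       cluster = c("a", "a"), n_c = 5L)
  expect_warning(ci2 <- bca_ci(solo, B = 200, seed = 1), "one shared-control")
  expect_equal(ci2[1], ci2[2])
})

test_that("subgroup analysis applies the k and exception rules", {
  set.seed(39)
  eff <- make_effects(y = rnorm(12, 0.4), v = runif(12, 0.2, 0.6),
                      response = "DON")
  eff$biome <- rep(c("TUNDRA", "BOREAL"), each = 6)
  sub <- subgroup_analysis(eff, factor = "biome", B = 300, seed = 2)
  expect_setequal(sub$level, c("TUNDRA", "BOREAL"))
  expect_true(all(sub$k == 6))
  expect_true(all(sub$ci_method == "BCA"))
  # per-level fit equals the overall fit restricted to that subset
  i <- which(eff$biome == "TUNDRA")
  direct <- fit_fixed_effect(eff[i, ], ci_method = "wald")
  expect_equal(sub$estimate[sub$level == "TUNDRA"], direct$estimate,
               tolerance = 1e-12)

  small <- eff[1:8, ]
  expect_message(
    none <- subgroup_analysis(small, factor = "biome", B = 300, seed = 2),
    "suppressed")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "suppressed"), "DON")

  small$response <- "N fixation"   # excepted: runs despite k = 8
  ex <- subgroup_analysis(small, factor = "biome", B = 300, seed = 2)
  expect_gt(nrow(ex), 0L)

  expect_error(subgroup_analysis(eff, factor = "nope"))
})

test_that("unknown stratum labels are excluded from that comparison only", {
  set.seed(40)
  eff <- make_effects(y = rnorm(12, 0.4), v = runif(12, 0.2, 0.6))
  eff$depth_bin <- c(rep("D5", 6), rep("D10", 4), "UNKNOWN", "UNKNOWN")
  sub <- subgroup_analysis(eff, factor = "depth_bin", B = 300, seed = 2)
  expect_setequal(sub$level, c("D5", "D10"))
  expect_equal(sum(sub$k), 10)
})
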