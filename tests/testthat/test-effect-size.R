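test_that("pooled_sd matches hand values and a brute-force oracle", {
  expect_equal(pooled_sd(2, 3, 4, 3), sqrt(10))
  # equal-SD identity for any arm sizes
  for (nm in list(c(3, 3), c(4, 9), c(10, 2))) {
    expect_equal(pooled_sd(1.7, nm[1], 1.7, nm[2]), 1.7)
  }
  # randomized inputs vs df-weighted pooled-variance oracle
  set.seed(11)
  for (i in 1:50) {
    sw <- runif(1, 0.1, 5); sc <- runif(1, 0.1, 5)
    nw <- sample(2:20, 1); nc <- sample(2:20, 1)
    pooled_var <- stats::weighted.mean(c(sw^2, sc^2), c(nw - 1, nc - 1))
    expect_equal(pooled_sd(sw, nw, sc, nc), sqrt(pooled_var),
                 tolerance = 1e-12)
  }
  expect_error(pooled_sd(1, 1, 1, 1), "at least 3")
  expect_error(pooled_sd(0, 5, 0, 5), "both arm SDs are zero")
})

test_that("smd and smd_variance evaluate the defining formulas", {
  expect_equal(smd(5, 5, 2), 0)
  expect_equal(smd(2, 1, 1), 1)
  expect_error(smd(1, 0, 0), "positive")
  expect_equal(smd_variance(0, 5, 5), 0.4)
  expect_equal(smd_variance(1, 4, 4), 0.5625)
  expect_equal(smd_variance(-1, 4, 4), 0.5625)  # symmetric in y
  expect_error(smd_variance(1, 0, 4), ">= 1")
})

test_that("SMD is scale invariant and antisymmetric; v decreases in n", {
  set.seed(21)
  for (i in 1:25) {
    mw <- rnorm(1, 10); mc <- rnorm(1, 9)
    sw <- runif(1, 0.5, 3); sc <- runif(1, 0.5, 3)
    nw <- sample(3:12, 1); nc <- sample(3:12, 1)
    y <- smd(mw, mc, pooled_sd(sw, nw, sc, nc))
    expect_equal(sign(y), sign(mw - mc))
    c_ <- runif(1, 0.01, 100)  # unit change
    expect_equal(smd(c_ * mw, c_ * mc,
                     pooled_sd(c_ * sw, nw, c_ * sc, nc)), y,
                 tolerance = 1e-10)
    # swapping arms negates y, preserves v
    y2 <- smd(mc, mw, pooled_sd(sc, nc, sw, nw))
    expect_equal(y2, -y, tolerance = 1e-12)
    expect_equal(smd_variance(y2, nc, nw), smd_variance(y, nw, nc),
                 tolerance = 1e-12)
    expect_lt(smd_variance(y, nw + 1, nc), smd_variance(y, nw, nc))
    expect_lt(smd_variance(y, nw, nc + 1), smd_variance(y, nw, nc))
    expect_gte(smd_variance(y, nw, nc), 1 / nw + 1 / nc)
  }
})

test_that("percent_change reproduces the printed worked values", {
  expect_equal(round(percent_change(0.23, 0.34)), 48)
  expect_equal(round(percent_change(2.1, 4.9)), 133)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 1), "zero control mean")
})

test_that("compute_effects matches the single-record chain and logs rejects", {
  expect_equal(nrow(compute_effects(normalize_study_table(make_table(0)))),
               0L)
  tab <- normalize_study_table(make_table(6, seed = 3))
  tab$sd_w[2] <- 0; tab$sd_c[2] <- 0              # zero-variance reject
  tab$n_w[5] <- 1L; tab$n_c[5] <- 1L              # df reject
  eff <- compute_effects(tab)
  expect_equal(nrow(eff), 4L)
  rej <- rejects(eff)
  expect_equal(sort(rej$row), c(2L, 5L))
  expect_match(rej$reason[rej$row == 2], "zero")
  expect_match(rej$reason[rej$row == 5], "at least 3")
  for (i in seq_len(nrow(eff))) {
    j <- match(eff$dataset_id[i], tab$dataset_id)
    sp <- pooled_sd(tab$sd_w[j], tab$n_w[j], tab$sd_c[j], tab$n_c[j])
    y <- (tab$mean_w[j] - tab$mean_c[j]) / sp
    expect_equal(eff$y[i], y, tolerance = 1e-12)
    expect_equal(eff$v[i], 1 / tab$n_w[j] + 1 / tab$n_c[j] +
                   y^2 / (2 * (tab$n_w[j] + tab$n_c[j])),
                 tolerance = 1e-12)
  }
})

test_that("hedges flag applies the small-sample correction factor", {
  tab <- normalize_study_table(make_table(3, seed = 5))
  d <- compute_effects(tab)
  g <- compute_effects(tab, hedges = TRUE)
  J <- 1 - 3 / (4 * (tab$n_w + tab$n_c - 2) - 1)
  expect_equal(g$y, d$y * J, tolerance = 1e-12)
})

test_that("build_vcov: diagonal for singleton clusters, shared-control off-diagonals", {
  eff <- make_effects(y = c(0.5, -0.2, 1.1), v = c(0.4, 0.5, 0.6))
  V <- build_vcov(eff)
  expect_equal(unclass(V), diag(eff$v), ignore_attr = TRUE)

  eff2 <- make_effects(y = c(0, 0), v = c(0.4, 0.4),
                       cluster = c("cl", "cl"), n_w = 5L, n_c = 5L)
  V2 <- build_vcov(eff2)
  expect_equal(V2[1, 2], 0.2)   # 1/n_c with vanishing product term

  # three effects, one shared pair: hand-enumerated elementwise oracle
  eff3 <- make_effects(y = c(0.8, -0.3, 0.4), v = c(0.41, 0.52, 0.63),
                       cluster = c("a", "a", "b"),
                       n_w = c(4L, 6L, 5L), n_c = c(7L, 7L, 5L))
  V3 <- build_vcov(eff3)
  ntilde <- 7 + (4 + 6) / 2
  expect_equal(V3[1, 2], 1 / 7 + 0.8 * (-0.3) / (2 * ntilde))
  expect_equal(V3[2, 1], V3[1, 2])
  expect_equal(V3[1, 3], 0); expect_equal(V3[2, 3], 0)
  expect_equal(diag(unclass(V3)), eff3$v, ignore_attr = TRUE)
  ev <- eigen(unclass(V3), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)

  # alternate sample-size convention
  V3b <- build_vcov(eff3, formula = "add_both")
  expect_equal(V3b[1, 2], 1 / 7 + 0.8 * (-0.3) / (2 * (7 + 4 + 6)))

  eff_bad <- make_effects(y = c(0.1, 0.2), v = c(0.4, 0.4),
                          cluster = c("cl", "cl"), n_c = c(5L, 6L))
  expect_error(build_vcov(eff_bad), "inconsistent control arm")
})
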