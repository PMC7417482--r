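test_that("group summaries use arithmetic mean and n-1 SD", {
  profile <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    key = "PA",
    mol_pct = c(10, 10, 10, 8, 10, 12))
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     treatment = rep(c("none", "DTT"), each = 3))
  gs <- group_summary(profile, meta, "treatment")
  expect_equal(gs$mean[gs$treatment == "none"], 10)
  expect_equal(gs$sd[gs$treatment == "none"], 0)
  expect_equal(gs$mean[gs$treatment == "DTT"], 10)
  expect_equal(gs$sd[gs$treatment == "DTT"], 2)
  expect_equal(gs$n, c(3, 3))

  # keys absent from a sample count as 0 mol%
  sparse <- profile[-4, ]
  sparse$key[1] <- "PC"
  gs2 <- group_summary(sparse, meta, "treatment")
  pa_none <- gs2[gs2$treatment == "none" & gs2$key == "PA", ]
  expect_equal(pa_none$mean, mean(c(0, 10, 10)))

  # n = 1 gives a missing SD
  gs3 <- group_summary(profile[1, ], meta[1, , drop = FALSE], "treatment")
  expect_true(is.na(gs3$sd))
})

test_that("difference propagation is root-sum-of-squares", {
  a <- tibble::tibble(key = "PA", mean = 10, sd = 1, n = 3)
  b <- tibble::tibble(key = "PA", mean = 8, sd = 1, n = 3)
  d <- diff_with_propagation(a, b)
  expect_equal(d$delta, 2)
  expect_equal(d$delta_sd, sqrt(2), tolerance = 1e-12)
  # antisymmetric delta, symmetric delta_sd
  d2 <- diff_with_propagation(b, a)
  expect_equal(d2$delta, -d$delta)
  expect_equal(d2$delta_sd, d$delta_sd)
  # identical groups: zero delta, sqrt(2) * SD
  d3 <- diff_with_propagation(a, a)
  expect_equal(d3$delta, 0)
  expect_equal(d3$delta_sd, sqrt(2) * 1)
})

test_that("the pooled t-test matches closed forms and stats::t.test", {
  # identical groups
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$tier, "ns")

  # +10 shift at pooled SD 1: t = 10 / sqrt(2/3), df 4
  r2 <- two_sample_t(c(11, 12, 13), c(1, 2, 3))
  expect_equal(r2$t, 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r2$df, 4)
  expect_true(r2$p < 0.001)
  expect_equal(r2$tier, "***")

  # agreement with stats::t.test on random fixtures, both flavors
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), mean = 0.5)
    mine <- two_sample_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    mw <- two_sample_t(a, b, var_equal = FALSE)
    rw <- stats::t.test(a, b)
    expect_equal(mw$t, unname(rw$statistic), tolerance = 1e-10)
    expect_equal(mw$p, rw$p.value, tolerance = 1e-10)
    expect_equal(mw$df, unname(rw$parameter), tolerance = 1e-10)
  }

  # degenerate zero-variance cases
  eq <- two_sample_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(eq$p, 1)
  ne <- two_sample_t(c(5, 5, 5), c(4, 4, 4))
  expect_equal(ne$p, 0)
  expect_true(ne$degenerate)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2 replicates")

  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("compare_groups assembles deltas, propagated SDs and tiers", {
  set.seed(8)
  profile <- tibble::tibble(
    sample_id = rep(paste0("S", 1:6), each = 2),
    key = rep(c("PA", "PC"), 6),
    mol_pct = c(rbind(c(2.0, 2.1, 1.9, 4.1, 3.9, 4.0),
                      c(20, 21, 19, 20.5, 19.5, 20))))
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     treatment = rep(c("none", "DTT"), each = 3))
  cmp <- compare_groups(profile, meta, "treatment", "DTT", "none")
  pa <- cmp[cmp$key == "PA", ]
  expect_equal(pa$delta, mean(c(4.1, 3.9, 4.0)) - mean(c(2.0, 2.1, 1.9)))
  expect_equal(pa$delta_sd,
               sqrt(sd(c(4.1, 3.9, 4.0))^2 + sd(c(2.0, 2.1, 1.9))^2))
  ref <- stats::t.test(c(4.1, 3.9, 4.0), c(2.0, 2.1, 1.9),
                       var.equal = TRUE)
  expect_equal(pa$p, ref$p.value, tolerance = 1e-10)
  expect_equal(pa$tier, significance_tier(ref$p.value))

  # optional BH correction adds a p_adj column consistent with p.adjust
  cmpb <- compare_groups(profile, meta, "treatment", "DTT", "none",
                         p_adjust = "BH")
  expect_equal(cmpb$p_adj, stats::p.adjust(cmpb$p, "BH"))
})

test_that("PCA separates groups, fixes signs, and accounts for variance", {
  # rank-1 case: two duplicated groups differing in one species
  m <- rbind(S1 = c(10, 90), S2 = c(10, 90), S3 = c(30, 70),
             S4 = c(30, 70))
  pc <- pca_species(m)
  expect_equal(pc$explained_variance[1], 1)
  expect_equal(sign(pc$scores$PC1[1]) == sign(pc$scores$PC1[2]), TRUE)
  expect_true(abs(pc$scores$PC1[1] - pc$scores$PC1[3]) > 1)

  set.seed(9)
  m2 <- matrix(rexp(60), nrow = 6,
               dimnames = list(paste0("S", 1:6), paste0("sp", 1:10)))
  pc2 <- pca_species(m2)
  # explained variance: non-increasing, sums to 1 over all components
  expect_true(all(diff(pc2$explained_variance) < 1e-12))
  expect_equal(sum(pc2$explained_variance), 1, tolerance = 1e-8)
  # sign convention: largest-|loading| positive
  for (j in seq_len(ncol(pc2$loadings))) {
    l <- pc2$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # permutation equivariance of scores
  perm <- c(3, 1, 6, 2, 5, 4)
  pc3 <- pca_species(m2[perm, ])
  expect_equal(pc3$scores$PC1[order(perm)], pc2$scores$PC1,
               tolerance = 1e-8)
  # scaled variant runs and drops nothing here
  expect_silent(pca_species(m2, "center_unit_variance"))
  expect_error(pca_species(matrix(1, 4, 3)), "constant")
  expect_error(pca_species(m2[1:2, ]), ">= 3 samples")
})

test_that("growth fitting recovers exponential parameters", {
  t <- seq(0, 400, by = 10)
  od <- 0.05 * 2^(t / 90)
  f <- fit_growth(t, od)
  expect_equal(f$doubling_time, 90, tolerance = 1e-6)
  expect_equal(f$k, log(2) / 90, tolerance = 1e-8)
  # only windowed points enter
  expect_equal(f$n_points, sum(od >= 0.2 & od <= 2.5))

  # time-translation invariance of the rate
  f2 <- fit_growth(t + 60, od)
  expect_equal(f2$k, f$k, tolerance = 1e-10)

  # scale equivariance with the window disabled
  f3 <- fit_growth(t, od * 3, od_window = NULL)
  f0 <- fit_growth(t, od, od_window = NULL)
  expect_equal(f3$k, f0$k, tolerance = 1e-8)
  expect_equal(f3$od0, 3 * f0$od0, tolerance = 1e-6)

  # log-linear cross-check agrees within 2% on low-noise data
  set.seed(10)
  noisy <- od * exp(rnorm(length(t), 0, 0.01))
  fn <- fit_growth(t, noisy)
  fl <- fit_growth(t, noisy, method = "loglinear")
  expect_equal(fn$doubling_time, fl$doubling_time, tolerance = 0.02)

  expect_error(fit_growth(c(0, 10), c(0.3, 0.4)), ">= 3 data points")
  # declining culture flagged
  fd <- fit_growth(t[1:10], rev(od[1:10]) + 0.2, od_window = NULL)
  expect_equal(fd$flag, "non_positive_rate")
  expect_true(is.na(fd$doubling_time))
})
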