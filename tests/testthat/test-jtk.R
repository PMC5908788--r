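test_that("reference grid enumerates periods 21/24/27 with 3-h lags", {
  grid <- build_reference_grid(zt48, run_config())
  per <- vapply(grid, `[[`, numeric(1), "period_h")
  lag <- vapply(grid, `[[`, numeric(1), "lag_h")
  expect_setequal(unique(per), c(21, 24, 27))
  expect_equal(unname(table(per)[c("21", "24", "27")]),
               c(7, 8, 9), ignore_attr = TRUE)
  expect_lte(length(grid), 24)
  # rank vectors are pairwise distinct after dedup
  keys <- vapply(grid, function(g) paste(g$ranks, collapse = ","), "")
  expect_false(any(duplicated(keys)))
  # degenerate range: only one period, 8 lags
  g24 <- build_reference_grid(zt48, run_config(period_range_h = c(24, 24)))
  expect_true(all(vapply(g24, `[[`, numeric(1), "period_h") == 24))
  expect_equal(length(g24), 8)
  # 6-h sampling admits only 24 within 20-28
  g6 <- build_reference_grid(seq(0, 42, 6),
                             run_config(sampling_interval_h = 6))
  expect_setequal(vapply(g6, `[[`, numeric(1), "period_h"), 24)
  expect_error(build_reference_grid(zt48,
      run_config(period_range_h = c(25, 26))), "admissible")
})

test_that("kendall_S matches hand and brute-force enumeration", {
  cfg <- run_config(period_range_h = c(24, 24))
  tpl <- build_reference_grid(c(0, 3, 6, 9), cfg)[[1]]
  # x identical to the reference ranks -> perfect concordance
  expect_equal(kendall_S(as.numeric(tpl$ranks), tpl)$tau, 1)
  expect_equal(kendall_S(-as.numeric(tpl$ranks), tpl)$tau, -1)
  # hand example: x=(3,1,4,2) vs untied reference (1,2,3,4)
  tpl2 <- tpl
  tpl2$ranks <- 1:4
  ut <- which(upper.tri(diag(4)), arr.ind = TRUE)
  tpl2$pair_i <- ut[, 1]; tpl2$pair_j <- ut[, 2]
  tpl2$pair_s <- rep(1, 6)
  tpl2$tie_pattern <- rep(1L, 4)
  res <- kendall_S(c(3, 1, 4, 2), tpl2)
  expect_identical(res$S, 0L)
  expect_equal(res$tau, 0)
  # brute force equality on random data across the real grid
  set.seed(2)
  grid <- build_reference_grid(zt48, run_config())
  for (rep_i in 1:10) {
    x <- rnorm(16)
    tpl <- grid[[sample(length(grid), 1)]]
    expect_identical(kendall_S(x, tpl)$S, brute_S(x, tpl$ranks))
  }
  # missing values excluded pairwise
  x <- rnorm(16); x[c(2, 9)] <- NA
  tpl <- grid[[1]]
  expect_identical(kendall_S(x, tpl)$S,
                   brute_S(x[!is.na(x)], tpl$ranks[!is.na(x)]))
})

test_that("exact null equals permutation enumeration (n=4,5)", {
  expect_equal(exact_null_pvalue(6, 4, c(1, 1, 1, 1)), 1 / 12)
  expect_equal(exact_null_pvalue(0, 4, c(1, 1, 1, 1)), 1)
  # n=5, tie pattern {2,2,1}: DP equals enumeration of all 120 orders
  ref <- c(1, 1, 2, 2, 3)
  pm <- all_perms(5)
  Sv <- apply(pm, 1, brute_S, ref = ref)
  for (S in unique(abs(Sv))) {
    expect_equal(exact_null_pvalue(S, 5, c(2, 2, 1)),
                 mean(abs(Sv) >= S))
  }
  expect_error(exact_null_pvalue(0, 5, c(2, 2)), "sum")
})

test_that("null distribution of S is symmetric and super-uniform", {
  nd <- circomics:::null_S_distribution(c(2, 2, 2, 2, 2, 2, 2, 2))
  expect_equal(sum(nd$probs), 1, tolerance = 1e-12)
  expect_equal(nd$probs, rev(nd$probs), tolerance = 1e-12)
  # monotone nonincreasing tail lookup
  expect_true(all(diff(nd$p_tail) <= 1e-15))
  # type-I control: 1000 null features at alpha 0.1
  set.seed(99)
  W <- matrix(rnorm(1000 * 16), 1000,
              dimnames = list(sprintf("n%04d", 1:1000), NULL))
  m <- omics_matrix(W - min(W) + 1, "whole_proteome", zt48, "raw")
  rt <- jtk_cycle(norm_zscore(m))
  expect_lte(mean(rt$rhythmic), 0.12)
})

test_that("jtk_cycle recovers noiseless cosines exactly", {
  x6 <- 10 + 2 * cos(2 * pi * (zt48 - 6) / 24)
  x15 <- 40 + 5 * cos(2 * pi * (zt48 - 15) / 24)
  m <- omics_matrix(rbind(a = x6, b = x15,
                          c = 10 + 2 * cos(2 * pi * (zt48 - 3) / 24)),
                    "tf_dba", zt48, "raw")
  rt <- jtk_cycle(norm_zscore(m))
  expect_equal(rt$best_period_h, rep(24, 3))
  expect_equal(rt$best_lag_h, c(6, 15, 3))
  expect_true(all(rt$p_adj < 0.001))
  expect_true(all(rt$rhythmic))
  expect_true(all(rt$tau == 1))
})

test_that("degenerate and boundary classification behaviour", {
  # constant feature: z-scoring empties it, jtk carries p = 1
  # (state fot so the compositional FOT step does not perturb it)
  set.seed(4)
  v <- rbind(const = rep(5, 16),
             noise = abs(rnorm(16)) + 1,
             noise2 = abs(rnorm(16)) + 1,
             noise3 = abs(rnorm(16)) + 1)
  rt <- jtk_cycle(zscore_per_cycle(
    omics_matrix(v, "tf_dba", zt48, norm_state = "fot")))
  cr <- rt[rt$feature_id == "const", ]
  expect_equal(cr$p_adj, 1)
  expect_false(cr$rhythmic)
  expect_equal(cr$amplitude_est, 0)
  # strict threshold: p_adj == alpha is NOT rhythmic
  fake <- data.frame(feature_id = c("x", "y", "z"),
                     p_adj = c(0.1, 0.05, 0.01))
  expect_identical(classify_rhythmic(fake, 0.1)$rhythmic,
                   c(FALSE, TRUE, TRUE))
  expect_identical(classify_rhythmic(fake, 0.05)$rhythmic,
                   c(FALSE, FALSE, TRUE))
  expect_error(classify_rhythmic(fake, 0), "alpha")
})

test_that("the test is invariant to strictly monotone transforms", {
  set.seed(31)
  fix <- cosine_matrix(20, snr = 3)
  z1 <- norm_zscore(fix$m)
  rt1 <- jtk_cycle(z1)
  # cube is strictly monotone: per-feature ranks unchanged
  z2 <- z1
  z2$values <- z1$values^3
  rt2 <- jtk_cycle(z2)
  expect_identical(rt1$S, rt2$S)
  expect_equal(rt1$p_raw, rt2$p_raw)
  expect_equal(rt1$best_lag_h, rt2$best_lag_h)
})

test_that("features with missing values use the reduced exact null", {
  set.seed(77)
  fix <- cosine_matrix(6, snr = 5)
  vals <- fix$m$values
  vals[2, c(3, 11)] <- NA
  vals[4, 1:13] <- NA    # only 3 observations: degenerate
  # state fot: bypass the compositional FOT step, which would couple
  # the missingness of row 4 into every other row of a 6-row matrix
  m <- omics_matrix(vals, "tf_dba", zt48, norm_state = "fot")
  rt <- jtk_cycle(zscore_per_cycle(m))
  expect_true(rt$rhythmic[2])           # still detected from 14 points
  expect_equal(rt$p_adj[4], 1)          # too few points: carried, p = 1
  expect_false(rt$rhythmic[4])
})
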