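rt_of <- function(ids, rhythmic) {
  data.frame(feature_id = ids, p_adj = ifelse(rhythmic, 0.01, 0.9),
             rhythmic = rhythmic, stringsAsFactors = FALSE)
}

edges_df <- function(tf, tg) data.frame(from = tf, to = tg,
                                        stringsAsFactors = FALSE)

test_that("DR-TF nomination applies its three conditions", {
  # background: 1000 transcripts, 10% rhythmic; TF with 8/10 rhythmic
  bg <- sprintf("G%04d", 1:1000)
  tgr <- rt_of(bg, c(rep(TRUE, 100), rep(FALSE, 900)))
  net <- edges_df(rep(c("TFa", "TFb", "TFc"), c(10, 10, 2)),
                  c(bg[1:8], bg[101:102],      # TFa: 8 rhythmic targets
                    bg[201:210],               # TFb: none rhythmic
                    bg[9:10]))                 # TFc: only 2 targets
  tfr <- rt_of(c("TFa", "TFb", "TFc"), c(TRUE, FALSE, TRUE))
  out <- nominate_dr_tfs(tfr, tgr, net, min_tg = 3, enrich_alpha = 0.05)
  a <- out[out$tf_id == "TFa", ]
  # oracle: exact hypergeometric tail sum
  p_oracle <- sum(dhyper(8:10, 100, 900, 10))
  expect_equal(a$target_rhythm_p, p_oracle)
  expect_lt(a$target_rhythm_p, 1e-6)
  expect_true(a$is_dr_tf)
  # (a) non-rhythmic TF never nominated even with rhythmic targets
  b <- out[out$tf_id == "TFb", ]
  expect_false(b$is_dr_tf)
  # also not when its targets are all rhythmic
  net2 <- edges_df(rep("TFb", 10), bg[1:10])
  out2 <- nominate_dr_tfs(tfr, tgr, net2)
  expect_false(out2$is_dr_tf)
  expect_lt(out2$target_rhythm_p, 1e-8)
  # (b) insufficient targets flagged
  cc <- out[out$tf_id == "TFc", ]
  expect_false(cc$is_dr_tf)
  expect_true(cc$insufficient_targets)
  expect_error(nominate_dr_tfs(tfr, tgr, edges_df(character(0),
                                                  character(0))),
               "empty")
})

test_that("activator/repressor labels follow strict r thresholds", {
  set.seed(5)
  x <- rnorm(16)
  tg <- rbind(same = x, anti = -x, none = rnorm(16))
  out <- classify_regulator_sign(x, tg)
  expect_identical(out$label[1:2], c("activator", "repressor"))
  expect_equal(out$r[1:2], c(1, -1))
  # r exactly at the threshold is unclassified (strict)
  y <- c(1, 2, 3); z <- c(1, 3, 2)           # r = 0.5 exactly
  out2 <- classify_regulator_sign(c(y, rep(NA, 13)),
                                  matrix(c(z, rep(NA, 13)), 1))
  expect_equal(out2$r, 0.5)
  expect_identical(out2$label, "unclassified")
  # zero-variance target flagged
  out3 <- classify_regulator_sign(x, matrix(rep(1, 16), 1))
  expect_true(out3$flagged)
  expect_identical(out3$label, "unclassified")
  # sign-count conservation over a simulated study
  st <- simulate_study(n_tfs = 10, n_tgs_per_tf = 6, frac_rhythmic = 1,
                       frac_dr = 1, frac_tp_specific = 0, seed = 3)
  z <- norm_zscore(st$matrices$tf_dba)
  zt <- zscore_per_cycle(st$matrices$transcriptome)
  tf1 <- st$truth$tf$tf_id[1]
  tgs <- st$truth$edges$to[st$truth$edges$from == tf1]
  lab <- classify_regulator_sign(z$values[tf1, ],
                                 zt$values[tgs, , drop = FALSE])
  expect_equal(nrow(lab), length(tgs))
  expect_equal(sum(lab$label == "activator") +
                 sum(lab$label == "repressor") +
                 sum(lab$label == "unclassified"), length(tgs))
})

test_that("ubiquitylation crosstab computes set-union percentages", {
  tfr <- rt_of(c("A", "B", "C", "D"), c(TRUE, TRUE, FALSE, FALSE))
  # A,B share targets; union size 25 with 2 ubiquitylated -> 8%
  tg_ab <- sprintf("u%02d", 1:25)
  net <- edges_df(c(rep("A", 15), rep("B", 15), rep("C", 10), rep("D", 10)),
                  c(tg_ab[1:15], tg_ab[11:25],
                    sprintf("v%02d", 1:10), sprintf("v%02d", 6:15)))
  ubi <- c("u01", "u02", "v01", "A")
  xt <- ubiquitylation_crosstab(tfr, net, ubi)
  expect_equal(xt$percent[xt$group == "tgs_of_rhythmic_tfs"], 8)
  expect_equal(xt$percent[xt$group == "rhythmic_tfs"], 50)
  expect_equal(xt$n[xt$group == "tgs_of_nonrhythmic_tfs"], 15)
  # 2 of 40 rhythmic TFs -> 5%
  tfr40 <- rt_of(sprintf("T%02d", 1:40), rep(TRUE, 40))
  net40 <- edges_df(sprintf("T%02d", 1:40), sprintf("g%02d", 1:40))
  xt40 <- ubiquitylation_crosstab(tfr40, net40, c("T01", "T02"))
  expect_equal(xt40$percent[xt40$group == "rhythmic_tfs"], 5)
  # empty denominator is NA, not 0
  expect_true(is.na(xt40$percent[xt40$group == "nonrhythmic_tfs"]))
})

test_that("resampling test obeys its degenerate contracts", {
  net <- edges_df(rep(sprintf("T%02d", 1:10), each = 5),
                  sprintf("g%03d", 1:50))
  ubi <- sprintf("g%03d", 1:10)
  # rhythmic set = all TFs: every null draw equals the observed set
  r <- random_tf_resample_test(net, ubi, sprintf("T%02d", 1:10),
                               n_iter = 200, seed = 1)
  expect_equal(r$p, 1)
  # observed statistic 0 -> p = 1 by the add-one estimator
  r0 <- random_tf_resample_test(net, character(0), sprintf("T%02d", 1:3),
                                n_iter = 200, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  expect_error(random_tf_resample_test(net, ubi, "T01", n_iter = 50),
               "n_iter")
  # planted enrichment is detected
  net20 <- edges_df(rep(sprintf("T%02d", 1:20), each = 5),
                    sprintf("g%03d", 1:100))
  rich <- sprintf("T%02d", 1:5)
  ubi2 <- sprintf("g%03d", 1:25)          # every target of the rich TFs
  r2 <- random_tf_resample_test(net20, ubi2, rich, n_iter = 2000,
                                seed = 2)
  expect_lt(r2$p, 0.01)
})
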