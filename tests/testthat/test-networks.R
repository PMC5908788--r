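g_from <- function(...) {
  igraph::graph_from_data_frame(data.frame(...), directed = FALSE)
}

test_that("shortest paths match definitions and a Floyd-Warshall oracle", {
  g <- g_from(from = c("A", "B"), to = c("B", "C"))
  d <- shortest_path_lengths(g, c("A"), c("A", "C"))
  expect_equal(d["A", "C"], 2)
  expect_equal(d["A", "A"], 0)
  # disconnected pair marked unreachable
  g2 <- g_from(from = c("A", "C"), to = c("B", "D"))
  d2 <- shortest_path_lengths(g2, "A", c("B", "D"))
  expect_equal(d2["A", "B"], 1)
  expect_true(is.infinite(d2["A", "D"]))
  expect_error(shortest_path_lengths(g, character(0), "A"), "non-empty")
  expect_message(shortest_path_lengths(g, c("A", "ZZ"), "C"), "absent")
  # Floyd-Warshall oracle on random graphs up to 30 nodes
  set.seed(14)
  for (rep_i in 1:5) {
    n <- sample(5:30, 1)
    nets <- simulate_networks(n_nodes = n, edge_prob = 0.15,
                              n_kinases = 0)
    adj <- as.matrix(igraph::as_adjacency_matrix(nets$ppi))
    D <- ifelse(adj > 0, 1, Inf); diag(D) <- 0
    for (k in 1:n) for (i in 1:n) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
    ids <- rownames(adj)
    got <- shortest_path_lengths(nets$ppi, ids, ids)
    expect_equal(got[ids, ids], D[ids, ids], ignore_attr = TRUE)
  }
})

test_that("paired path comparison matches the closed-form t-test", {
  ps <- data.frame(substrate_id = c("s1", "s2", "s3"),
                   mean_path_to_pathway_tfs = c(2, 3, 4),
                   mean_path_to_all_tfs = c(1, 1, 1))
  # differences (1,2,3): t = mean*sqrt(n)/sd = 2*sqrt(3)/1
  out <- compare_path_lengths(ps)
  expect_equal(out$statistic, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(out$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(out$df, 2)
  expect_equal(out$p_two_sided, 2 * pt(-2 * sqrt(3), 2),
               tolerance = 1e-6)
  expect_equal(out$p_two_sided, 0.0742, tolerance = 1e-3)
  # all differences zero: degenerate
  ps0 <- ps; ps0$mean_path_to_pathway_tfs <- ps0$mean_path_to_all_tfs
  expect_error(compare_path_lengths(ps0), "degenerate")
})

test_that("hub topology makes pathway-TF paths measurably shorter", {
  # substrates wired straight to pathway TFs; other TFs hang off a
  # two-step chain from a single hub
  subs <- sprintf("S%02d", 1:8)
  ptf <- sprintf("PT%02d", 1:3)
  otf <- sprintf("OT%02d", 1:10)
  el <- rbind(
    expand.grid(from = subs, to = ptf, stringsAsFactors = FALSE),
    data.frame(from = ptf[1], to = "hub"),
    data.frame(from = "hub", to = "relay"),
    data.frame(from = "relay", to = otf),
    # shortcuts so per-substrate means differ (non-degenerate pairs)
    data.frame(from = c("S01", "S02"), to = c("relay", "hub")))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  ps <- summarize_paths(g, subs, ptf, c(ptf, otf))
  tt <- compare_path_lengths(ps)
  expect_true(all(ps$mean_path_to_pathway_tfs <
                    ps$mean_path_to_all_tfs))
  expect_lt(tt$p_two_sided, 0.05)
})

test_that("top-k mediator linking ranks by r with lexicographic ties", {
  tp <- zt48
  tf <- matrix(sin(2 * pi * tp / 24), 1, dimnames = list("TF1", NULL))
  base <- sin(2 * pi * tp / 24)
  set.seed(6)
  med <- rbind(
    MedA = base + rnorm(16, 0, 0.10),
    MedB = 0.5 * base + rnorm(16, 0, 1.1),
    MedC = rev(base),
    MedD = rnorm(16),
    MedE = base)
  out <- top_k_correlated_mediators(tf, med, k = 3)
  expect_equal(nrow(out), 3)
  expect_equal(out$mediator_id[1], "MedE")   # exact copy: r = 1 first
  expect_equal(out$r[1], 1)
  expect_false(any(out$flagged_short))
  # fewer mediators than k: all linked, flagged
  out2 <- top_k_correlated_mediators(tf, med[1:2, ], k = 3)
  expect_equal(nrow(out2), 2)
  expect_true(all(out2$flagged_short))
  # exact tie on r broken lexicographically by mediator id
  m_tie <- rbind(Mz = base, Ma = base, Mm = -base, Mq = 0.2 * base +
                   c(rep(c(1, -1), 8)))
  out3 <- top_k_correlated_mediators(tf, m_tie, k = 2)
  expect_equal(out3$mediator_id, c("Ma", "Mz"))
})

test_that("correlation-set comparison pairs by mediator", {
  set.seed(30)
  meds <- sprintf("M%02d", 1:6)
  r_path <- matrix(0.8 + rnorm(30, 0, 0.03), 6, 5,
                   dimnames = list(meds, NULL))
  r_all <- matrix(0.2 + rnorm(30, 0, 0.03), 6, 5,
                  dimnames = list(meds, NULL))
  out <- compare_correlation_sets(r_path, r_all)
  expect_equal(out$mean_pathway - out$mean_all, 0.6, tolerance = 0.05)
  expect_lt(out$p_two_sided, 1e-4)
  expect_equal(out$n_mediators, 6)
  expect_error(compare_correlation_sets(r_path, r_path), "degenerate")
})

test_that("bipartite edge counting is symmetric and excludes within-set", {
  g <- g_from(from = c("A", "A", "A", "B", "B", "C"),
              to = c("B", "C", "D", "C", "D", "D"))  # K4
  expect_equal(bipartite_edge_count(c("A", "B"), c("C", "D"), g), 4)
  expect_equal(bipartite_edge_count(c("C", "D"), c("A", "B"), g), 4)
  g1 <- g_from(from = "A", to = "B")
  expect_equal(bipartite_edge_count("A", "B", g1), 1)
  expect_equal(bipartite_edge_count(c("A", "B"), "Z", g1), 0)
})

test_that("hypergeometric enrichment equals exhaustive tail enumeration", {
  bg <- sprintf("b%03d", 1:100)
  fg <- bg[1:10]
  sets <- list(hit = bg[c(1:5, 50:54)],     # 5 of 10 in fg
               miss = bg[90:95],
               all_fg = bg[1:10])
  out <- fisher_enrichment(fg, bg, sets)
  p_oracle <- sum(vapply(5:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(out$p[out$set == "hit"], p_oracle, tolerance = 1e-12)
  expect_gt(out$p[out$set == "miss"], 0.4)
  # fg == bg: p = 1 for every set
  out2 <- fisher_enrichment(bg, bg, sets)
  expect_true(all(out2$p == 1))
  expect_error(fisher_enrichment(character(0), bg, sets), "empty")
  expect_message(fisher_enrichment(c(fg, "extra"), bg, sets), "clipped")
  # exhaustive enumeration oracle at small scale
  set.seed(17)
  for (rep_i in 1:5) {
    N <- sample(10:60, 1); n <- sample(3:(N - 1), 1)
    K <- sample(1:N, 1)
    bgs <- paste0("x", 1:N)
    fgs <- sample(bgs, n)
    s <- sample(bgs, K)
    k <- length(intersect(fgs, s))
    p_or <- sum(vapply(k:min(n, K), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, numeric(1)))
    got <- fisher_enrichment(fgs, bgs, list(s = s))$p
    expect_equal(got, p_or, tolerance = 1e-10)
  }
})

test_that("pearson_r follows the product-moment definition", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -2 * (1:10) + 7), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 2, NA), c(1, 2, 3)), "complete")
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})
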