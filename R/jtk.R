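# Nonparametric rhythmicity test of the JTK_CYCLE family.
#
# Each feature's time series is compared with cosine reference
# templates over a period x phase-lag grid via Kendall concordance;
# the minimum p over the grid is Bonferroni-adjusted for the number
# of distinct templates searched ("amplitude and phase as free
# parameters" implies a search the adjustment must pay for). The
# null distribution of the concordance statistic S is exact: under a
# uniformly random ordering of the data, the number of discordant
# pairs relative to a reference ranking with tie groups t_1..t_g is
# distributed as the inversions of a uniform random multiset
# permutation, whose generating function is the Gaussian
# (q-)multinomial coefficient -- computed here by convolving Gaussian
# binomials group by group.

.jtk_cache <- new.env(parent = emptyenv())

poly_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Coefficients of the Gaussian binomial [m+t, t]_q (degree m*t):
# coefficient j = number of interleavings of t tied new elements into
# m old ones producing j new-vs-old inversions. Built by the exact
# product formula with interleaved synthetic division, which keeps
# every intermediate an integer-coefficient Gaussian binomial.
qbinom_coeffs <- function(m, t) {
  P <- 1
  if (t == 0L || m == 0L) return(P)
  for (i in seq_len(t)) {
    d <- m + i
    Pnew <- c(P, numeric(d)) - c(numeric(d), P)  # * (1 - q^(m+i))
    L <- length(Pnew) - i                        # / (1 - q^i)
    cpol <- numeric(L)
    for (j in seq_len(L)) {
      cpol[j] <- Pnew[j] + if (j > i) cpol[j - i] else 0
    }
    P <- cpol
  }
  P
}

# Exact null distribution of the discordance count D (and hence of
# S = K - 2 D) for a reference ranking with the given tie-group sizes.
null_S_distribution <- function(tie_pattern) {
  t <- as.integer(tie_pattern)
  if (any(t < 1)) stop("tie pattern sizes must be positive")
  n <- sum(t)
  key <- paste(sort(t), collapse = ",")
  hit <- .jtk_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- (n^2 - sum(t^2)) / 2
  P <- 1
  m <- 0L
  for (tk in t) {
    g <- qbinom_coeffs(m, tk)
    g <- g / sum(g)
    P <- poly_conv(P, g)
    m <- m + tk
  }
  probs <- P / sum(P)          # probs[d + 1] = P(D = d), d = 0..K
  # two-sided tail lookup: p_tail[a + 1] = P(|S| >= a), a = 0..K
  absS <- abs(K - 2 * (0:K))
  p_tail <- vapply(0:K, function(a) sum(probs[absS >= a]), numeric(1))
  p_tail <- pmin(p_tail, 1)
  res <- list(K = K, probs = probs, p_tail = p_tail)
  assign(key, res, envir = .jtk_cache)
  res
}

#' Exact two-sided null p-value of the Kendall concordance statistic
#'
#' Probability, under uniformly random orderings of the data given
#' the reference's tie pattern, that the concordance statistic
#' `|S_null| >= |S|`. Exact for series up to length 50 (Gaussian
#' q-multinomial convolution); beyond that a seeded permutation
#' approximation with `n_perm` draws is used.
#'
#' @param S Observed statistic (concordant minus discordant pairs
#'   over reference-untied pairs).
#' @param n Series length.
#' @param tie_pattern Integer vector of reference tie-group sizes
#'   (must sum to `n`).
#' @param n_perm Permutation draws for the large-`n` fallback
#'   (default 10000; the caller seeds the RNG).
#' @return Two-sided p-value in (0, 1].
#' @export
exact_null_pvalue <- function(S, n, tie_pattern, n_perm = 10000L) {
  tie_pattern <- as.integer(tie_pattern)
  if (sum(tie_pattern) != n) {
    stop("tie pattern sizes sum to ", sum(tie_pattern),
         ", expected n = ", n)
  }
  if (n <= 50) {
    nd <- null_S_distribution(tie_pattern)
    a <- abs(S)
    if (a > nd$K) stop("|S| exceeds the maximum ", nd$K,
                       " attainable under this tie pattern")
    return(nd$p_tail[a + 1L])
  }
  # permutation approximation (n > 50): simulate S under random data
  ref <- rep(seq_along(tie_pattern), times = tie_pattern)
  cmb <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sref <- sign(ref[cmb[, 2]] - ref[cmb[, 1]])
  keep <- sref != 0
  i <- cmb[keep, 1]; j <- cmb[keep, 2]; sref <- sref[keep]
  hits <- 0L
  for (b in seq_len(n_perm)) {
    x <- sample.int(n)
    Sb <- sum(sign(x[j] - x[i]) * sref)
    if (abs(Sb) >= abs(S)) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Cosine reference template grid for the rank rhythm test
#'
#' Enumerates reference templates cos(2 pi (t - lag) / period) over
#' every admissible period in the configured range (periods are
#' restricted to integer multiples of the sampling interval, so the
#' default 20-28 h range at 3-h sampling yields 21, 24 and 27 h) and
#' every lag stepping by the sampling interval within one period.
#' Templates whose rank vectors coincide are deduplicated (first
#' period/lag kept); the deduplicated count is the Bonferroni factor.
#'
#' @param timepoints Numeric ZT hours of the series.
#' @param config A [run_config()].
#' @return List of `jtk_template` objects, each carrying
#'   `period_h`, `lag_h`, `ranks`, `tie_pattern` and precomputed
#'   reference-untied pair indices.
#' @export
build_reference_grid <- function(timepoints, config = run_config()) {
  h <- config$sampling_interval_h
  lo <- config$period_range_h[1]; hi <- config$period_range_h[2]
  periods <- seq(ceiling(lo / h) * h, floor(hi / h) * h, by = h)
  periods <- periods[periods > 0]
  if (!length(periods)) {
    stop("no admissible period (integer multiple of ", h,
         " h) in range [", lo, ", ", hi, "]")
  }
  n <- length(timepoints)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  templates <- list()
  seen <- character(0)
  for (p in periods) {
    for (lag in seq(0, p - h, by = h)) {
      ref <- cos(2 * pi * (timepoints - lag) / p)
      r <- rank(round(ref, 9))
      key <- paste(r, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      sref <- sign(r[ut[, 2]] - r[ut[, 1]])
      keep <- sref != 0
      templates[[length(templates) + 1L]] <- structure(
        list(period_h = p, lag_h = lag, ranks = r,
             tie_pattern = as.integer(sort(table(r), decreasing = TRUE)),
             pair_i = ut[keep, 1], pair_j = ut[keep, 2],
             pair_s = sref[keep]),
        class = "jtk_template")
    }
  }
  templates
}

#' Kendall concordance of a series with a reference template
#'
#' S counts concordant minus discordant pairs among pairs untied in
#' the reference; data-tied pairs contribute zero and are excluded
#' from the tau denominator (tau-b style: S divided by the number of
#' pairs untied in both reference and data). Pairs involving missing
#' values are excluded pairwise.
#'
#' @param x Numeric series (same length as the template's
#'   timepoints; `NA` allowed).
#' @param ref A `jtk_template` from [build_reference_grid()].
#' @return List with `S`, `tau`, `n_pairs` (non-missing
#'   reference-untied pairs), `n_untied` (tau denominator) and a
#'   `degenerate` flag (fewer than 4 observations or all data tied).
#' @export
kendall_S <- function(x, ref) {
  stopifnot(inherits(ref, "jtk_template"))
  dx <- x[ref$pair_j] - x[ref$pair_i]
  ok <- !is.na(dx)
  sg <- sign(dx[ok])
  S <- sum(sg * ref$pair_s[ok])
  denom <- sum(sg != 0)
  degenerate <- sum(!is.na(x)) < 4 || denom == 0
  list(S = as.integer(S),
       tau = if (denom > 0) S / denom else 0,
       n_pairs = sum(ok), n_untied = denom,
       degenerate = degenerate)
}

# Test one (possibly incomplete) series against one (period, lag):
# template ranks, tie pattern and the exact null are all rebuilt on
# the observed timepoints only.
kendall_template_test <- function(x, timepoints, period, lag) {
  obs <- which(!is.na(x))
  n <- length(obs)
  if (n < 4) {
    return(list(S = 0L, tau = 0, p = 1, degenerate = TRUE))
  }
  ref <- cos(2 * pi * (timepoints[obs] - lag) / period)
  r <- rank(round(ref, 9))
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sref <- sign(r[ut[, 2]] - r[ut[, 1]])
  keep <- sref != 0
  if (!any(keep)) return(list(S = 0L, tau = 0, p = 1, degenerate = TRUE))
  xx <- x[obs]
  sg <- sign(xx[ut[keep, 2]] - xx[ut[keep, 1]])
  S <- sum(sg * sref[keep])
  denom <- sum(sg != 0)
  if (denom == 0) return(list(S = 0L, tau = 0, p = 1, degenerate = TRUE))
  tie_pattern <- as.integer(sort(table(r), decreasing = TRUE))
  p <- exact_null_pvalue(S, n, tie_pattern)
  list(S = as.integer(S), tau = S / denom, p = p, degenerate = FALSE)
}

# Seeded permutation p for a feature whose data ties exceed the
# fraction where the reference-only exact null is trusted.
permutation_pvalue <- function(x, ref, n_perm = 10000L) {
  obs <- x[!is.na(x)]
  ks <- kendall_S(x, ref)
  hits <- 0L
  n <- length(x)
  miss <- is.na(x)
  for (b in seq_len(n_perm)) {
    xb <- x
    xb[!miss] <- sample(obs)
    Sb <- kendall_S(xb, ref)$S
    if (abs(Sb) >= abs(ks$S)) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' JTK-family rhythm test across a matrix
#'
#' Runs the Kendall/cosine-template test on every feature of a
#' z-scored matrix: per feature the minimum raw p over the template
#' grid is taken (ties broken by larger |tau|, then smaller period,
#' then smaller lag), Bonferroni-adjusted by the deduplicated
#' template count, and flagged rhythmic when `p_adj < alpha`
#' (strict). Amplitude is estimated as half the difference between
#' the mean of the values at the best template's top-quartile
#' reference ranks and the mean at its bottom-quartile ranks (a
#' non-canonical but monotone estimator). Two-cycle courses are
#' analysed as one series with the template wrapped at its period.
#'
#' Features with missing values are rescored against templates
#' rebuilt on their observed timepoints; features with excessive data
#' ties (> 25% of pairs) fall back to a seeded permutation null.
#' Degenerate features (constant, or < 4 observations) are carried
#' through with p = 1.
#'
#' @param m A z-scored [omics_matrix()].
#' @param config A [run_config()].
#' @param alpha Rhythmicity threshold; default follows the layer
#'   (`alpha_transcript` for the transcriptome, `alpha_proteome`
#'   otherwise).
#' @return A `RhythmTable` data frame with columns `feature_id`,
#'   `best_period_h`, `best_lag_h`, `tau`, `S`, `amplitude_est`,
#'   `p_raw`, `p_adj`, `rhythmic`; the Bonferroni factor is stored in
#'   attribute `"n_templates"`, the threshold in `"alpha"`.
#' @export
jtk_cycle <- function(m, config = run_config(), alpha = NULL) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (!m$norm_state %in% c("zscored", "fpkm_zscored")) {
    warning("jtk_cycle input has norm_state '", m$norm_state,
            "'; the test is rank-based but z-scored input is the ",
            "intended contract")
  }
  if (is.null(alpha)) {
    alpha <- if (m$layer == "transcriptome") config$alpha_transcript
             else config$alpha_proteome
  }
  grid <- build_reference_grid(m$timepoints, config)
  nt <- length(grid)
  X <- m$values
  nf <- nrow(X)
  per <- vapply(grid, `[[`, numeric(1), "period_h")
  lag <- vapply(grid, `[[`, numeric(1), "lag_h")
  Pm <- matrix(1, nf, nt)
  Tau <- matrix(0, nf, nt)
  Sm <- matrix(0L, nf, nt)
  degen <- logical(nf)
  complete <- rowSums(is.na(X)) == 0L
  for (k in seq_len(nt)) {
    tpl <- grid[[k]]
    nd <- null_S_distribution(tpl$tie_pattern)
    if (any(complete)) {
      Xc <- X[complete, , drop = FALSE]
      SG <- sign(Xc[, tpl$pair_j, drop = FALSE] -
                 Xc[, tpl$pair_i, drop = FALSE])
      S <- as.vector(SG %*% tpl$pair_s)
      npair <- length(tpl$pair_s)
      tied <- rowSums(SG == 0)
      denom <- npair - tied
      tau <- ifelse(denom > 0, S / denom, 0)
      p <- nd$p_tail[abs(S) + 1L]
      heavy <- which(tied / npair > 0.25 & denom > 0)
      for (f in heavy) {
        p[f] <- permutation_pvalue(Xc[f, ], tpl)
      }
      p[denom == 0] <- 1
      Pm[complete, k] <- p
      Tau[complete, k] <- tau
      Sm[complete, k] <- as.integer(S)
    }
  }
  # constant complete rows: every template gives denom 0 -> p 1
  if (any(complete)) {
    allone <- complete & apply(Pm == 1 & Sm == 0L, 1L, all) &
      apply(X, 1L, function(r) length(unique(r[!is.na(r)])) <= 1)
    degen[allone] <- TRUE
  }
  inc <- which(!complete)
  for (f in inc) {
    x <- X[f, ]
    if (sum(!is.na(x)) < 4) { degen[f] <- TRUE; next }
    for (k in seq_len(nt)) {
      res <- kendall_template_test(x, m$timepoints, per[k], lag[k])
      Pm[f, k] <- res$p
      Tau[f, k] <- res$tau
      Sm[f, k] <- res$S
    }
    if (all(Pm[f, ] == 1 & Sm[f, ] == 0L)) degen[f] <- TRUE
  }
  # tie-break at equal minimum p: prefer the positively concordant
  # template (antiphase pairs tie on p and |tau|, but the lag of a
  # template is only a peak time when the association is positive),
  # then smaller period, then smaller lag
  best <- integer(nf)
  for (f in seq_len(nf)) {
    best[f] <- order(Pm[f, ], -Tau[f, ], per, lag)[1L]
  }
  idx <- cbind(seq_len(nf), best)
  p_raw <- Pm[idx]
  p_adj <- pmin(1, p_raw * nt)
  amplitude <- numeric(nf)
  for (f in seq_len(nf)) {
    tpl <- grid[[best[f]]]
    x <- X[f, ]
    obs <- !is.na(x)
    r <- if (all(obs)) tpl$ranks else
      rank(round(cos(2 * pi * (m$timepoints[obs] - tpl$lag_h) /
                       tpl$period_h), 9))
    xx <- x[obs]
    nobs <- length(xx)
    if (nobs < 4) { amplitude[f] <- NA_real_; next }
    kq <- ceiling(nobs / 4)
    o <- order(r)
    amplitude[f] <- (mean(xx[o[(nobs - kq + 1):nobs]]) -
                       mean(xx[o[1:kq]])) / 2
  }
  # a negatively concordant best template peaks where the data
  # troughs: the implied peak time is the template lag shifted by
  # half its period (relevant for periods whose antiphase lag is not
  # on the 3-h grid)
  best_lag <- ifelse(Tau[idx] < 0,
                     (lag[best] + per[best] / 2) %% per[best],
                     lag[best])
  # report the lag as a clock time: circular mean (mod 24) of the
  # template's peak times inside the observation window -- identical
  # to the lag for 24-h templates, and the unbiased projection onto
  # the 24-h day for 21/27-h templates whose peaks drift across the
  # two cycles
  tmax <- max(m$timepoints)
  best_lag <- vapply(seq_len(nf), function(f) {
    circ_peak_mod24(per[best[f]], best_lag[f], tmax)
  }, numeric(1))
  out <- data.frame(
    feature_id = rownames(X),
    best_period_h = ifelse(degen, NA_real_, per[best]),
    best_lag_h = ifelse(degen, NA_real_, best_lag),
    tau = Tau[idx],
    S = Sm[idx],
    # magnitude: a negatively concordant template sees the contrast
    # with opposite sign
    amplitude_est = ifelse(degen, 0, abs(amplitude)),
    p_raw = ifelse(degen, 1, p_raw),
    p_adj = ifelse(degen, 1, p_adj),
    stringsAsFactors = FALSE)
  out$rhythmic <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "n_templates") <- nt
  attr(out, "alpha") <- alpha
  attr(out, "layer") <- m$layer
  class(out) <- c("RhythmTable", "data.frame")
  out
}

circ_peak_mod24 <- function(period, lag, tmax) {
  if (is.na(lag)) return(NA_real_)
  peaks <- seq(lag, tmax, by = period) %% 24
  ang <- 2 * pi * peaks / 24
  est <- atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)
  round(est %% 24, 9)
}

#' Re-flag rhythmicity at a different threshold
#'
#' @param rt A `RhythmTable` from [jtk_cycle()].
#' @param alpha Threshold in (0, 1]; features with `p_adj < alpha`
#'   (strict) are flagged rhythmic.
#' @return The table with its `rhythmic` column and `"alpha"`
#'   attribute updated.
#' @export
classify_rhythmic <- function(rt, alpha) {
  stopifnot(is.data.frame(rt), "p_adj" %in% names(rt))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  rt$rhythmic <- rt$p_adj < alpha
  attr(rt, "alpha") <- alpha
  rt
}
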