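# Shared fixtures: everything is generated in code at test time.

zt48 <- seq(0, 45, by = 3)

# cosine + noise matrix with known acrophases
cosine_matrix <- function(n, snr, acro = NULL, baseline = 50,
                          noise_sd = 1, timepoints = zt48,
                          layer = "tf_dba") {
  if (is.null(acro)) acro <- runif(n, 0, 24)
  vals <- t(sapply(seq_len(n), function(i) {
    pmax(0, baseline + snr * noise_sd *
           cos(2 * pi * (timepoints - acro[i]) / 24) +
           rnorm(length(timepoints), 0, noise_sd))
  }))
  rownames(vals) <- sprintf("F%04d", seq_len(n))
  list(m = omics_matrix(vals, layer, timepoints = timepoints,
                        norm_state = "raw"),
       acro = acro)
}

norm_zscore <- function(m) zscore_per_cycle(ibaq_to_fot(m))

# all permutations of 1..n (oracle enumerator, n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, p + (p >= k)))
  }
  unname(out)
}

# brute-force Kendall S of data x against a reference with ties
brute_S <- function(x, ref) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ref[i] != ref[j] && x[i] != x[j]) {
        s <- s + sign(x[j] - x[i]) * sign(ref[j] - ref[i])
      }
    }
  }
  as.integer(s)
}

# integer partitions of n (tie patterns)
partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
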