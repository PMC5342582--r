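# Independent brute-force oracles used to validate the fast paths.

# All-pairs AUC with half credit for ties.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (a in sp) {
    for (b in sn) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(sp) * length(sn))
}

# Exhaustive 1-D k = 2 medoid search, written as plain loops.
oracle_pam_k2_cost <- function(values) {
  n <- length(values)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cost <- 0
      for (v in values) {
        cost <- cost + min(abs(v - values[i]), abs(v - values[j]))
      }
      best <- min(best, cost)
    }
  }
  best
}

# Naive O(n * m) interval overlap counting, half-open coordinates.
oracle_count_overlaps <- function(peaks, regions) {
  out <- integer(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] == regions$chrom[r] &&
          peaks$start[p] < regions$end[r] &&
          regions$start[r] < peaks$end[p]) {
        out[r] <- out[r] + 1L
      }
    }
  }
  out
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Random small interval set on a toy genome.
random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                             max_len = 500) {
  starts <- sample.int(max_pos, n, replace = TRUE) - 1L
  lens <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = starts + lens
  )
}

small_cohort <- function(n_per_group = 10, sigma = 0.3, seed = 11, ...) {
  spec <- cohort_spec(n_per_group = n_per_group, sigma = sigma, seed = seed, ...)
  gen_expression_cohort(spec)
}
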