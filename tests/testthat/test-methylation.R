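test_that("binning sums counts into half-open 100-nt bins", {
  track <- tibble::tibble(
    pos = 0:100, sample_id = "s1", count = 1L
  )
  out <- bin_track(track, bin_size = 100)
  expect_equal(out$count[out$bin == 0], 100)
  expect_equal(out$count[out$bin == 1], 1) # position 100 goes to bin 1
  # random track equals the per-position loop
  set.seed(31)
  tr <- tibble::tibble(
    pos = sample(0:999, 300, replace = TRUE),
    sample_id = sample(c("a", "b"), 300, replace = TRUE),
    count = rpois(300, 3)
  )
  got <- bin_track(tr, bin_size = 50)
  for (i in seq_len(nrow(got))) {
    want <- sum(tr$count[tr$sample_id == got$sample_id[i] &
                           tr$pos >= got$bin_start[i] &
                           tr$pos < got$bin_end[i]])
    expect_equal(got$count[i], want)
  }
})

test_that("methylation fractions follow #C / (#C + #T)", {
  expect_equal(methylation_fraction(3, 1), 0.75)
  expect_equal(methylation_fraction(0, 7), 0)
  expect_equal(methylation_fraction(5, 0), 1)
  expect_warning(out <- methylation_fraction(c(2, 0), c(2, 0)), "zero coverage")
  expect_equal(out, c(0.5, NA))
})

test_that("the binned count test flags only genuine rate differences", {
  mk <- function(case_counts, ctrl_counts) {
    purrr::imap_dfr(list(case = case_counts, control = ctrl_counts),
                    function(counts, grp) {
      purrr::imap_dfr(counts, function(bin_counts, s) {
        tibble::tibble(
          bin = seq_along(bin_counts) - 1L,
          bin_start = (seq_along(bin_counts) - 1L) * 100L,
          bin_end = seq_along(bin_counts) * 100L,
          sample_id = paste0(grp, s), group = grp, count = bin_counts
        )
      })
    })
  }
  # identical group totals: no signal
  b0 <- mk(list(c(5L, 5L), c(5L, 5L)), list(c(5L, 5L), c(5L, 5L)))
  out0 <- diff_bins_counts(b0)
  expect_true(all(!out0$flagged))
  expect_true(all(out0$p_value > 0.9))
  # one 50-vs-0 bin on equal library sizes (100 each): p = 2 * 0.5^50
  b1 <- mk(list(c(50L, 25L), c(0L, 25L)), list(c(0L, 50L), c(0L, 50L)))
  out1 <- diff_bins_counts(b1)
  expect_equal(out1$p_value[1], 2 * 0.5^50, tolerance = 1e-10)
  expect_true(out1$flagged[1])
  expect_equal(out1$direction[1], "hyper")
})

test_that("the binned count test is calibrated under the null", {
  set.seed(32)
  n_bins <- 1000
  binned <- purrr::map_dfr(c("case", "control"), function(grp) {
    purrr::map_dfr(1:2, function(s) {
      tibble::tibble(
        bin = seq_len(n_bins) - 1L,
        bin_start = (seq_len(n_bins) - 1L) * 100L,
        bin_end = seq_len(n_bins) * 100L,
        sample_id = paste0(grp, s), group = grp,
        count = rpois(n_bins, 20)
      )
    })
  })
  out <- diff_bins_counts(binned)
  # exact binomial test at alpha = 0.01 is conservative: the raw
  # rejection rate stays at or below ~1%
  expect_lte(mean(out$p_value < 0.01, na.rm = TRUE), 0.02)
  expect_false(any(out$flagged))
})

test_that("position-level rank tests recover a strong planted DMR", {
  set.seed(33)
  recovered <- vapply(1:10, function(s) {
    tr <- gen_methylation(methyl_spec(
      n_positions = 60, dmr_interval = c(0, 1000), delta = 0.5,
      depth = 100, n_per_group = 10, p0 = 0.2, step = 50, seed = s
    ))
    out <- diff_positions_fraction(tr)
    planted <- out$pos < 1000 # 20 positions
    sum(out$flagged[planted]) >= 18
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
  # BH q-values are monotone in the ranked p-values
  tr <- gen_methylation(methyl_spec(seed = 3))
  out <- diff_positions_fraction(tr)
  ord <- order(out$p_value)
  expect_true(all(diff(out$q_value[ord]) >= -1e-12))
  # identical groups flag nothing
  tr0 <- gen_methylation(methyl_spec(delta = 0, seed = 5))
  out0 <- diff_positions_fraction(tr0)
  expect_lte(mean(out0$flagged), 0.05)
})

test_that("beta-value region calling respects the cutoff and permutation null", {
  mk_betas <- function(d, n = 6, probes = 10, seed = 1) {
    set.seed(seed)
    tidyr::expand_grid(
      pos = seq_len(probes) * 100L,
      sample_id = paste0("s", 1:(2 * n))
    ) %>%
      dplyr::mutate(
        group = ifelse(as.integer(sub("s", "", sample_id)) <= n,
                       "case", "control"),
        beta = pmin(1, pmax(0, 0.3 + ifelse(group == "case" & pos <= 300,
                                            d, 0) +
                              rnorm(dplyr::n(), 0, 0.02)))
      )
  }
  # no planted difference: no candidate regions
  out0 <- diff_regions_beta(mk_betas(0), n_perm = 20, seed = 2)
  expect_equal(nrow(out0), 0)
  # single clear probe-level difference forms a region
  one <- tibble::tibble(
    pos = rep(100L, 4), sample_id = paste0("s", 1:4),
    group = c("case", "case", "control", "control"),
    beta = c(0.8, 0.8, 0.1, 0.1)
  )
  out1 <- diff_regions_beta(one, n_perm = 20, seed = 2)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$score, 0.7, tolerance = 1e-9)
  expect_equal(out1$direction, "hyper")
  # strong planted region: permutation p <= 0.05 in most seeds
  sig <- vapply(1:10, function(s) {
    out <- diff_regions_beta(mk_betas(0.4, seed = s), n_perm = 60, seed = s)
    nrow(out) > 0 && min(out$p_value) <= 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("flagged items merge by adjacency rules and direction", {
  bins <- tibble::tibble(
    bin_start = c(0L, 100L, 300L),
    bin_end = c(100L, 200L, 400L),
    direction = "hyper"
  )
  out <- merge_flagged(bins, mode = "bin")
  expect_equal(out$start, c(0L, 300L))
  expect_equal(out$end, c(200L, 400L))
  pos <- tibble::tibble(pos = c(1000L, 1050L, 1200L), direction = "hyper")
  outp <- merge_flagged(pos, mode = "position", gap = 100)
  expect_equal(outp$start, c(1000L, 1200L))
  expect_equal(outp$end, c(1051L, 1201L))
  expect_equal(outp$n_items, c(2L, 1L))
  # opposite directions never merge, and unsorted input is sorted
  mixed <- tibble::tibble(
    bin_start = c(100L, 0L), bin_end = c(200L, 100L),
    direction = c("hypo", "hyper")
  )
  outm <- merge_flagged(mixed, mode = "bin")
  expect_equal(nrow(outm), 2)
})

test_that("DMR-expression correlation is rank-based and sign-faithful", {
  expect_equal(correlate_dmr_expression(c(1, 2, 3), c(9, 4, 1)), -1)
  expect_equal(correlate_dmr_expression(1:5, (1:5)^3), 1)
  expect_warning(out <- correlate_dmr_expression(rep(1, 5), 1:5), "Constant")
  expect_true(is.na(out))
  expect_error(correlate_dmr_expression(1:2, 1:2), "at least 3")
  set.seed(34)
  x <- rnorm(50)
  y <- rnorm(50)
  expect_equal(correlate_dmr_expression(x, y), oracle_spearman(x, y))
})
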