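test_that("cohort generation is deterministic and conserves sample counts", {
  spec <- cohort_spec(n_per_group = 5, seed = 7)
  a <- gen_expression_cohort(spec)
  b <- gen_expression_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$samples), 5 * length(spec$groups))
  expect_equal(
    nrow(a$intensities),
    nrow(a$samples) * nrow(a$map)
  )
})

test_that("zero-noise cohorts recover planted group means exactly", {
  spec <- cohort_spec(n_per_group = 3, sigma = 0, probesets_per_isoform = 1,
                      ref_shift_sd = 0, seed = 1)
  co <- gen_expression_cohort(spec)
  prof <- summarize_isoforms(co$intensities, co$map)
  expected <- planted_profile(spec)
  joined <- dplyr::inner_join(
    dplyr::inner_join(prof, co$samples, by = "sample_id"),
    expected, by = c("group", "feature")
  )
  expect_gt(nrow(joined), 0)
  expect_equal(joined$expression, joined$expected_expression, tolerance = 1e-12)
})

test_that("planted NAP-PCa shift is recovered within the CLT bound", {
  means <- default_isoform_means()
  means["PDE4D5", ] <- c(5, 3, 3, 3) # planted -2 log2 shift NAP -> PCa
  spec <- cohort_spec(n_per_group = 50, sigma = 0.5, isoform_means = means,
                      probesets_per_isoform = 1, seed = 42)
  co <- gen_expression_cohort(spec)
  prof <- summarize_isoforms(co$intensities, co$map) %>%
    dplyr::inner_join(co$samples, by = "sample_id") %>%
    dplyr::filter(.data$feature == "PDE4D5")
  diff <- mean(prof$expression[prof$group == "PCa"]) -
    mean(prof$expression[prof$group == "NAP"])
  # mean difference of 50-vs-50 samples with sd 0.5: allow 3 standard errors
  expect_lt(abs(diff - (-2)), 3 * 0.5 / sqrt(50) * sqrt(2))
})

test_that("invalid cohort parameters raise errors naming the field", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(sigma = -1), "sigma")
  expect_error(cohort_spec(probesets_per_isoform = 0), "probesets_per_isoform")
})

test_that("peak placement respects rates and chromosome bounds", {
  cs <- tibble::tibble(chrom = "c1", size = 50000000L)
  tl <- tibble::tibble(chrom = "c1", start = 10000000L, end = 11500000L)
  # background 0: every peak must fall inside the target
  sc0 <- gen_peaks_and_loci(enrichment_spec(
    cs, tl, background_rate = 0, target_rate = 20,
    region_len = 1500000L, n_decoys = 10, seed = 3
  ))
  expect_gt(nrow(sc0$peaks), 0)
  expect_true(all(sc0$peaks$start >= tl$start & sc0$peaks$start < tl$end))
  # equal rates: target count within the Poisson 99% band
  sc1 <- gen_peaks_and_loci(enrichment_spec(
    cs, tl, background_rate = 40, target_rate = 40,
    region_len = 1500000L, n_decoys = 10, seed = 5
  ))
  expect_true(all(sc1$peaks$end <= cs$size))
  lambda <- 40 * 1.5
  n_target <- count_overlaps(sc1$peaks, tl)$n_peaks
  expect_gte(n_target, qpois(0.005, lambda))
  expect_lte(n_target, qpois(0.995, lambda))
  # loci are pairwise non-overlapping
  loci <- sc1$loci
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1, loci$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
})

test_that("empty chromosome table yields an empty peak scenario", {
  sc <- gen_peaks_and_loci(enrichment_spec(
    tibble::tibble(chrom = character(), size = integer()),
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    seed = 1
  ))
  expect_equal(nrow(sc$peaks), 0)
  expect_equal(nrow(sc$loci), 0)
})

test_that("methylation generator plants the requested fraction difference", {
  # delta = 0: no expected group difference anywhere
  tr0 <- gen_methylation(methyl_spec(n_positions = 50, delta = 0, depth = 50,
                                     n_per_group = 20, seed = 2))
  f0 <- tr0 %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(f = sum(c_count) / sum(c_count + t_count))
  expect_lt(abs(diff(f0$f)), 0.02)
  # delta = 0.5 at depth 100, n = 20/group: difference within binomial SE bound
  tr <- gen_methylation(methyl_spec(
    n_positions = 100, dmr_interval = c(0, 5000), delta = 0.5, depth = 100,
    n_per_group = 20, p0 = 0.2, step = 50, seed = 9
  ))
  f <- tr %>%
    dplyr::filter(pos < 5000) %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(f = sum(c_count) / sum(c_count + t_count))
  d <- f$f[f$group == "case"] - f$f[f$group == "control"]
  expect_lt(abs(d - 0.5), 0.1)
})

test_that("a DMR interval outside the measured range warns and changes nothing", {
  spec_out <- methyl_spec(n_positions = 10, dmr_interval = c(1e6, 2e6),
                          delta = 0.5, seed = 4)
  expect_warning(tr <- gen_methylation(spec_out), "unmodified")
  f <- tr %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(f = sum(c_count) / sum(c_count + t_count))
  expect_lt(abs(diff(f$f)), 0.05)
})

test_that("survival generator honours the proportional-hazards model", {
  set.seed(1)
  scores <- rnorm(500)
  # null coefficient: Cox recovers ~0
  rec0 <- gen_survival(scores, hazard_coef = 0, censor_rate = 0.01, seed = 11)
  fit0 <- cox_fit(rec0)
  expect_lt(abs(fit0$terms$estimate[1]), 2 * fit0$terms$std_error[1])
  # planted coefficient 1 recovered within +/- 0.3
  rec1 <- gen_survival(scores, hazard_coef = 1, censor_rate = 0.005, seed = 12)
  fit1 <- cox_fit(rec1)
  expect_lt(abs(fit1$terms$estimate[1] - 1), 0.3)
  # extreme censoring: essentially everything censored
  rec2 <- gen_survival(scores, hazard_coef = 0, censor_rate = 1e6,
                       baseline_rate = 1e-4, seed = 13)
  expect_equal(sum(rec2$event), 0)
})
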