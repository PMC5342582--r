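make_matrix <- function(values) {
  # values: named list gene -> named numeric probeset vector, one sample
  purrr::imap_dfr(values, function(v, gene) {
    tibble::tibble(sample_id = "s1", probeset_id = names(v), intensity = v)
  })
}

test_that("reference factor is the mean of per-gene probeset means", {
  ints <- tibble::tibble(
    sample_id = "s1",
    probeset_id = c("a1", "a2", "b1"),
    intensity = c(7, 9, 9) # gene A mean 8, gene B mean 9 -> factor 8.5
  )
  map <- tibble::tibble(
    feature = c("A", "A", "B"), role = "reference",
    probeset_id = c("a1", "a2", "b1")
  )
  expect_equal(reference_factor(ints, map)$ref_factor, 8.5)
  # single gene, single probeset: identity
  expect_equal(
    reference_factor(ints[3, ], map[3, ])$ref_factor, 9
  )
  # two-level nesting differs from the flat probeset mean by construction
  expect_false(isTRUE(all.equal(8.5, mean(ints$intensity))))
})

test_that("reference factor matches a nested-mean brute force on random data", {
  set.seed(3)
  genes <- paste0("G", 1:5)
  map <- purrr::map_dfr(genes, function(g) {
    tibble::tibble(feature = g, role = "reference",
                   probeset_id = paste0(g, "_", 1:3))
  })
  ints <- tidyr::expand_grid(sample_id = paste0("s", 1:4),
                             probeset_id = map$probeset_id) %>%
    dplyr::mutate(intensity = rnorm(dplyr::n(), 8, 1))
  got <- reference_factor(ints, map)
  for (s in unique(ints$sample_id)) {
    gene_means <- vapply(genes, function(g) {
      ps <- map$probeset_id[map$feature == g]
      mean(ints$intensity[ints$sample_id == s & ints$probeset_id %in% ps])
    }, numeric(1))
    expect_equal(got$ref_factor[got$sample_id == s], mean(gene_means))
  }
  # missing reference probeset is a data error naming the probeset
  expect_error(reference_factor(ints[ints$probeset_id != "G1_1", ], map),
               "G1_1")
})

test_that("isoform summarization averages normalized probesets", {
  ints <- tibble::tibble(
    sample_id = "s1",
    probeset_id = c("i1", "i2", "r1"),
    intensity = c(10, 12, 8.5)
  )
  map <- tibble::tibble(
    feature = c("ISO", "ISO", "REF"),
    role = c("isoform", "isoform", "reference"),
    probeset_id = c("i1", "i2", "r1")
  )
  prof <- summarize_isoforms(ints, map)
  expect_equal(prof$expression[prof$feature == "ISO"], (1.5 + 3.5) / 2)
  expect_error(summarize_isoforms(ints[-1, ], map), "i1")
})

test_that("summarization is shift-invariant and matches a two-loop oracle", {
  set.seed(8)
  co <- small_cohort(n_per_group = 3, sigma = 0.4, seed = 21)
  prof <- summarize_isoforms(co$intensities, co$map)
  # add a constant to every probeset of one sample: profile unchanged
  shifted <- co$intensities %>%
    dplyr::mutate(intensity = intensity +
                    ifelse(sample_id == sample_id[1], 3.7, 0))
  prof_shift <- summarize_isoforms(shifted, co$map)
  expect_equal(prof$expression, prof_shift$expression, tolerance = 1e-12)
  # naive two-loop recomputation
  targets <- co$map[co$map$role != "reference", ]
  refs <- co$map[co$map$role == "reference", ]
  for (s in unique(co$samples$sample_id)[1:3]) {
    sub <- co$intensities[co$intensities$sample_id == s, ]
    gene_means <- vapply(unique(refs$feature), function(g) {
      mean(sub$intensity[sub$probeset_id %in%
                           refs$probeset_id[refs$feature == g]])
    }, numeric(1))
    rf <- mean(gene_means)
    for (f in unique(targets$feature)) {
      ps <- targets$probeset_id[targets$feature == f]
      want <- mean(sub$intensity[sub$probeset_id %in% ps] - rf)
      got <- prof$expression[prof$sample_id == s & prof$feature == f]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("TPM conversion multiplies by one million and rejects negatives", {
  expect_equal(tpm_from_scaled_estimate(0), 0)
  expect_equal(tpm_from_scaled_estimate(2.5e-6), 2.5)
  expect_equal(tpm_from_scaled_estimate(1), 1e6)
  expect_error(tpm_from_scaled_estimate(-1), "non-negative")
})

test_that("qPCR normalization subtracts target Ct from the reference mean", {
  ct <- tibble::tibble(
    sample_id = "p1", location = "tumour",
    gene = c("R1", "R2", "PDE4D7"),
    ct = c(20, 22, 25)
  )
  out <- qpcr_normalize(ct, "PDE4D7", reference_genes = c("R1", "R2"))
  expect_equal(out$normalized, 21 - 25)
  # target at the reference mean scores zero
  ct2 <- ct
  ct2$ct[3] <- 21
  expect_equal(
    qpcr_normalize(ct2, "PDE4D7", reference_genes = c("R1", "R2"))$normalized, 0
  )
  # missing Ct names the sample, location and gene
  expect_error(qpcr_normalize(ct[-1, ], "PDE4D7",
                              reference_genes = c("R1", "R2")),
               "p1.*tumour.*R1")
})

test_that("qPCR normalization matches the hand formula and is antitone in Ct", {
  set.seed(5)
  refs <- c("ACTB", "HPRT1", "TUBA1B", "POLR2A", "PUM1", "TBP")
  ct <- tidyr::expand_grid(
    sample_id = paste0("p", 1:3),
    location = c("tumour", "edge"),
    gene = c(refs, "PDE4D5")
  ) %>% dplyr::mutate(ct = runif(dplyr::n(), 18, 30))
  out <- qpcr_normalize(ct, "PDE4D5")
  for (i in seq_len(nrow(out))) {
    sub <- ct[ct$sample_id == out$sample_id[i] &
                ct$location == out$location[i], ]
    expect_equal(out$normalized[i],
                 mean(sub$ct[sub$gene %in% refs]) -
                   sub$ct[sub$gene == "PDE4D5"])
  }
  # raising target Ct lowers normalized expression
  ct_hi <- ct %>%
    dplyr::mutate(ct = ct + ifelse(gene == "PDE4D5", 2, 0))
  out_hi <- qpcr_normalize(ct_hi, "PDE4D5")
  expect_true(all(out_hi$normalized < out$normalized))
})

test_that("relative expression is 2^delta with the baseline at exactly 1", {
  norm <- tibble::tibble(
    sample_id = "p1",
    location = c("tumour", "edge", "5mm", "10mm"),
    normalized = c(2, 2, 3, -2)
  )
  rel <- relative_to_location(norm, "tumour")
  expect_equal(rel$relative[rel$location == "tumour"], 1)
  expect_equal(rel$relative[rel$location == "edge"], 1)
  expect_equal(rel$relative[rel$location == "5mm"], 2)
  expect_equal(rel$relative[rel$location == "10mm"], 0.0625)
  expect_error(relative_to_location(norm[-1, ], "tumour"), "p1")
})

test_that("biopsy summaries report the mean and SEM per location", {
  rel <- tibble::tibble(
    sample_id = c("a", "b", "c", "a", "b"),
    location = c("t", "t", "t", "e", "e"),
    relative = c(1, 1, 1, 1, 3)
  )
  out <- summarize_biopsy_profile(rel)
  expect_equal(out$mean[out$location == "t"], 1)
  expect_equal(out$sem[out$location == "t"], 0)
  expect_equal(out$mean[out$location == "e"], 2)
  expect_equal(out$sem[out$location == "e"], 1) # sd sqrt(2) / sqrt(2)
  expect_error(
    summarize_biopsy_profile(rel[c(1, 4), ]),
    "fewer than 2"
  )
  # matches the textbook formula on simulated patients
  set.seed(2)
  sim <- tibble::tibble(
    sample_id = paste0("p", 1:18), location = "5mm",
    relative = rlnorm(18)
  )
  out_sim <- summarize_biopsy_profile(sim)
  expect_equal(out_sim$mean, mean(sim$relative))
  expect_equal(out_sim$sem, sd(sim$relative) / sqrt(18))
})
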