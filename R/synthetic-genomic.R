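#' Specify a synthetic peak-enrichment scenario
#'
#' Parameters for [gen_peaks_and_loci()]: a genome of chromosome sizes, a
#' target locus, a genome-wide background peak rate and an elevated rate
#' inside the target. Peaks are placed by a homogeneous Poisson process
#' at `background_rate` everywhere plus an independent Poisson excess of
#' `target_rate - background_rate` inside the target locus.
#'
#' @param chrom_sizes tibble with columns `chrom`, `size` (bp).
#' @param target_locus one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param background_rate peaks per Mb genome-wide (>= 0).
#' @param target_rate peaks per Mb inside the target (>= background_rate).
#' @param region_len length of decoy loci in bp (default 1.5 Mb, the size
#'   of the PDE4D gene locus).
#' @param n_decoys number of decoy loci for locus-background nulls.
#' @param peak_width width of generated peaks in bp.
#' @param seed RNG seed.
#' @return an object of class `enrichment_spec`.
#' @export
enrichment_spec <- function(chrom_sizes,
                            target_locus,
                            background_rate = 1,
                            target_rate = 10,
                            region_len = 1500000,
                            n_decoys = 2000,
                            peak_width = 300,
                            seed = 1L) {
  check_columns(chrom_sizes, c("chrom", "size"), "chrom_sizes")
  if (nrow(chrom_sizes) > 0L) {
    check_columns(target_locus, c("chrom", "start", "end"), "target_locus")
    if (nrow(target_locus) != 1L) {
      stop_parameter("`target_locus` must have exactly one row.")
    }
    csize <- chrom_sizes$size[match(target_locus$chrom, chrom_sizes$chrom)]
    if (is.na(csize) || target_locus$start < 0 ||
        target_locus$end <= target_locus$start || target_locus$end > csize) {
      stop_parameter("`target_locus` must lie within its chromosome.")
    }
  }
  check_number(background_rate, "background_rate", min = 0)
  check_number(target_rate, "target_rate", min = background_rate)
  region_len <- check_count(region_len, "region_len", min = 1L)
  n_decoys <- check_count(n_decoys, "n_decoys", min = 0L)
  peak_width <- check_count(peak_width, "peak_width", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      chrom_sizes = as_tibble(chrom_sizes), target_locus = as_tibble(target_locus),
      background_rate = background_rate, target_rate = target_rate,
      region_len = region_len, n_decoys = n_decoys,
      peak_width = peak_width, seed = seed
    ),
    class = "enrichment_spec"
  )
}

empty_intervals <- function(extra = character()) {
  out <- tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character()
  )
  out
}

#' Generate synthetic transcription-factor peaks and a locus catalog
#'
#' Peaks are dropped by a Poisson process: `background_rate` per Mb on
#' every chromosome plus an excess of `target_rate - background_rate` per
#' Mb inside the target locus. The locus catalog holds the target plus
#' `n_decoys` pairwise non-overlapping decoy loci of `region_len` bp that
#' avoid the target, so decoy peak counts are draws from the background
#' null. All coordinates are 0-based half-open.
#'
#' @param spec an [enrichment_spec()].
#' @return list of class `peak_scenario` with tibbles `peaks` and `loci`
#'   (the target locus is named `"TARGET"`).
#' @export
gen_peaks_and_loci <- function(spec) {
  if (!inherits(spec, "enrichment_spec")) {
    stop_parameter("`spec` must be created with enrichment_spec().")
  }
  set.seed(spec$seed)
  cs <- spec$chrom_sizes
  if (nrow(cs) == 0L) {
    return(structure(list(peaks = empty_intervals(), loci = empty_intervals()),
                     class = "peak_scenario"))
  }
  w <- spec$peak_width
  peaks <- purrr::pmap_dfr(cs, function(chrom, size) {
    n_bg <- rpois(1L, spec$background_rate * size / 1e6)
    starts <- if (n_bg > 0) floor(runif(n_bg, 0, max(1, size - w))) else integer()
    tibble(chrom = chrom, start = as.integer(starts))
  })
  tl <- spec$target_locus
  excess <- spec$target_rate - spec$background_rate
  if (excess > 0) {
    len <- tl$end - tl$start
    n_t <- rpois(1L, excess * len / 1e6)
    if (n_t > 0) {
      peaks <- bind_rows(peaks, tibble(
        chrom = tl$chrom,
        start = as.integer(tl$start + floor(runif(n_t, 0, max(1, len - w))))
      ))
    }
  }
  peaks <- peaks %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(
      end = .data$start + w,
      name = sprintf("peak%05d", dplyr::row_number()),
      score = 0, strand = "."
    )

  loci <- tibble(
    chrom = tl$chrom, start = as.integer(tl$start), end = as.integer(tl$end),
    name = "TARGET", score = 0, strand = "."
  )
  if (spec$n_decoys > 0L) {
    decoys <- place_decoys(cs, tl, spec$region_len, spec$n_decoys)
    loci <- bind_rows(loci, decoys)
  }
  structure(list(peaks = peaks, loci = loci), class = "peak_scenario")
}

# Non-overlapping decoy placement: tile each chromosome into
# region_len-sized slots, drop slots touching the target locus, and
# sample the requested number of slots without replacement. Slot-aligned
# windows carry exactly the background Poisson count distribution.
place_decoys <- function(chrom_sizes, target, region_len, n_decoys) {
  usable <- chrom_sizes %>% filter(.data$size >= region_len)
  if (nrow(usable) == 0L) {
    stop_parameter("No chromosome can hold a decoy of `region_len` bp.")
  }
  slots <- purrr::pmap_dfr(usable, function(chrom, size) {
    n_slots <- floor(size / region_len)
    tibble(chrom = chrom,
           start = as.integer(region_len * (seq_len(n_slots) - 1L)))
  }) %>%
    mutate(end = .data$start + as.integer(region_len)) %>%
    filter(!(.data$chrom == target$chrom &
               .data$start < target$end & target$start < .data$end))
  if (nrow(slots) < n_decoys) {
    stop_parameter(sprintf(
      "Genome too small for %d non-overlapping decoys of %d bp (only %d slots available).",
      n_decoys, region_len, nrow(slots)
    ))
  }
  slots[sort(sample.int(nrow(slots), n_decoys)), ] %>%
    mutate(name = sprintf("decoy%05d", dplyr::row_number()),
           score = 0, strand = ".") %>%
    arrange(.data$chrom, .data$start)
}

#' Specify a synthetic methylation experiment
#'
#' Parameters for [gen_methylation()]: bisulfite-style C/T counts at
#' evenly spaced positions for a control and a case group, with a planted
#' hyper-methylated interval in the case group.
#'
#' @param n_positions number of measured positions.
#' @param dmr_interval length-2 numeric, planted interval (bp, 0-based
#'   half-open) where case methylation is elevated.
#' @param delta planted methylation-fraction increase in (0, 1].
#' @param depth mean read depth per position (Poisson, >= 1).
#' @param n_per_group samples per group (>= 2).
#' @param p0 baseline methylation fraction.
#' @param chrom chromosome label.
#' @param start coordinate of the first position.
#' @param step spacing between consecutive positions (bp).
#' @param seed RNG seed.
#' @return an object of class `methyl_spec`.
#' @export
methyl_spec <- function(n_positions = 200,
                        dmr_interval = c(2000, 4000),
                        delta = 0.4,
                        depth = 30,
                        n_per_group = 10,
                        p0 = 0.2,
                        chrom = "chr5",
                        start = 0,
                        step = 50,
                        seed = 1L) {
  n_positions <- check_count(n_positions, "n_positions", min = 1L)
  if (length(dmr_interval) != 2L || dmr_interval[2] <= dmr_interval[1]) {
    stop_parameter("`dmr_interval` must be c(start, end) with start < end.")
  }
  check_number(delta, "delta", min = 0, max = 1, allow_min = TRUE)
  if (delta > 0 && p0 + delta > 1) {
    stop_parameter("`p0` + `delta` must not exceed 1.")
  }
  check_number(depth, "depth", min = 1)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  check_number(p0, "p0", min = 0, max = 1)
  step <- check_count(step, "step", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_positions = n_positions, dmr_interval = dmr_interval, delta = delta,
      depth = depth, n_per_group = n_per_group, p0 = p0, chrom = chrom,
      start = start, step = step, seed = seed
    ),
    class = "methyl_spec"
  )
}

#' Generate synthetic bisulfite methylation tracks for two groups
#'
#' Per position and sample, coverage is Poisson(`depth`) and methylated
#' base calls are Binomial(coverage, p), with p = `p0` everywhere except
#' inside `dmr_interval` for the case group, where p = `p0 + delta`.
#' Groups are labelled `"control"` and `"case"`.
#'
#' @param spec a [methyl_spec()].
#' @return tibble (chrom, pos, sample_id, group, c_count, t_count).
#' @export
gen_methylation <- function(spec) {
  if (!inherits(spec, "methyl_spec")) {
    stop_parameter("`spec` must be created with methyl_spec().")
  }
  set.seed(spec$seed)
  pos <- spec$start + spec$step * (seq_len(spec$n_positions) - 1L)
  in_dmr <- pos >= spec$dmr_interval[1] & pos < spec$dmr_interval[2]
  if (spec$delta > 0 && !any(in_dmr)) {
    warn("`dmr_interval` covers no measured position; track left unmodified.")
  }
  samples <- tibble(
    sample_id = sprintf("M%03d", seq_len(2L * spec$n_per_group)),
    group = rep(c("control", "case"), each = spec$n_per_group)
  )
  grid <- tidyr::expand_grid(tibble(chrom = spec$chrom, pos = pos), samples)
  elevated <- grid$group == "case" &
    grid$pos >= spec$dmr_interval[1] & grid$pos < spec$dmr_interval[2]
  p <- spec$p0 + ifelse(elevated, spec$delta, 0)
  cov <- rpois(nrow(grid), spec$depth)
  c_count <- rbinom(nrow(grid), cov, p)
  grid %>%
    mutate(c_count = c_count, t_count = cov - c_count) %>%
    select("chrom", "pos", "sample_id", "group", "c_count", "t_count")
}

#' Generate survival records under exponential proportional hazards
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(hazard_coef * score)`; censoring times are
#' independent exponential with rate `censor_rate` (0 disables
#' censoring). Observed time is the minimum; the event flag is 1 when the
#' event precedes censoring.
#'
#' @param scores numeric vector or tibble with `sample_id`, `score`.
#' @param hazard_coef log-hazard per unit score.
#' @param censor_rate exponential censoring rate (>= 0).
#' @param baseline_rate baseline hazard (events per month).
#' @param seed RNG seed.
#' @return tibble (sample_id, score, time, event).
#' @export
gen_survival <- function(scores, hazard_coef, censor_rate = 0.02,
                         baseline_rate = 0.02, seed = 1L) {
  if (is.data.frame(scores)) {
    check_columns(scores, c("sample_id", "score"), "scores")
    ids <- scores$sample_id
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    ids <- sprintf("S%04d", seq_along(s))
  }
  if (length(s) < 1L || any(!is.finite(s))) {
    stop_parameter("`scores` must be non-empty and finite.")
  }
  check_number(hazard_coef, "hazard_coef")
  check_number(censor_rate, "censor_rate", min = 0)
  check_number(baseline_rate, "baseline_rate", min = 0, allow_min = FALSE)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  t_event <- rexp(length(s), rate = baseline_rate * exp(hazard_coef * s))
  t_cens <- if (censor_rate > 0) rexp(length(s), rate = censor_rate) else Inf
  tibble(
    sample_id = ids,
    score = s,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}
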