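#' Bin a methylation read-count track
#'
#' Sums per-sample read counts into fixed-width genomic bins: a count at
#' position p falls into bin `floor(p / bin_size)`, i.e. the half-open
#' interval `[k * bin_size, (k + 1) * bin_size)`.
#'
#' @param track tibble with columns `pos`, `sample_id` and `count`
#'   (plus optional `chrom`, `group` carried through).
#' @param bin_size bin width in nt (default 100).
#' @return tibble (bin, bin_start, bin_end, sample_id, [group,] count).
#' @export
bin_track <- function(track, bin_size = 100L) {
  check_columns(track, c("pos", "sample_id", "count"), "track")
  bin_size <- check_count(bin_size, "bin_size", min = 1L)
  keys <- intersect(c("group"), names(track))
  track %>%
    mutate(bin = as.integer(floor(.data$pos / bin_size))) %>%
    group_by(across(all_of(c("bin", "sample_id", keys)))) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(
      bin_start = .data$bin * bin_size,
      bin_end = (.data$bin + 1L) * bin_size
    ) %>%
    select(all_of(c("bin", "bin_start", "bin_end", "sample_id", keys, "count")))
}

#' Methylation fraction from bisulfite base calls
#'
#' `#C / (#C + #T)` per position. Positions with zero coverage are
#' undefined and returned as `NA` with a note.
#'
#' @param c_count,t_count non-negative base-call counts (vectorized).
#' @return numeric fraction(s) in `[0, 1]`, `NA` where coverage is zero.
#' @export
methylation_fraction <- function(c_count, t_count) {
  if (any(c_count < 0, na.rm = TRUE) || any(t_count < 0, na.rm = TRUE)) {
    stop_parameter("Base-call counts must be non-negative.")
  }
  total <- c_count + t_count
  out <- ifelse(total > 0, c_count / total, NA_real_)
  if (any(total == 0, na.rm = TRUE)) {
    warn(sprintf(
      "%d position(s) with zero coverage skipped (fraction undefined).",
      sum(total == 0, na.rm = TRUE)
    ))
  }
  out
}

group_roles <- function(groups, case, control, what = "track") {
  lv <- unique(groups)
  if (!case %in% lv || !control %in% lv) {
    stop_parameter(sprintf(
      "`case` ('%s') and `control` ('%s') must both appear in `%s` groups.",
      case, control, what
    ))
  }
}

#' Differential methylation of binned read counts
#'
#' MeDIP-style two-group test per bin: group-summed counts are compared
#' as competing Poisson rates conditioned on their total, i.e. an exact
#' two-sided binomial test of the case share against the library-size
#' expectation. P-values are Bonferroni-adjusted over the bins actually
#' tested (non-zero total); bins with adjusted p below `alpha` are
#' flagged. Direction is hyper when the case rate (per library size)
#' exceeds the control rate.
#'
#' @param binned tibble from [bin_track()] with a `group` column.
#' @param case,control group labels.
#' @param alpha adjusted-p threshold (default 0.01).
#' @return tibble (bin, bin_start, bin_end, sum_case, sum_control,
#'   p_value, p_adj, direction, flagged).
#' @export
diff_bins_counts <- function(binned, case = "case", control = "control",
                             alpha = 0.01) {
  check_columns(binned, c("bin", "bin_start", "bin_end", "sample_id",
                          "group", "count"), "binned")
  group_roles(binned$group, case, control, "binned")
  check_number(alpha, "alpha", min = 0, max = 1)
  n_case <- binned %>% filter(.data$group == case) %>% distinct(.data$sample_id) %>% nrow()
  n_ctrl <- binned %>% filter(.data$group == control) %>% distinct(.data$sample_id) %>% nrow()
  if (n_case < 2L || n_ctrl < 2L) {
    stop_parameter("Both groups need at least 2 samples.")
  }
  sums <- binned %>%
    filter(.data$group %in% c(case, control)) %>%
    group_by(.data$bin, .data$bin_start, .data$bin_end, .data$group) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "count",
                       values_fill = 0L) %>%
    rename(sum_case = all_of(case), sum_control = all_of(control))
  lib_case <- sum(sums$sum_case)
  lib_ctrl <- sum(sums$sum_control)
  if (lib_case + lib_ctrl == 0) {
    stop_data("All counts are zero; nothing to test.")
  }
  p_share <- lib_case / (lib_case + lib_ctrl)
  total <- sums$sum_case + sums$sum_control
  pvals <- vapply(seq_len(nrow(sums)), function(i) {
    if (total[i] == 0L) return(NA_real_)
    binom.test(sums$sum_case[i], total[i], p = p_share)$p.value
  }, numeric(1))
  tested <- !is.na(pvals)
  p_adj <- rep(NA_real_, length(pvals))
  p_adj[tested] <- pmin(1, pvals[tested] * sum(tested)) # Bonferroni over tested bins
  sums %>%
    mutate(
      p_value = pvals,
      p_adj = p_adj,
      direction = ifelse(.data$sum_case / max(lib_case, 1) >=
                           .data$sum_control / max(lib_ctrl, 1),
                         "hyper", "hypo"),
      flagged = !is.na(p_adj) & p_adj < alpha
    ) %>%
    arrange(.data$bin)
}

#' Differential methylation of per-position fractions
#'
#' Bisulfite-style two-group comparison: per position, a two-sided
#' Wilcoxon rank test of per-sample methylation fractions, followed by
#' Benjamini-Hochberg FDR adjustment; positions with q below `fdr` are
#' flagged. Positions that are constant across both groups get p = 1.
#'
#' @param track tibble (pos, sample_id, group, c_count, t_count), e.g.
#'   from [gen_methylation()].
#' @param case,control group labels.
#' @param fdr q-value threshold (default 0.05).
#' @return tibble (pos, mean_case, mean_control, p_value, q_value,
#'   direction, flagged).
#' @export
diff_positions_fraction <- function(track, case = "case", control = "control",
                                    fdr = 0.05) {
  check_columns(track, c("pos", "sample_id", "group", "c_count", "t_count"),
                "track")
  group_roles(track$group, case, control)
  check_number(fdr, "fdr", min = 0, max = 1)
  frac <- track %>%
    filter(.data$group %in% c(case, control)) %>%
    mutate(fraction = suppressWarnings(
      methylation_fraction(.data$c_count, .data$t_count)
    )) %>%
    filter(!is.na(.data$fraction))
  by_group <- function(pos_df, g) pos_df$fraction[pos_df$group == g]
  per_pos <- frac %>%
    group_by(.data$pos) %>%
    dplyr::group_map(function(df, key) {
      a <- by_group(df, case)
      b <- by_group(df, control)
      if (length(a) < 2L || length(b) < 2L) {
        stop_parameter("Both groups need at least 2 covered samples per position.")
      }
      p <- if (length(unique(c(a, b))) == 1L) 1 else suppressWarnings(
        wilcox.test(a, b, exact = FALSE)$p.value
      )
      tibble(
        pos = key$pos, mean_case = mean(a), mean_control = mean(b), p_value = p
      )
    }) %>%
    bind_rows()
  per_pos %>%
    mutate(
      q_value = p.adjust(.data$p_value, method = "BH"),
      direction = ifelse(.data$mean_case >= .data$mean_control, "hyper", "hypo"),
      flagged = .data$q_value < fdr
    ) %>%
    arrange(.data$pos)
}

#' Differential methylation regions from array beta values
#'
#' Bump-style region calling: probes whose absolute group mean difference
#' (case minus control) reaches `cutoff` are candidates; runs of
#' consecutive candidate probes with the same direction are merged into
#' regions scored by the sum of their differences. Region significance
#' is assessed by permuting group labels `n_perm` times and comparing
#' each observed absolute region score with the permutation distribution
#' of the genome-wide maximum absolute region score.
#'
#' @param betas tibble (pos, sample_id, group, beta) with beta in [0, 1].
#' @param case,control group labels.
#' @param cutoff candidate threshold on |mean difference| (default 0.15).
#' @param n_perm number of label permutations (default 100).
#' @param seed RNG seed for permutations.
#' @return tibble (start, end, n_probes, direction, score, p_value); zero
#'   rows when no probe passes the cutoff.
#' @export
diff_regions_beta <- function(betas, case = "case", control = "control",
                              cutoff = 0.15, n_perm = 100L, seed = 1L) {
  check_columns(betas, c("pos", "sample_id", "group", "beta"), "betas")
  group_roles(betas$group, case, control, "betas")
  check_number(cutoff, "cutoff", min = 0, allow_min = FALSE)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  if (any(betas$beta < 0 | betas$beta > 1)) {
    stop_data("`beta` values must lie in [0, 1].")
  }
  wide <- betas %>%
    filter(.data$group %in% c(case, control)) %>%
    tidyr::pivot_wider(id_cols = "pos", names_from = "sample_id",
                       values_from = "beta") %>%
    arrange(.data$pos)
  sample_groups <- betas %>%
    filter(.data$group %in% c(case, control)) %>%
    distinct(.data$sample_id, .data$group)
  if (sum(sample_groups$group == case) < 2L ||
      sum(sample_groups$group == control) < 2L) {
    stop_parameter("Both groups need at least 2 samples.")
  }
  mat <- as.matrix(wide[, sample_groups$sample_id, drop = FALSE])
  is_case <- sample_groups$group == case

  regions_for <- function(case_mask) {
    d <- rowMeans(mat[, case_mask, drop = FALSE]) -
      rowMeans(mat[, !case_mask, drop = FALSE])
    cand <- abs(d) >= cutoff
    if (!any(cand)) {
      return(tibble(start = integer(), end = integer(), n_probes = integer(),
                    direction = character(), score = numeric()))
    }
    sign_d <- ifelse(d >= 0, "hyper", "hypo")
    run_id <- cumsum(
      c(TRUE, diff(cand) != 0 | (sign_d[-1] != sign_d[-length(sign_d)]))
    )
    idx <- which(cand)
    tibble(pos = wide$pos[idx], d = d[idx], run = run_id[idx],
           dir = sign_d[idx]) %>%
      group_by(.data$run, .data$dir) %>%
      summarise(
        start = min(.data$pos), end = max(.data$pos) + 1L,
        n_probes = dplyr::n(), score = sum(.data$d), .groups = "drop"
      ) %>%
      select("start", "end", "n_probes", direction = "dir", "score") %>%
      arrange(.data$start)
  }

  observed <- regions_for(is_case)
  if (nrow(observed) == 0L) {
    return(observed %>% mutate(p_value = numeric()))
  }
  set.seed(seed)
  max_perm <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(is_case)
    r <- regions_for(perm)
    if (nrow(r) == 0L) 0 else max(abs(r$score))
  }, numeric(1))
  observed %>%
    mutate(p_value = vapply(abs(.data$score), function(s) {
      (1 + sum(max_perm >= s)) / (n_perm + 1)
    }, numeric(1)))
}

#' Merge flagged bins or positions into regions
#'
#' Bin mode merges flagged bins whose intervals touch exactly
#' (`bin_end == next bin_start`); position mode merges flagged positions
#' within `gap` nt of each other (default 100). Items of opposite
#' direction are never merged. Unsorted input is sorted internally.
#'
#' @param flagged tibble of flagged items: bin mode needs `bin_start`,
#'   `bin_end`, `direction`; position mode needs `pos`, `direction`.
#' @param mode `"bin"` or `"position"`.
#' @param gap maximum merge distance for position mode, in nt.
#' @return tibble (start, end, n_items, direction) of merged regions,
#'   0-based half-open (a single position p becomes `[p, p + 1)`).
#' @export
merge_flagged <- function(flagged, mode = c("bin", "position"), gap = 100L) {
  mode <- match.arg(mode)
  gap <- check_count(gap, "gap", min = 0L)
  if (mode == "bin") {
    check_columns(flagged, c("bin_start", "bin_end", "direction"), "flagged")
    items <- flagged %>%
      arrange(.data$bin_start) %>%
      mutate(start = .data$bin_start, end = .data$bin_end)
    joined <- function(prev_end, start) start <= prev_end
  } else {
    check_columns(flagged, c("pos", "direction"), "flagged")
    items <- flagged %>%
      arrange(.data$pos) %>%
      mutate(start = as.integer(.data$pos), end = as.integer(.data$pos) + 1L)
    joined <- function(prev_end, start) start - (prev_end - 1L) <= gap
  }
  if (nrow(items) == 0L) {
    return(tibble(start = integer(), end = integer(), n_items = integer(),
                  direction = character()))
  }
  out <- list()
  cur <- items[1L, c("start", "end", "direction")]
  cur$n_items <- 1L
  for (i in seq_len(nrow(items))[-1L]) {
    it <- items[i, ]
    if (it$direction == cur$direction && joined(cur$end, it$start)) {
      cur$end <- max(cur$end, it$end)
      cur$n_items <- cur$n_items + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- it[, c("start", "end", "direction")]
      cur$n_items <- 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  bind_rows(out) %>% select("start", "end", "n_items", "direction")
}

#' Spearman correlation of region methylation with isoform expression
#'
#' Rank correlation (average ranks for ties) between per-sample summary
#' methylation of a differentially methylated region and the expression
#' of its associated isoform. Hyper-methylation that silences a promoter
#' shows up as negative rho.
#'
#' @param methylation numeric per-sample methylation summary.
#' @param expression numeric per-sample isoform expression, same order.
#' @return Spearman rho; `NA` with a warning when either vector is
#'   constant (correlation undefined).
#' @export
correlate_dmr_expression <- function(methylation, expression) {
  if (length(methylation) != length(expression)) {
    stop_parameter("Inputs must be the same length.")
  }
  ok <- is.finite(methylation) & is.finite(expression)
  if (sum(ok) < 3L) {
    stop_parameter("Need at least 3 paired samples.")
  }
  m <- methylation[ok]
  e <- expression[ok]
  if (length(unique(m)) == 1L || length(unique(e)) == 1L) {
    warn("Constant input; Spearman correlation undefined (NA returned).")
    return(NA_real_)
  }
  cor(m, e, method = "spearman")
}
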