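#' Probeset map for the PDE4D isoform panel
#'
#' The HuEx exon-array probesets measuring each PDE4D isoform channel,
#' the five reference genes used as normalization panel (HPRT1, PUM1,
#' TBP, POLR2A, TUBA1B) and the auxiliary prostate markers PCA3, ERG and
#' PART1. PDE4D1 and PDE4D2 share a single probeset and are therefore
#' reported as one joint channel `"PDE4D1/2"`.
#'
#' @return tibble with columns `feature`, `role` (isoform / reference /
#'   auxiliary) and `probeset_id`.
#' @export
default_probeset_map <- function() {
  iso <- list(
    "PDE4D1/2" = "2858166",
    "PDE4D3" = c("2858290", "2858291"),
    "PDE4D4" = c("2858368", "2858369", "2858370"),
    "PDE4D5" = c("2858345", "2858346", "2858347"),
    "PDE4D6" = c("2858155", "2858156"),
    "PDE4D7" = c("2858406", "2858407", "2858408"),
    "PDE4D8" = c("2858257", "2858258"),
    "PDE4D9" = c("2858240", "2858241")
  )
  refs <- c(
    HPRT1 = "3991698", PUM1 = "2404254", TBP = "2937984",
    POLR2A = "3453732", TUBA1B = "3708704"
  )
  aux <- c(PCA3 = "3175538", ERG = "3931765", PART1 = "2811145")
  bind_rows(
    purrr::imap_dfr(iso, ~ tibble(feature = .y, role = "isoform",
                                  probeset_id = .x)),
    tibble(feature = names(refs), role = "reference", probeset_id = unname(refs)),
    tibble(feature = names(aux), role = "auxiliary", probeset_id = unname(aux))
  )
}

check_intensities <- function(intensities) {
  check_columns(intensities, c("sample_id", "probeset_id", "intensity"),
                "intensities")
  if (any(!is.finite(intensities$intensity))) {
    stop_data("`intensities` contains non-finite values.")
  }
  if (anyDuplicated(intensities[, c("sample_id", "probeset_id")])) {
    stop_data("`intensities` has duplicate (sample_id, probeset_id) rows.")
  }
  invisible(intensities)
}

check_map <- function(map) {
  check_columns(map, c("feature", "role", "probeset_id"), "map")
  if (!any(map$role == "reference")) {
    stop_data("`map` declares no reference genes.")
  }
  invisible(map)
}

#' Per-sample reference normalization factor
#'
#' For each sample, expression of each reference gene is estimated as the
#' mean log2 intensity of its probesets, and the normalization factor is
#' the mean of those per-gene estimates. The two-level nesting (probesets
#' within gene, then genes) is deliberate and differs from a flat mean
#' over all reference probesets when genes have unequal probeset counts.
#'
#' @param intensities long tibble (sample_id, probeset_id, intensity).
#' @param map probeset map as from [default_probeset_map()].
#' @return tibble (sample_id, ref_factor).
#' @export
reference_factor <- function(intensities, map) {
  check_intensities(intensities)
  check_map(map)
  refs <- map %>% filter(.data$role == "reference")
  present <- unique(intensities$probeset_id)
  missing <- setdiff(refs$probeset_id, present)
  if (length(missing) > 0L) {
    stop_data(sprintf(
      "Reference probeset(s) missing from intensities: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  intensities %>%
    inner_join(refs, by = "probeset_id") %>%
    group_by(.data$sample_id, .data$feature) %>%
    summarise(gene_expr = mean(.data$intensity), .groups = "drop") %>%
    group_by(.data$sample_id) %>%
    summarise(ref_factor = mean(.data$gene_expr), .groups = "drop")
}

#' Summarize normalized isoform expression
#'
#' Subtracts each sample's reference normalization factor (see
#' [reference_factor()]) from every probeset intensity and averages the
#' normalized probesets per isoform channel. Auxiliary genes in the map
#' are summarized the same way. The result is shift-invariant: adding a
#' constant to all probesets of a sample (references included) leaves the
#' profile unchanged.
#'
#' @inheritParams reference_factor
#' @return tibble of class `isoform_profile`
#'   (sample_id, feature, expression).
#' @export
summarize_isoforms <- function(intensities, map) {
  check_intensities(intensities)
  check_map(map)
  targets <- map %>% filter(.data$role != "reference")
  missing <- setdiff(targets$probeset_id, unique(intensities$probeset_id))
  if (length(missing) > 0L) {
    stop_data(sprintf(
      "Mapped probeset(s) missing from intensities: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  rf <- reference_factor(intensities, map)
  out <- intensities %>%
    inner_join(targets, by = "probeset_id") %>%
    inner_join(rf, by = "sample_id") %>%
    group_by(.data$sample_id, .data$feature) %>%
    summarise(expression = mean(.data$intensity - .data$ref_factor),
              .groups = "drop")
  class(out) <- c("isoform_profile", class(out))
  out
}

#' Convert an RSEM scaled estimate to transcripts per million
#'
#' @param scaled non-negative scaled-estimate value(s).
#' @return `scaled * 1e6`.
#' @export
tpm_from_scaled_estimate <- function(scaled) {
  if (!is.numeric(scaled) || any(!is.finite(scaled)) || any(scaled < 0)) {
    stop_parameter("`scaled` must be finite and non-negative.")
  }
  scaled * 1e6
}

#' Normalize qPCR Ct values against a reference-gene panel
#'
#' Computes, per (sample, biopsy location),
#' `mean(Ct(reference genes)) - Ct(target gene)`: higher values mean
#' higher target expression (the normalization is antitone in target Ct).
#'
#' @param ct_table tibble (sample_id, location, gene, ct).
#' @param target_gene gene to quantify (e.g. "PDE4D7").
#' @param reference_genes character vector of reference genes; the
#'   default is the six-gene qPCR panel.
#' @return tibble (sample_id, location, normalized).
#' @export
qpcr_normalize <- function(ct_table, target_gene,
                           reference_genes = c("ACTB", "HPRT1", "TUBA1B",
                                               "POLR2A", "PUM1", "TBP")) {
  check_columns(ct_table, c("sample_id", "location", "gene", "ct"), "ct_table")
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    stop_data("`ct` values must be finite and positive.")
  }
  units <- ct_table %>% distinct(.data$sample_id, .data$location)
  needed <- tidyr::expand_grid(units, gene = c(reference_genes, target_gene))
  missing <- needed %>%
    dplyr::anti_join(ct_table, by = c("sample_id", "location", "gene"))
  if (nrow(missing) > 0L) {
    m <- missing[1L, ]
    stop_data(sprintf(
      "Missing Ct for sample %s, location %s, gene %s (%d missing in total).",
      m$sample_id, m$location, m$gene, nrow(missing)
    ))
  }
  refs <- ct_table %>%
    filter(.data$gene %in% reference_genes) %>%
    group_by(.data$sample_id, .data$location) %>%
    summarise(ref_mean = mean(.data$ct), .groups = "drop")
  ct_table %>%
    filter(.data$gene == target_gene) %>%
    inner_join(refs, by = c("sample_id", "location")) %>%
    mutate(normalized = .data$ref_mean - .data$ct) %>%
    select("sample_id", "location", "normalized")
}

#' Express biopsy values relative to a baseline location
#'
#' Converts normalized log2-scale values to linear fold change relative
#' to the baseline biopsy location of the same patient:
#' `2^(normalized - normalized_baseline)`. The baseline location maps to
#' exactly 1.
#'
#' @param normalized tibble (sample_id, location, normalized), as from
#'   [qpcr_normalize()].
#' @param baseline_location location used as the per-patient reference
#'   (the within-tumour biopsy in the assay design).
#' @return tibble (sample_id, location, relative).
#' @export
relative_to_location <- function(normalized, baseline_location = "tumour") {
  check_columns(normalized, c("sample_id", "location", "normalized"),
                "normalized")
  base <- normalized %>%
    filter(.data$location == baseline_location) %>%
    select("sample_id", baseline = "normalized")
  absent <- setdiff(unique(normalized$sample_id), base$sample_id)
  if (length(absent) > 0L) {
    stop_data(sprintf(
      "Baseline location '%s' absent for sample(s): %s.",
      baseline_location, paste(absent, collapse = ", ")
    ))
  }
  normalized %>%
    inner_join(base, by = "sample_id") %>%
    mutate(relative = 2^(.data$normalized - .data$baseline)) %>%
    select("sample_id", "location", "relative")
}

#' Mean and standard error of relative expression per biopsy location
#'
#' @param relative tibble (sample_id, location, relative), as from
#'   [relative_to_location()].
#' @return tibble (location, n, mean, sem) with sem = sd / sqrt(n).
#' @export
summarize_biopsy_profile <- function(relative) {
  check_columns(relative, c("sample_id", "location", "relative"), "relative")
  out <- relative %>%
    group_by(.data$location) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$relative),
      sem = sd(.data$relative) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  if (any(out$n < 2L)) {
    bad <- out$location[out$n < 2L]
    stop_data(sprintf(
      "SEM undefined: fewer than 2 patients at location(s) %s.",
      paste(bad, collapse = ", ")
    ))
  }
  out
}
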