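#' Specify a synthetic expression cohort
#'
#' Builds the parameter object for [gen_expression_cohort()]. The defaults
#' describe a four-condition prostate cohort (normal adjacent prostate,
#' primary tumour, castration-resistant disease, metastasis) whose planted
#' isoform shifts follow the qualitative ordering observed for PDE4D:
#' PDE4D7 up in primary tumours and down again with progression, PDE4D5
#' and PDE4D9 monotonically down, and the short PDE4D1/2 channel flat.
#'
#' @param n_per_group samples per condition group (>= 2).
#' @param groups ordered character vector of condition labels.
#' @param isoform_means numeric matrix of mean log2 probeset intensities,
#'   rows = isoform channels, columns = `groups`.
#' @param sigma within-group standard deviation of probeset noise, log2
#'   units (>= 0; 0 gives the deterministic zero-noise limit).
#' @param seed RNG seed; equal seeds give byte-identical cohorts.
#' @param n_ref_genes number of reference (normalization) genes.
#' @param probesets_per_isoform probesets measuring each channel (>= 1).
#' @param ref_shift_sd standard deviation of the per-sample global shift
#'   added to every probeset of a sample (what reference normalization
#'   must remove).
#' @param erg_fraction probability that a tumour-derived sample carries an
#'   ERG-fusion-like ERG upshift.
#' @param erg_shift size of the ERG upshift in log2 units.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 50,
                        groups = c("NAP", "PCa", "CRPC", "metastasis"),
                        isoform_means = default_isoform_means(groups),
                        sigma = 0.5,
                        seed = 1L,
                        n_ref_genes = 5,
                        probesets_per_isoform = 3,
                        ref_shift_sd = 1,
                        erg_fraction = 0.5,
                        erg_shift = 3) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  if (!is.character(groups) || length(groups) < 1L || anyDuplicated(groups)) {
    stop_parameter("`groups` must be distinct, non-empty labels.")
  }
  if (!is.matrix(isoform_means) || is.null(rownames(isoform_means))) {
    stop_parameter("`isoform_means` must be a matrix with isoform rownames.")
  }
  if (!identical(colnames(isoform_means), groups)) {
    stop_parameter("`isoform_means` columns must match `groups` exactly.")
  }
  check_number(sigma, "sigma", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  n_ref_genes <- check_count(n_ref_genes, "n_ref_genes", min = 1L)
  probesets_per_isoform <- check_count(probesets_per_isoform,
                                       "probesets_per_isoform", min = 1L)
  check_number(ref_shift_sd, "ref_shift_sd", min = 0)
  check_number(erg_fraction, "erg_fraction", min = 0, max = 1)
  check_number(erg_shift, "erg_shift")
  structure(
    list(
      n_per_group = n_per_group, groups = groups,
      isoform_means = isoform_means, sigma = sigma, seed = seed,
      n_ref_genes = n_ref_genes,
      probesets_per_isoform = probesets_per_isoform,
      ref_shift_sd = ref_shift_sd, erg_fraction = erg_fraction,
      erg_shift = erg_shift
    ),
    class = "cohort_spec"
  )
}

#' Default planted isoform group means
#'
#' Mean log2 intensities per isoform channel and condition group. The
#' shape (not the magnitudes, which are free configuration) encodes the
#' observed switching pattern: the diagnostic contrast D7 - D5 separates
#' tumour from benign tissue, and long-isoform loss with progression
#' drives the prognostic contrast.
#'
#' @param groups condition labels; defaults require the four standard ones.
#' @return matrix with rows PDE4D1/2, PDE4D5, PDE4D7, PDE4D9.
#' @export
default_isoform_means <- function(groups = c("NAP", "PCa", "CRPC", "metastasis")) {
  base <- matrix(
    c(
      5.0, 5.0, 5.0, 5.0,   # PDE4D1/2: stable short isoforms
      6.0, 5.0, 4.0, 3.5,   # PDE4D5: monotone loss
      5.0, 6.5, 4.5, 4.0,   # PDE4D7: up in PCa, down with progression
      5.5, 4.7, 3.9, 3.5    # PDE4D9: monotone loss
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("PDE4D1/2", "PDE4D5", "PDE4D7", "PDE4D9"),
      c("NAP", "PCa", "CRPC", "metastasis")
    )
  )
  missing <- setdiff(groups, colnames(base))
  if (length(missing) > 0L) {
    stop_parameter(sprintf(
      "No default means for group(s) %s; supply `isoform_means`.",
      paste(missing, collapse = ", ")
    ))
  }
  base[, groups, drop = FALSE]
}

aux_gene_means <- function(groups) {
  base <- matrix(
    c(
      4.0, 6.0, 6.0, 6.0,   # PCA3: elevated in cancer tissue
      4.0, 4.0, 4.0, 4.0,   # ERG: baseline; fusion upshift added per sample
      5.0, 5.0, 5.0, 5.0    # PART1: flat
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("PCA3", "ERG", "PART1"),
      c("NAP", "PCa", "CRPC", "metastasis")
    )
  )
  present <- intersect(groups, colnames(base))
  out <- matrix(rep(base[, "NAP"], length(groups)),
                nrow = 3,
                dimnames = list(rownames(base), groups))
  out[, present] <- base[, present]
  out
}

ref_gene_means <- function(n_ref_genes) {
  setNames(8 + 0.25 * (seq_len(n_ref_genes) - (n_ref_genes + 1) / 2),
           sprintf("REF%02d", seq_len(n_ref_genes)))
}

#' Generate a synthetic probeset-intensity cohort
#'
#' Draws a samples-by-probesets log2 intensity table with planted group
#' means per isoform channel, Gaussian probeset noise, a shared per-sample
#' global shift applied to every probeset (including references, so that
#' reference-gene normalization provably removes it), flat reference
#' genes, and auxiliary genes (PCA3, ERG with a per-sample fusion-like
#' upshift in tumour groups, PART1).
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `isoform_cohort` with tibbles:
#'   `intensities` (sample_id, probeset_id, intensity), `samples`
#'   (sample_id, group, erg_true, ref_shift), `map`
#'   (feature, role, probeset_id).
#' @export
gen_expression_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_parameter("`spec` must be created with cohort_spec().")
  }
  set.seed(spec$seed)
  isoforms <- rownames(spec$isoform_means)
  aux <- aux_gene_means(spec$groups)
  refs <- ref_gene_means(spec$n_ref_genes)

  feature_tbl <- dplyr::bind_rows(
    tibble(feature = isoforms, role = "isoform"),
    tibble(feature = rownames(aux), role = "auxiliary"),
    tibble(feature = names(refs), role = "reference")
  )
  map <- feature_tbl %>%
    mutate(ps = purrr::map(.data$feature, function(f) {
      sprintf("%s_ps%02d", gsub("[^A-Za-z0-9]", "", f),
              seq_len(spec$probesets_per_isoform))
    })) %>%
    tidyr::unnest_longer(col = "ps", values_to = "probeset_id") %>%
    select("feature", "role", "probeset_id")

  n_total <- spec$n_per_group * length(spec$groups)
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_total)),
    group = rep(spec$groups, each = spec$n_per_group)
  )
  tumour_like <- samples$group != spec$groups[1]
  samples$erg_true <- tumour_like &
    (runif(n_total) < spec$erg_fraction)
  samples$ref_shift <- rnorm(n_total, 0, spec$ref_shift_sd)

  mean_lookup <- rbind(spec$isoform_means, aux,
                       matrix(rep(refs, length(spec$groups)),
                              nrow = length(refs),
                              dimnames = list(names(refs), spec$groups)))

  grid <- tidyr::expand_grid(
    samples %>% select("sample_id", "group", "erg_true", "ref_shift"),
    map
  )
  mu <- mean_lookup[cbind(grid$feature, grid$group)]
  mu <- mu + ifelse(grid$feature == "ERG" & grid$erg_true, spec$erg_shift, 0)
  grid$intensity <- mu + grid$ref_shift +
    if (spec$sigma > 0) rnorm(nrow(grid), 0, spec$sigma) else 0

  structure(
    list(
      intensities = grid %>% select("sample_id", "probeset_id", "intensity"),
      samples = samples,
      map = map
    ),
    class = "isoform_cohort"
  )
}

#' Planted normalized profile of a cohort spec
#'
#' The expected reference-normalized expression per (group, channel):
#' the planted channel mean minus the average reference-gene mean. On a
#' zero-noise cohort, [summarize_isoforms()] recovers these exactly.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with group, feature, expected_expression.
#' @export
planted_profile <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_parameter("`spec` must be created with cohort_spec().")
  }
  ref_mean <- mean(ref_gene_means(spec$n_ref_genes))
  as_tibble(as.data.frame.table(spec$isoform_means,
                                stringsAsFactors = FALSE)) %>%
    rename(feature = "Var1", group = "Var2", mean_log2 = "Freq") %>%
    mutate(expected_expression = .data$mean_log2 - ref_mean) %>%
    select("group", "feature", "expected_expression")
}
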