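#' Read a BED3/BED6 file
#'
#' Coordinates stay 0-based half-open, matching the BED convention used
#' throughout the package. Malformed lines raise a parse error naming the
#' line number.
#'
#' @param path path to a BED file.
#' @return tibble (chrom, start, end, name, score, strand); optional
#'   columns are filled with `"."` / 0 for BED3 input.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    stop_data(sprintf("BED file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_intervals())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_line <- function(f, i) {
    if (length(f) < 3L) {
      stop_data(sprintf("BED parse error at line %d: fewer than 3 fields.", i))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      stop_data(sprintf(
        "BED parse error at line %d: invalid interval [%s, %s).", i, f[2], f[3]
      ))
    }
    strand <- if (length(f) >= 6L) f[6] else "."
    if (!strand %in% c("+", "-", ".")) {
      stop_data(sprintf("BED parse error at line %d: bad strand '%s'.", i, strand))
    }
    tibble(
      chrom = f[1], start = as.integer(start), end = as.integer(end),
      name = if (length(f) >= 4L) f[4] else ".",
      score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0,
      strand = strand
    )
  }
  purrr::imap_dfr(fields, parse_line)
}

#' Write intervals as BED6
#'
#' @param intervals tibble with at least chrom, start, end; name, score
#'   and strand are filled with defaults when absent.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  check_columns(intervals, c("chrom", "start", "end"), "intervals")
  out <- tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

check_intervals <- function(x, what = "intervals") {
  check_columns(x, c("chrom", "start", "end"), what)
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad) > 0L) {
    stop_data(sprintf(
      "`%s` row %d is not a valid 0-based half-open interval.", what, bad[1]
    ))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed).
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Count peak overlaps per region
#'
#' A peak counts for a region iff they share at least one base under
#' half-open semantics; one peak may count for several regions.
#' Chromosomes absent from the peak set simply yield zero counts.
#'
#' @param peaks tibble of peak intervals (chrom, start, end, ...).
#' @param regions tibble of regions to annotate.
#' @return `regions` with an added integer column `n_peaks`.
#' @export
count_overlaps <- function(peaks, regions) {
  check_intervals(regions, "regions")
  if (nrow(peaks) == 0L) {
    return(regions %>% mutate(n_peaks = 0L))
  }
  check_intervals(peaks, "peaks")
  counts <- suppressWarnings(GenomicRanges::countOverlaps(
    as_granges(regions), as_granges(peaks),
    minoverlap = 1L, ignore.strand = TRUE
  ))
  regions %>% mutate(n_peaks = as.integer(counts))
}

#' Strand-aware TSS window
#'
#' The transcription start site of a locus is its strand-appropriate
#' 5-prime base: `start` for + strand, `end - 1` for - strand. The
#' returned window spans `flank` bases on each side of the TSS base
#' (genomic half-open interval `[TSS - flank, TSS + flank)` on the +
#' strand and its mirrored counterpart `[TSS - flank, TSS + flank + 1)`
#' on the - strand), clipped to `[0, chromosome size)` when
#' `chrom_sizes` is given.
#'
#' @param loci tibble with chrom, start, end, strand.
#' @param flank half-width of the window in bp (default 2000).
#' @param chrom_sizes optional tibble (chrom, size) used for clipping.
#' @return tibble (chrom, start, end, name, score, strand) of windows.
#' @export
tss_window <- function(loci, flank = 2000L, chrom_sizes = NULL) {
  check_intervals(loci, "loci")
  check_columns(loci, "strand", "loci")
  flank <- check_count(flank, "flank", min = 1L)
  if (!all(loci$strand %in% c("+", "-"))) {
    stop_parameter("TSS windows need a known strand ('+' or '-') per locus.")
  }
  tss <- ifelse(loci$strand == "+", loci$start, loci$end - 1L)
  start <- pmax(0L, as.integer(tss - flank))
  end <- as.integer(tss + flank + ifelse(loci$strand == "-", 1L, 0L))
  if (!is.null(chrom_sizes)) {
    check_columns(chrom_sizes, c("chrom", "size"), "chrom_sizes")
    size <- chrom_sizes$size[match(loci$chrom, chrom_sizes$chrom)]
    end <- as.integer(pmin(end, size, na.rm = TRUE))
  }
  tibble(
    chrom = loci$chrom, start = start, end = end,
    name = if ("name" %in% names(loci)) paste0(loci$name, "_tss") else "tss",
    score = 0, strand = loci$strand
  )
}

#' Nearest peaks to a query point or interval
#'
#' Distances are genomic gaps in bp: overlapping (or directly abutting)
#' features have distance 0. Only same-chromosome peaks are considered;
#' an empty peak set returns an empty result. Distance ties are ordered
#' by peak start.
#'
#' @param peaks tibble of peak intervals.
#' @param query one-row tibble (chrom, start, end); use
#'   `start = p, end = p + 1` for a point.
#' @param k number of nearest peaks to return.
#' @return tibble of up to `k` peaks with an added `distance` column,
#'   sorted by ascending distance.
#' @export
nearest_peaks <- function(peaks, query, k = 5L) {
  check_intervals(query, "query")
  if (nrow(query) != 1L) {
    stop_parameter("`query` must be a single interval.")
  }
  k <- check_count(k, "k", min = 1L)
  if (nrow(peaks) == 0L) {
    return(empty_intervals() %>% mutate(distance = integer()))
  }
  check_intervals(peaks, "peaks")
  same <- peaks %>% filter(.data$chrom == query$chrom)
  if (nrow(same) == 0L) {
    return(same %>% mutate(distance = integer()))
  }
  dist <- pmax(0L, pmax(query$start - same$end, same$start - query$end))
  same %>%
    mutate(distance = as.integer(dist)) %>%
    arrange(.data$distance, .data$start) %>%
    head(k)
}

#' Random-window budget per chromosome
#'
#' Applies the sampling formula `number of regions = chromosome size in
#' Mb * 1000` (equivalently `floor(size_bp / 1000)`) per chromosome.
#' Chromosomes shorter than `region_len` are skipped with a warning.
#'
#' @param chrom_sizes tibble (chrom, size in bp).
#' @param region_len window length in bp (default 1.5 Mb).
#' @return tibble (chrom, size, n_requested).
#' @export
requested_windows <- function(chrom_sizes, region_len = 1500000L) {
  check_columns(chrom_sizes, c("chrom", "size"), "chrom_sizes")
  region_len <- check_count(region_len, "region_len", min = 1L)
  short <- chrom_sizes$size < region_len
  if (any(short)) {
    warn(sprintf(
      "Skipping %d chromosome(s) shorter than region_len: %s",
      sum(short), paste(chrom_sizes$chrom[short], collapse = ", ")
    ))
  }
  chrom_sizes %>%
    mutate(n_requested = ifelse(.data$size < region_len, 0L,
                                as.integer(floor(.data$size / 1000))))
}

#' Sample random genomic windows
#'
#' Per chromosome, draws the [requested_windows()] number of fixed-length
#' windows with independent uniform start positions in
#' `[0, size - region_len]` (sampling with replacement). Windows
#' overlapping `exclude` are removed after sampling, without resampling,
#' mirroring an exclusion (not replacement) policy. Deterministic under
#' `seed`.
#'
#' @inheritParams requested_windows
#' @param exclude optional tibble of intervals whose overlapping windows
#'   are dropped.
#' @param seed RNG seed.
#' @param n_per_chrom optional override of the per-chromosome window
#'   count (for small designs); `NULL` uses the size-based formula.
#' @return tibble (chrom, start, end) of surviving windows.
#' @export
sample_windows <- function(chrom_sizes, region_len = 1500000L, exclude = NULL,
                           seed = 1L, n_per_chrom = NULL) {
  req <- suppressWarnings(requested_windows(chrom_sizes, region_len))
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  if (!is.null(n_per_chrom)) {
    req$n_requested <- ifelse(req$n_requested > 0L,
                              check_count(n_per_chrom, "n_per_chrom", min = 1L),
                              0L)
  }
  windows <- purrr::pmap_dfr(req, function(chrom, size, n_requested) {
    if (n_requested == 0L) return(tibble(chrom = character(), start = integer()))
    starts <- floor(runif(n_requested, 0, size - region_len + 1))
    tibble(chrom = chrom, start = as.integer(starts))
  })
  windows <- windows %>% mutate(end = .data$start + as.integer(region_len))
  if (!is.null(exclude) && nrow(windows) > 0L && nrow(exclude) > 0L) {
    check_intervals(exclude, "exclude")
    hits <- GenomicRanges::countOverlaps(
      as_granges(windows), as_granges(exclude),
      minoverlap = 1L, ignore.strand = TRUE
    )
    windows <- windows[hits == 0L, ]
  }
  windows
}

#' Empirical-distribution percentile of an observed count
#'
#' `100 * |{x in background : x <= observed}| / N` - the inclusive ECDF,
#' so an observation at or above the background maximum reports 100.
#'
#' @param background_counts numeric background counts (non-empty).
#' @param observed observed count.
#' @return percentile in `[0, 100]`.
#' @export
ecdf_percentile <- function(background_counts, observed) {
  if (length(background_counts) == 0L) {
    stop_parameter("`background_counts` must be non-empty.")
  }
  if (!is.numeric(observed) || length(observed) != 1L || !is.finite(observed)) {
    stop_parameter("`observed` must be a single finite number.")
  }
  100 * mean(background_counts <= observed)
}

#' Peak-enrichment report for a target locus
#'
#' Counts peaks in the target locus and in every background region (gene
#' loci or random windows) and reports the empirical percentile of the
#' target count in the background distribution.
#'
#' @param peaks tibble of peak intervals.
#' @param target_locus one-row tibble (chrom, start, end).
#' @param background tibble of background regions; must not contain the
#'   target itself when a window background is used.
#' @param target_name label for the report.
#' @return object of class `enrichment_report`: list with `target_name`,
#'   `target_count`, `background_counts`, `n_background`, `percentile`.
#' @export
enrichment_report <- function(peaks, target_locus, background,
                              target_name = "target") {
  check_intervals(target_locus, "target_locus")
  if (nrow(target_locus) != 1L) {
    stop_parameter("`target_locus` must be a single interval.")
  }
  check_intervals(background, "background")
  if (nrow(background) == 0L) {
    stop_parameter("`background` must contain at least one region.")
  }
  target_count <- count_overlaps(peaks, target_locus)$n_peaks
  bg_counts <- count_overlaps(peaks, background)$n_peaks
  structure(
    list(
      target_name = target_name,
      target_count = target_count,
      background_counts = bg_counts,
      n_background = length(bg_counts),
      percentile = ecdf_percentile(bg_counts, target_count)
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "Enrichment of '%s': %d peaks; %.3f percentile of %d background regions\n",
    x$target_name, x$target_count, x$percentile, x$n_background
  ))
  invisible(x)
}

#' @method glance enrichment_report
#' @export
glance.enrichment_report <- function(x, ...) {
  tibble(
    target = x$target_name,
    target_count = x$target_count,
    n_background = x$n_background,
    background_mean = mean(x$background_counts),
    percentile = x$percentile
  )
}

#' hg19 major-chromosome sizes
#'
#' Sizes in bp of chromosomes 1-22, X and Y on the hg19 assembly, read
#' from the table shipped with the package.
#'
#' @return tibble (chrom, size).
#' @export
hg19_chrom_sizes <- function() {
  path <- system.file("extdata", "hg19.chrom.sizes", package = "isoswitchr",
                      mustWork = TRUE)
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  col_types = "ci", progress = FALSE)
}
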