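profile_wide <- function(profile, needed) {
  check_columns(profile, c("sample_id", "feature", "expression"), "profile")
  missing <- setdiff(needed, unique(profile$feature))
  if (length(missing) > 0L) {
    stop_data(sprintf(
      "Profile is missing required channel(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  profile %>%
    filter(.data$feature %in% needed) %>%
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "feature",
                       values_from = "expression")
}

#' Diagnostic isoform-switch score
#'
#' Per-sample score `PDE4D7 - PDE4D5`. Higher values are more
#' tumour-like: PDE4D7 rises in primary prostate cancer while PDE4D5
#' falls. The score is invariant to any per-sample shift common to both
#' channels, and in particular to the reference normalization offset.
#'
#' @param profile long tibble (sample_id, feature, expression), as from
#'   [summarize_isoforms()].
#' @return tibble (sample_id, score).
#' @export
diagnostic_score <- function(profile) {
  w <- profile_wide(profile, c("PDE4D7", "PDE4D5"))
  tibble(sample_id = w$sample_id, score = w$PDE4D7 - w$PDE4D5)
}

#' Prognostic isoform-switch score
#'
#' Per-sample score `PDE4D1/2 - (PDE4D5 + PDE4D7 + PDE4D9)`: the stable
#' short-isoform channel against the sum of the long isoforms that are
#' lost with disease progression. Higher values indicate worse prognosis.
#'
#' @inheritParams diagnostic_score
#' @return tibble (sample_id, score).
#' @export
prognostic_score <- function(profile) {
  w <- profile_wide(profile, c("PDE4D1/2", "PDE4D5", "PDE4D7", "PDE4D9"))
  tibble(
    sample_id = w$sample_id,
    score = w[["PDE4D1/2"]] - (w$PDE4D5 + w$PDE4D7 + w$PDE4D9)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC:
#' `P(score_pos > score_neg) + 0.5 * P(tie)`. No orientation flipping is
#' applied; the reported AUC is for the stated positive class.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (logical, 0/1, or a factor/character with
#'   two levels; the larger/last level is the positive class unless
#'   `positive` is given).
#' @param positive value of `labels` to treat as the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) {
    stop_parameter("`scores` and `labels` must have equal length.")
  }
  if (any(!is.finite(scores))) {
    stop_parameter("`scores` must be finite.")
  }
  if (is.null(positive)) {
    if (is.logical(labels)) {
      pos <- labels
    } else if (is.numeric(labels)) {
      pos <- labels == max(labels)
    } else {
      lv <- if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
      pos <- as.character(labels) == lv[length(lv)]
    }
  } else {
    pos <- labels == positive
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_evaluation("Both classes must be present to compute an AUC.")
  }
  r <- rank(scores) # average ranks give half credit for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Wilcoxon-Mann-Whitney comparison of two groups
#'
#' For combined sample sizes up to `exact_limit` the p-value is computed
#' by exhaustive enumeration of all group assignments of the pooled
#' average ranks (exact even in the presence of ties); larger inputs use
#' the normal approximation with tie-corrected variance via
#' [stats::wilcox.test()].
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @param exact_limit combined-size cutoff for the exact path.
#' @return one-row tibble (p_value, method, n_a, n_b).
#' @export
compare_groups <- function(values_a, values_b, exact_limit = 20L) {
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop_parameter("Both groups must be non-empty.")
  }
  if (any(!is.finite(c(values_a, values_b)))) {
    stop_parameter("Group values must be finite.")
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a + n_b <= exact_limit) {
    pooled <- c(values_a, values_b)
    r <- rank(pooled)
    mu <- n_a * (n_a + n_b + 1) / 2
    obs <- abs(sum(r[seq_len(n_a)]) - mu)
    splits <- utils::combn(n_a + n_b, n_a)
    stat <- abs(colSums(matrix(r[splits], nrow = n_a)) - mu)
    p <- mean(stat >= obs - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = FALSE)$p.value
    )
    method <- "normal approximation"
  }
  tibble(p_value = p, method = method, n_a = n_a, n_b = n_b)
}

#' Evaluate a signature against binary class labels
#'
#' Convenience wrapper joining scores to labels and reporting the AUC and
#' the Wilcoxon-Mann-Whitney p-value between classes.
#'
#' @param scores tibble (sample_id, score).
#' @param labels tibble (sample_id, label) with a two-level label.
#' @param positive label value treated as the positive class.
#' @return object of class `signature_eval`: list with `scores` (joined
#'   tibble), `auc`, `p_value`, `n_positive`, `n_negative`, `positive`.
#' @export
evaluate_signature <- function(scores, labels, positive) {
  check_columns(scores, c("sample_id", "score"), "scores")
  check_columns(labels, c("sample_id", "label"), "labels")
  joined <- inner_join(scores, labels, by = "sample_id")
  if (nrow(joined) == 0L) {
    stop_data("No samples shared between `scores` and `labels`.")
  }
  is_pos <- joined$label == positive
  if (!any(is_pos) || all(is_pos)) {
    stop_evaluation("Both classes must be present after joining.")
  }
  auc <- roc_auc(joined$score, is_pos)
  cmp <- compare_groups(joined$score[is_pos], joined$score[!is_pos])
  structure(
    list(
      scores = joined, auc = auc, p_value = cmp$p_value,
      n_positive = sum(is_pos), n_negative = sum(!is_pos),
      positive = positive
    ),
    class = "signature_eval"
  )
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf(
    "Signature evaluation: AUC = %.3f (%d positive '%s' vs %d negative), Wilcoxon p = %.3g\n",
    x$auc, x$n_positive, x$positive, x$n_negative, x$p_value
  ))
  invisible(x)
}

#' @method glance signature_eval
#' @export
glance.signature_eval <- function(x, ...) {
  tibble(
    auc = x$auc, p_value = x$p_value,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}
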