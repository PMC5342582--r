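#' Call copy-number state from a log2 ratio
#'
#' Uses the symmetric cutoff of +/- log2(1.5/2) ~= +/- 0.415: values at
#' or below -log2(4/3) are losses, values at or above +log2(4/3) are
#' gains, everything between is neutral.
#'
#' @param cna_log2 finite numeric vector of copy-number log2 ratios.
#' @param cutoff positive threshold magnitude; default `-log2(1.5/2)`.
#' @return character vector in {"loss", "neutral", "gain"}.
#' @export
call_cna <- function(cna_log2, cutoff = -log2(1.5 / 2)) {
  if (!is.numeric(cna_log2) || any(!is.finite(cna_log2))) {
    stop_data("`cna_log2` must be finite numeric.")
  }
  check_number(cutoff, "cutoff", min = 0, allow_min = FALSE)
  dplyr::case_when(
    cna_log2 <= -cutoff ~ "loss",
    cna_log2 >= cutoff ~ "gain",
    TRUE ~ "neutral"
  )
}

check_surv <- function(times, events) {
  if (length(times) != length(events) || length(times) < 1L) {
    stop_parameter("`times` and `events` must be non-empty and equal length.")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_data("`times` must be finite and non-negative.")
  }
  if (!all(events %in% c(0, 1))) {
    stop_data("`events` must be 0/1 indicators.")
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve; tied event times are processed
#' together, as in the standard product-limit estimator.
#'
#' @param times follow-up times (months).
#' @param events 0/1 event indicators (1 = event observed).
#' @return tibble of class `km_curve` (time, n_risk, n_event, n_censor,
#'   survival), one row per distinct observed time.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param groups two-level group labels.
#' @return one-row tibble (statistic, df, p_value).
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) {
    stop_parameter("`groups` must contain exactly two groups.")
  }
  if (sum(events) < 1L) {
    stop_parameter("At least one event is required.")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd$n) - 1L
  tibble(
    statistic = unname(sd$chisq),
    df = df,
    p_value = pchisq(sd$chisq, df, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards fit for a signature score
#'
#' Fits `Surv(time, event) ~ score (+ covariates)` by partial likelihood
#' and reports coefficients, hazard ratios, Wald confidence intervals
#' and p-values. Non-convergence or degenerate (constant / aliased)
#' terms are reported explicitly via `converged`, never silently.
#'
#' @param records tibble with columns `time`, `event`, the score column
#'   and any covariate columns.
#' @param score_col name of the score column (default "score").
#' @param covariates optional character vector of covariate columns.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return object of class `isoswitch_cox`: list with `fit` (the coxph
#'   object), `terms` (tidy tibble), `converged`, `n`, `n_event`.
#' @export
cox_fit <- function(records, score_col = "score", covariates = NULL,
                    conf_level = 0.95) {
  check_columns(records, c("time", "event", score_col, covariates), "records")
  check_surv(records$time, records$event)
  terms <- c(score_col, covariates)
  degenerate <- terms[vapply(terms, function(v) {
    length(unique(records[[v]])) <= 1L
  }, logical(1))]
  if (sum(records$event) < length(terms)) {
    stop_parameter("Fewer events than model parameters.")
  }
  term_labels <- ifelse(make.names(terms) == terms, terms,
                        sprintf("`%s`", terms))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(term_labels, collapse = " + ")
  ))
  fit_warned <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = records),
      warning = function(w) {
        fit_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop_evaluation("Cox model failed to fit.")
  }
  co <- summary(fit, conf.int = conf_level)
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  tidy_terms <- tibble(
    term = names(est),
    estimate = unname(est),
    std_error = se,
    hazard_ratio = exp(unname(est)),
    conf_low = exp(unname(est) - z * se),
    conf_high = exp(unname(est) + z * se),
    p_value = unname(co$coefficients[, "Pr(>|z|)"])
  )
  converged <- length(degenerate) == 0L && !any(is.na(est)) && !fit_warned
  structure(
    list(
      fit = fit,
      terms = tidy_terms,
      converged = converged,
      degenerate = degenerate,
      n = fit$n,
      n_event = fit$nevent
    ),
    class = "isoswitch_cox"
  )
}

#' @export
print.isoswitch_cox <- function(x, ...) {
  cat(sprintf("Cox fit on %d samples (%d events)%s\n", x$n, x$n_event,
              if (x$converged) "" else " [NOT CONVERGED / DEGENERATE]"))
  print(x$terms)
  invisible(x)
}

#' @method tidy isoswitch_cox
#' @export
tidy.isoswitch_cox <- function(x, ...) {
  x$terms
}

#' @method glance isoswitch_cox
#' @export
glance.isoswitch_cox <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event, converged = x$converged,
    n_degenerate = length(x$degenerate)
  )
}

#' Evaluate the prognostic signature against survival endpoints
#'
#' Composes the pipeline used for outcome analysis: compute the
#' prognostic score, dichotomize the cohort into signature high/low by
#' one-dimensional PAM, then report per-group Kaplan-Meier curves, the
#' log-rank test and a Cox fit on the continuous score (plus any
#' covariates). An optional follow-up `horizon` truncates observation:
#' times beyond the horizon are censored there.
#'
#' @param profile isoform profile tibble (sample_id, feature, expression).
#' @param records clinical tibble with sample_id, time, event and any
#'   covariates.
#' @param covariates optional covariate columns for the Cox model.
#' @param horizon optional follow-up truncation time.
#' @return object of class `prognostic_eval`: list with `scores`
#'   (sample_id, score, group), `km` (per-group km_curve rows), `logrank`,
#'   `cox`, `unstable_grouping` flag and group sizes.
#' @export
evaluate_prognostic <- function(profile, records, covariates = NULL,
                                horizon = NULL) {
  check_columns(records, c("sample_id", "time", "event", covariates),
                "records")
  scores <- prognostic_score(profile)
  joined <- inner_join(scores, records, by = "sample_id")
  if (nrow(joined) < 4L) {
    stop_data("Too few samples with both profile and follow-up.")
  }
  if (!is.null(horizon)) {
    check_number(horizon, "horizon", min = 0, allow_min = FALSE)
    over <- joined$time > horizon
    joined$event[over] <- 0L
    joined$time[over] <- horizon
  }
  pam <- pam_1d(joined$score)
  joined$group <- label_clusters(pam, high_label = "high", low_label = "low")
  sizes <- table(joined$group)
  unstable <- length(sizes) < 2L || min(sizes) < 2L
  km <- joined %>%
    group_by(.data$group) %>%
    dplyr::group_map(function(df, key) {
      km_estimate(df$time, df$event) %>% mutate(group = key$group)
    }) %>%
    bind_rows()
  lr <- if (!unstable && sum(joined$event) >= 1L) {
    logrank_test(joined$time, joined$event, joined$group)
  } else {
    tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  cox <- cox_fit(joined, score_col = "score", covariates = covariates)
  structure(
    list(
      scores = joined %>% select("sample_id", "score", "group", "time", "event"),
      km = km,
      logrank = lr,
      cox = cox,
      unstable_grouping = unstable,
      n_high = sum(joined$group == "high"),
      n_low = sum(joined$group == "low")
    ),
    class = "prognostic_eval"
  )
}

#' @export
print.prognostic_eval <- function(x, ...) {
  cat(sprintf(
    "Prognostic evaluation: %d high vs %d low; log-rank p = %.3g%s\n",
    x$n_high, x$n_low, x$logrank$p_value,
    if (x$unstable_grouping) " [UNSTABLE GROUPING]" else ""
  ))
  invisible(x)
}

#' @method glance prognostic_eval
#' @export
glance.prognostic_eval <- function(x, ...) {
  score_term <- x$cox$terms[x$cox$terms$term %in% c("score", "`score`"), ]
  tibble(
    n_high = x$n_high, n_low = x$n_low,
    logrank_p = x$logrank$p_value,
    cox_hr = score_term$hazard_ratio[1],
    cox_p = score_term$p_value[1],
    unstable_grouping = x$unstable_grouping
  )
}
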