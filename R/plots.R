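#' Plot normalized isoform expression by group
#'
#' Boxplots of normalized expression per isoform channel, faceted by
#' channel, optionally coloured by a sample grouping.
#'
#' @param object an `isoform_profile` tibble.
#' @param groups optional tibble (sample_id, group).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot isoform_profile
#' @export
autoplot.isoform_profile <- function(object, groups = NULL, ...) {
  df <- object
  if (!is.null(groups)) {
    check_columns(groups, c("sample_id", "group"), "groups")
    df <- df %>% inner_join(groups, by = "sample_id")
  } else {
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$expression,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized expression (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot Kaplan-Meier curves
#'
#' Step curves of the product-limit estimate; a `group` column (as
#' produced inside [evaluate_prognostic()]) is used for colour when
#' present.
#'
#' @param object a `km_curve` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- object
  if (!"group" %in% names(df)) df$group <- "all"
  start <- df %>%
    distinct(.data$group) %>%
    mutate(time = 0, survival = 1)
  df <- bind_rows(start, df %>% select("group", "time", "survival")) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a peak-enrichment null distribution
#'
#' Histogram of background peak counts with the observed target count
#' marked; the empirical percentile appears in the subtitle.
#'
#' @param object an `enrichment_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot enrichment_report
#' @export
autoplot.enrichment_report <- function(object, ...) {
  df <- tibble(count = object$background_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$target_count, colour = "red") +
    ggplot2::labs(
      x = "peaks per background region", y = "regions",
      title = sprintf("Peak enrichment: %s", object$target_name),
      subtitle = sprintf("observed %d peaks; %.3f percentile of %d regions",
                         object$target_count, object$percentile,
                         object$n_background)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean relative biopsy expression with SEM error bars
#'
#' @param summary tibble from [summarize_biopsy_profile()].
#' @param location_order optional ordering of biopsy locations.
#' @return a ggplot object.
#' @export
plot_biopsy_profile <- function(summary,
                                location_order = c("tumour", "edge",
                                                   "5mm", "10mm")) {
  check_columns(summary, c("location", "mean", "sem"), "summary")
  df <- summary %>%
    mutate(location = factor(.data$location,
                             levels = intersect(location_order,
                                                unique(.data$location))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$location, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = "biopsy location", y = "relative expression (fold)") +
    ggplot2::theme_minimal()
}
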