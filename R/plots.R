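#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Importance plot for a two-step random-forest selection
#'
#' Permutation importance per SNP, faceted by selection stage, colored by the
#' selection flag.
#'
#' @param object An `rf_selection` from [two_step_select()].
#' @param top_n Show at most this many SNPs per stage (by importance).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rf_selection
#' @export
autoplot.rf_selection <- function(object, top_n = 30L, ...) {
  df <- tidy(object)
  df <- dplyr::slice_max(dplyr::group_by(df, .data$stage),
                         .data$importance, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$snp_id, .data$importance),
    color = .data$selected
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$snp_id, .data$importance))) +
    ggplot2::facet_wrap(~stage, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "permutation importance", y = NULL,
                  color = "selected") +
    ggplot2::theme_minimal()
}

#' Triplet-statistic plot for a pipeline run
#'
#' Signed interaction-information gain against the chi-square test statistic
#' for every evaluated triplet, with the screen threshold visible through the
#' color coding of the cascade outcome.
#'
#' @param object A `wii_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wii_pipeline
#' @export
autoplot.wii_pipeline <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0L) {
    stop("pipeline stopped before the triplet stage; nothing to plot",
         call. = FALSE)
  }
  df$outcome <- dplyr::case_when(
    !df$pass_screen ~ "screened out",
    df$excluded_reason == "pairwise_2way" ~ "pairwise excluded",
    df$excluded_reason == "ld_pair" ~ "LD excluded",
    !is.na(df$significant) & df$significant ~ "significant",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iig, y = .data$t_stat,
                                   color = .data$outcome)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "interaction information gain (nats)",
                  y = expression(T[IG]), color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a penetrance-table triplet
#'
#' Heatmap of the 27 penetrance entries, faceted by the third SNP's genotype;
#' for a pure parity table the checkerboard pattern (and the absence of any
#' row/column trend) is visible directly.
#'
#' @param triplet A [penetrance_triplet].
#' @return A ggplot object.
#' @export
plot_penetrance <- function(triplet) {
  stopifnot(inherits(triplet, "penetrance_triplet"))
  df <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  df$f <- as.vector(triplet$penetrance)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$g1), y = factor(.data$g2),
                                   fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~g3, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "P(D = 1)") +
    ggplot2::labs(x = "genotype SNP 1", y = "genotype SNP 2") +
    ggplot2::theme_minimal()
}
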