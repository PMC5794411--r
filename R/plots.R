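#' Plot the balanced-model reference lines
#'
#' The two straight lines of the model: expected eta (solid) and expected mu
#' (dashed) as a function of the average z-score, with slopes equal to the
#' battery's mean VP and VMC recruitment.
#'
#' @param battery An [battery()] object.
#' @param z_range Range of average z-scores to draw, default `c(-3, 0)`.
#' @param administered Optional subset of test names.
#' @return A ggplot object.
#' @export
plot_model_lines <- function(battery = default_battery(),
                             z_range = c(-3, 0), administered = NULL) {
  grid <- model_lines(seq(min(z_range), max(z_range), length.out = 61),
                      battery, administered)
  long <- tidyr::pivot_longer(grid, c("eta_exp", "mu_exp"),
                              names_to = "index", values_to = "value")
  long$index <- ifelse(long$index == "eta_exp", "eta (VP)", "mu (VMC)")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$avg_z, y = .data$value,
                               linetype = .data$index)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c("eta (VP)" = "solid",
                                              "mu (VMC)" = "dashed")) +
    ggplot2::labs(x = "average z-score", y = "index (arbitrary units)",
                  linetype = NULL,
                  title = "Expected indices under balanced impairment") +
    ggplot2::theme_minimal()
}

#' Plot session scores
#'
#' Observed eta and mu per session next to their expected baselines, the
#' per-patient view used to read off which domain exceeds its share.
#'
#' @param object An `etamu_scores` tibble from [score_sessions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.etamu_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("subject_id", "session", "eta", "mu",
                          "eta_exp", "mu_exp")],
    c("eta", "mu", "eta_exp", "mu_exp"),
    names_to = "index", values_to = "value"
  )
  long$domain <- ifelse(grepl("^eta", long$index), "VP (eta)", "VMC (mu)")
  long$kind <- ifelse(grepl("_exp$", long$index), "expected", "observed")
  long$label <- paste(long$subject_id, long$session)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$domain, y = .data$value,
                               fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "index (arbitrary units)", fill = NULL,
                  title = "Observed vs expected impairment indices") +
    ggplot2::theme_minimal()
}

#' Plot pre/post comparisons
#'
#' Arrow per subject and domain from the pre-treatment to the post-treatment
#' index value.
#'
#' @param object An `etamu_comparison` tibble from [compare_sessions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.etamu_comparison <- function(object, ...) {
  df <- as_tibble(object)
  long <- bind_rows(
    tibble(subject_id = df$subject_id, domain = "VP (eta)",
           pre = df$eta_pre, post = df$eta_post),
    tibble(subject_id = df$subject_id, domain = "VMC (mu)",
           pre = df$mu_pre, post = df$mu_post)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$subject_id, y = .data$pre, yend = .data$post),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm"))
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pre)) +
    ggplot2::facet_wrap(~domain) +
    ggplot2::labs(x = NULL, y = "index (arbitrary units)",
                  title = "Change in impairment indices after treatment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
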