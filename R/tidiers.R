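#' Tidy session scores
#'
#' Long, one-statistic-per-row view of an `etamu_scores` object, convenient
#' for plotting and joining.
#'
#' @param x An `etamu_scores` tibble from [score_sessions()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `session`, `statistic`,
#'   `value`.
#' @exportS3Method generics::tidy
tidy.etamu_scores <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("subject_id", "session", "n_tests", "avg_z", "eta",
                     "mu", "eta_exp", "mu_exp", "delta_eta", "delta_mu")],
    -c("subject_id", "session"),
    names_to = "statistic", values_to = "value"
  )
}

#' Glance at session scores
#'
#' One-row cohort-level summary of an `etamu_scores` object: session count,
#' median average z with Tukey-hinge bounds (when at least two sessions are
#' scored), the tolerance, and the battery label.
#'
#' @inheritParams tidy.etamu_scores
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.etamu_scores <- function(x, ...) {
  base <- tibble(
    n_sessions = nrow(x),
    n_subjects = length(unique(x$subject_id)),
    median_avg_z = NA_real_,
    lower_hinge = NA_real_,
    upper_hinge = NA_real_,
    tolerance = x$tolerance[1],
    battery_label = attr(x, "battery_label") %||% NA_character_
  )
  if (nrow(x) >= 2) {
    h <- tukey_hinges(x$avg_z)
    base$median_avg_z <- h$median
    base$lower_hinge <- h$lower_hinge
    base$upper_hinge <- h$upper_hinge
  }
  base
}

#' @rdname tidy.etamu_scores
#' @exportS3Method generics::tidy
tidy.etamu_comparison <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("subject_id", "avg_z_change", "eta_improvement",
                     "mu_improvement", "paired_p")],
    -"subject_id", names_to = "statistic", values_to = "value"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
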