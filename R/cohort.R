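#' Tukey hinges and median
#'
#' Five-number-style summary used for the cohort interquartile range: the
#' lower (upper) hinge is the median of the lower (upper) half of the sorted
#' data, the halves excluding the overall median element when the count is
#' odd. With four values this reproduces the midpoints of the two outer
#' pairs.
#'
#' @param values Numeric vector, length at least 2; `NA` not allowed.
#' @return A one-row tibble with `median`, `lower_hinge`, `upper_hinge`.
#' @export
#' @examples
#' tukey_hinges(c(1, 2, 3, 4))   # 2.5, 1.5, 3.5
tukey_hinges <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) abort("`values` must not contain NA")
  n <- length(values)
  if (n < 2) abort("need at least 2 values")
  s <- sort(values)
  half <- floor(n / 2)
  tibble(
    median = median(s),
    lower_hinge = median(s[seq_len(half)]),
    upper_hinge = median(s[seq(n - half + 1, n)])
  )
}

#' Cohort summary of session scores
#'
#' Summarises the average z-scores of a set of scored sessions with the
#' median and Tukey-hinge interquartile range, the robust description used
#' for small clinical cohorts.
#'
#' @param scores An `etamu_scores` tibble from [score_sessions()] (or any
#'   data frame with an `avg_z` column), at least 2 rows.
#' @return A one-row tibble with `n_subjects`, `median_avg_z`,
#'   `lower_hinge`, `upper_hinge`.
#' @export
#' @examples
#' path <- system.file("extdata", "table3_pre.csv", package = "etamu")
#' read_subject_table(path) |> score_sessions() |> cohort_summary()
cohort_summary <- function(scores) {
  stopifnot(is.data.frame(scores), "avg_z" %in% names(scores))
  if (nrow(scores) < 2) abort("need at least 2 scored sessions")
  h <- tukey_hinges(scores$avg_z)
  tibble(
    n_subjects = nrow(scores),
    median_avg_z = h$median,
    lower_hinge = h$lower_hinge,
    upper_hinge = h$upper_hinge
  )
}

#' Compare pre- and post-treatment sessions
#'
#' For each subject present in both sessions, scores the two time points
#' over the *intersection* of administered tests (so the mean recruitment
#' weights are identical pre and post), and reports the relative reduction
#' of each index, the change in average z, and an exact two-sided Wilcoxon
#' signed-rank test on the per-test z-score pairs.
#'
#' The improvement metric is `100 * (pre - post) / pre`, reported only when
#' the pre index is positive (a non-impaired baseline has no meaningful
#' relative reduction, so the value is `NA` there). When every per-test
#' difference is zero the signed-rank statistic is undefined and `paired_p`
#' is `NA`.
#'
#' @param data Long subject table containing both sessions (columns
#'   `subject_id`, `session`, `test_name`, `z_score`).
#' @param battery An [battery()] object.
#' @param pre,post Session labels identifying the two time points.
#' @param tolerance Balanced-band half-width for the per-session
#'   classification.
#' @return A tibble of class `etamu_comparison`, one row per subject, with
#'   pre/post indices, `eta_improvement`, `mu_improvement`, `avg_z_change`
#'   (post minus pre), `n_paired` and `paired_p`.
#' @export
compare_sessions <- function(data, battery = default_battery(),
                             pre = "pre", post = "post", tolerance = 2) {
  data <- .check_subject_table(data)
  have <- unique(data$session)
  for (lab in c(pre, post)) {
    if (!lab %in% have) {
      abort(paste0("session label \"", lab, "\" not present in the data"))
    }
  }
  subjects <- intersect(unique(data$subject_id[data$session == pre]),
                        unique(data$subject_id[data$session == post]))
  if (length(subjects) == 0) abort("no subject has both sessions")
  out <- purrr::map_dfr(subjects, function(sid) {
    zp <- data[data$subject_id == sid & data$session == pre, ]
    zq <- data[data$subject_id == sid & data$session == post, ]
    shared <- intersect(zp$test_name, zq$test_name)
    if (length(shared) == 0) {
      abort(paste0("subject ", sid, ": pre and post sessions share no test"))
    }
    z1 <- setNames(zp$z_score, zp$test_name)[shared]
    z2 <- setNames(zq$z_score, zq$test_name)[shared]
    r1 <- score_session(z1, battery, tolerance, sid, pre)
    r2 <- score_session(z2, battery, tolerance, sid, post)
    p <- .paired_signed_rank(z1, z2)
    tibble(
      subject_id = sid,
      n_paired = length(shared),
      avg_z_pre = r1$avg_z, avg_z_post = r2$avg_z,
      avg_z_change = r2$avg_z - r1$avg_z,
      eta_pre = r1$eta, eta_post = r2$eta,
      eta_improvement = .relative_reduction(r1$eta, r2$eta),
      mu_pre = r1$mu, mu_post = r2$mu,
      mu_improvement = .relative_reduction(r1$mu, r2$mu),
      delta_eta_pre = r1$delta_eta, delta_eta_post = r2$delta_eta,
      delta_mu_pre = r1$delta_mu, delta_mu_post = r2$delta_mu,
      classification_pre = r1$classification,
      classification_post = r2$classification,
      paired_p = p
    )
  })
  attr(out, "battery_label") <- attr(battery, "label")
  attr(out, "sessions") <- c(pre = pre, post = post)
  class(out) <- c("etamu_comparison", class(out))
  out
}

# percent relative reduction of an index; undefined at a nonpositive baseline
.relative_reduction <- function(pre, post) {
  if (is.na(pre) || pre <= 0) return(NA_real_)
  100 * (pre - post) / pre
}

# exact two-sided Wilcoxon signed-rank on the per-test z pairs; NA when the
# statistic is undefined (all differences zero)
.paired_signed_rank <- function(z_pre, z_post) {
  if (all(z_pre == z_post)) return(NA_real_)
  tryCatch(
    suppressWarnings(
      wilcox.test(z_pre, z_post, paired = TRUE, exact = TRUE)$p.value
    ),
    error = function(e) NA_real_
  )
}
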