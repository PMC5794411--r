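#' Eta and Mu: weighted impairment indices
#'
#' The core of the model. For a session of `n` administered tests with
#' z-scores `z_i` (standardised against age norms, negative = below norm)
#' and recruitment weights `vp_i`, `vmc_i`:
#'
#' \deqn{\eta = -\sum_i vp_i z_i / n, \qquad \mu = -\sum_i vmc_i z_i / n}
#'
#' so both indices are positive when performance is below norms, and their
#' sum is always \eqn{-100 \bar z}. Expected baselines describe the
#' "balanced" subject whose VP and VMC systems are impaired to the same
#' extent (identical z on every test):
#'
#' \deqn{\eta_{exp} = \overline{vp}\,|\bar z|, \qquad
#'       \mu_{exp} = \overline{vmc}\,|\bar z|}
#'
#' where the mean weights are taken over the administered subset (76/24 for
#' the complete default battery). The excess \eqn{\Delta\eta = \eta -
#' \eta_{exp}} quantifies the prevalent visuoperceptive deficit,
#' \eqn{\Delta\mu} the visuomotor one; when the average z is nonpositive the
#' two deltas are exact opposites.
#'
#' @param z Named numeric vector of z-scores; names are test names present
#'   in `battery`. Missing tests are simply absent.
#' @param battery An [battery()] object (default: [default_battery()]).
#' @return `compute_eta()` and `compute_mu()` return a single number;
#'   `average_z()` the plain mean of the administered z-scores.
#' @name eta_mu
#' @export
#' @examples
#' z <- c(corsi_visual = -3, corsi_simultaneous = -2, corsi_sequential = -1.5,
#'        bhk_quality = -0.5, bhk_velocity = -0.5, tcm_velocity = -1.5,
#'        tcm_accuracy = -2, rocf_copy = -1.5, rocf_memory = -2,
#'        dem_ratio = -2)
#' compute_eta(z)   # 140.5
#' compute_mu(z)    # 24.5
compute_eta <- function(z, battery = default_battery()) {
  w <- .session_weights(z, battery)
  -sum(w$vp_weight * z) / length(z)
}

#' @rdname eta_mu
#' @export
compute_mu <- function(z, battery = default_battery()) {
  w <- .session_weights(z, battery)
  -sum(w$vmc_weight * z) / length(z)
}

#' @rdname eta_mu
#' @export
average_z <- function(z) {
  if (length(z) == 0) abort("session has no z-scores")
  mean(z)
}

# match a session's tests against the battery, preserving session order
.session_weights <- function(z, battery) {
  if (length(z) == 0) abort("session has no z-scores")
  nm <- names(z)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    abort("z-scores must be named by test")
  }
  unknown <- setdiff(nm, battery$name)
  if (length(unknown) > 0) {
    abort(paste0("test(s) not in battery: ", paste(unknown, collapse = ", ")))
  }
  idx <- match(nm, battery$name)
  list(vp_weight = battery$vp_weight[idx],
       vmc_weight = battery$vmc_weight[idx])
}

#' Expected indices under balanced impairment
#'
#' @param avg_z Mean z-score of the session.
#' @param mean_vp,mean_vmc Mean recruitment percents of the administered
#'   subset; must sum to 100 (see [mean_weights()]).
#' @return A one-row tibble with `eta_exp`, `mu_exp`.
#' @export
#' @examples
#' expected_indices(-1.65, 76, 24)   # 125.4, 39.6
expected_indices <- function(avg_z, mean_vp, mean_vmc) {
  if (abs(mean_vp + mean_vmc - 100) > 1e-9) {
    abort("mean_vp + mean_vmc must equal 100")
  }
  tibble(eta_exp = mean_vp * abs(avg_z),
         mu_exp = mean_vmc * abs(avg_z))
}

#' Deficit classification from the index excesses
#'
#' A session is `VP_PREVALENT` when `delta_eta > tolerance`, `VMC_PREVALENT`
#' when `delta_mu > tolerance`, and `BALANCED` otherwise (a tie at exactly
#' the tolerance is balanced). The rule is only meaningful when the average
#' z is nonpositive, where the two deltas are exact opposites; for sessions
#' with a positive average z there is no net impairment to apportion, so
#' the classification is `NA` (callers flag these separately).
#'
#' @param delta_eta,delta_mu Observed minus expected index.
#' @param avg_z Mean z-score of the session.
#' @param tolerance Half-width of the balanced band, in the same arbitrary
#'   units as eta/mu. Default 2.
#' @return Character vector over `VP_PREVALENT`, `VMC_PREVALENT`,
#'   `BALANCED`, or `NA` when `avg_z > 0`.
#' @export
classify_deficit <- function(delta_eta, delta_mu, avg_z, tolerance = 2) {
  stopifnot(tolerance >= 0)
  out <- rep(NA_character_, length(delta_eta))
  net <- avg_z <= 0
  out[net & delta_eta > tolerance] <- "VP_PREVALENT"
  out[net & delta_mu > tolerance] <- "VMC_PREVALENT"
  out[net & delta_eta <= tolerance & delta_mu <= tolerance] <- "BALANCED"
  out
}

#' Score one session
#'
#' Convenience wrapper that scores a single named z-score vector; the tidy
#' data-frame interface is [score_sessions()].
#'
#' @inheritParams eta_mu
#' @param tolerance Balanced-band half-width, see [classify_deficit()].
#' @param subject_id,session Identifiers carried into the result.
#' @return A one-row tibble with `subject_id`, `session`, `n_tests`,
#'   `avg_z`, `mean_vp`, `mean_vmc`, `eta`, `mu`, `eta_exp`, `mu_exp`,
#'   `delta_eta`, `delta_mu`, `classification`, `no_net_impairment`,
#'   `tolerance`.
#' @export
score_session <- function(z, battery = default_battery(), tolerance = 2,
                          subject_id = "subject", session = "session") {
  w <- .session_weights(z, battery)
  if (any(abs(z) > 5)) {
    warn(paste0("implausible z-score(s) (|z| > 5) in ", subject_id, "/",
                session, ": ",
                paste(names(z)[abs(z) > 5], collapse = ", ")))
  }
  n <- length(z)
  avg <- mean(z)
  eta <- -sum(w$vp_weight * z) / n
  mu <- -sum(w$vmc_weight * z) / n
  mean_vp <- mean(w$vp_weight)
  mean_vmc <- mean(w$vmc_weight)
  eta_exp <- mean_vp * abs(avg)
  mu_exp <- mean_vmc * abs(avg)
  delta_eta <- eta - eta_exp
  delta_mu <- mu - mu_exp
  no_net <- avg > 0
  if (no_net) {
    warn(paste0("session ", subject_id, "/", session, " has positive average ",
                "z-score: no net impairment, classification withheld"))
  }
  tibble(
    subject_id = subject_id, session = session,
    n_tests = n, avg_z = avg,
    mean_vp = mean_vp, mean_vmc = mean_vmc,
    eta = eta, mu = mu, eta_exp = eta_exp, mu_exp = mu_exp,
    delta_eta = delta_eta, delta_mu = delta_mu,
    classification = classify_deficit(delta_eta, delta_mu, avg, tolerance),
    no_net_impairment = no_net,
    tolerance = tolerance
  )
}

#' Score every session in a subject table
#'
#' The main verb of the package. Takes a long/tidy table of z-scores --
#' one row per `(subject_id, session, test_name)` -- and returns one row of
#' derived quantities per session: average z, the weighted indices eta and
#' mu, their expected baselines over the administered subset, the excesses
#' delta_eta/delta_mu, and the deficit classification. Incomplete sessions
#' are scored over the tests actually administered, with the mean
#' recruitment weights recomputed for that subset.
#'
#' @param data Data frame with columns `subject_id`, `session`, `test_name`,
#'   `z_score`.
#' @param battery An [battery()] object.
#' @param tolerance Balanced-band half-width, see [classify_deficit()].
#' @return A tibble of class `etamu_scores`, one row per session, ordered by
#'   subject then session.
#' @seealso [score_session()], [cohort_summary()], [compare_sessions()]
#' @export
#' @examples
#' path <- system.file("extdata", "table2_worked_example.csv",
#'                     package = "etamu")
#' read_subject_table(path) |> score_sessions()
score_sessions <- function(data, battery = default_battery(), tolerance = 2) {
  data <- .check_subject_table(data)
  groups <- dplyr::group_split(dplyr::group_by(data, subject_id, session))
  out <- purrr::map_dfr(groups, function(g) {
    z <- setNames(g$z_score, g$test_name)
    score_session(z, battery = battery, tolerance = tolerance,
                  subject_id = g$subject_id[1], session = g$session[1])
  })
  out <- arrange(out, subject_id, session)
  attr(out, "battery_label") <- attr(battery, "label")
  class(out) <- c("etamu_scores", class(out))
  out
}

# basic structural checks shared by the scoring and comparison verbs
.check_subject_table <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("subject_id", "session", "test_name", "z_score"),
                          names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("subject table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("subject table is empty")
  key <- paste(data$subject_id, data$session, data$test_name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1, ]
    abort(paste0("duplicate (subject_id, session, test_name) row: ",
                 d$subject_id, "/", d$session, "/", d$test_name))
  }
  as_tibble(data)
}

#' Reference lines of the balanced model
#'
#' Evaluates the expected indices over a grid of average z-scores, giving
#' the two straight reference lines against which an individual session is
#' judged: the eta line with slope `mean_vp` and the mu line with slope
#' `mean_vmc` (in absolute z).
#'
#' @param z_grid Numeric vector of average z-scores.
#' @param battery An [battery()] object.
#' @param administered Optional subset of test names over which to take the
#'   mean weights.
#' @return A tibble with columns `avg_z`, `eta_exp`, `mu_exp`.
#' @export
#' @examples
#' model_lines(c(-1, -2))   # 76/24 slopes of the default battery
model_lines <- function(z_grid, battery = default_battery(),
                        administered = NULL) {
  if (length(z_grid) == 0) abort("`z_grid` must be nonempty")
  mw <- mean_weights(battery, administered)
  tibble(
    avg_z = as.numeric(z_grid),
    eta_exp = mw$mean_vp * abs(z_grid),
    mu_exp = mw$mean_vmc * abs(z_grid)
  )
}
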