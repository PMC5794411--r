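#' Impairment profiles for synthetic subjects
#'
#' A profile parameterises the generative inverse of the scoring equations:
#' the two severities are expressed in z units *per unit recruitment*, so a
#' subject with `vp_severity == vmc_severity == s` scores `z = -s` on every
#' test (the ideal "balanced" subject), and an unbalanced profile depresses
#' the tests in proportion to how strongly they recruit the affected domain.
#' Gaussian measurement noise with standard deviation `noise_sd` is added
#' independently per test.
#'
#' @param vp_severity,vmc_severity Nonnegative impairment severities in z
#'   units per unit recruitment. Vectorised: one row per subject.
#' @param noise_sd Nonnegative measurement-noise standard deviation in z
#'   units.
#' @param seed Optional per-subject random seed (`NA` lets
#'   [simulate_cohort()] derive one from its global seed).
#' @return A tibble with columns `vp_severity`, `vmc_severity`, `noise_sd`,
#'   `seed`, one row per subject.
#' @export
#' @examples
#' impairment_profile(vp_severity = c(2, 0), vmc_severity = c(0, 2),
#'                    noise_sd = 0.3)
impairment_profile <- function(vp_severity = 0, vmc_severity = 0,
                               noise_sd = 0, seed = NA_integer_) {
  out <- tibble(
    vp_severity = as.numeric(vp_severity),
    vmc_severity = as.numeric(vmc_severity),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  if (any(out$vp_severity < 0) || any(out$vmc_severity < 0) ||
      any(out$noise_sd < 0)) {
    abort("severities and noise_sd must be nonnegative")
  }
  out
}

#' Simulate one subject session
#'
#' Draws one session from an impairment profile:
#' `z_i = -(vp_severity * vp_i + vmc_severity * vmc_i) / 100 + e_i` with
#' `e_i ~ Normal(0, noise_sd^2)`, for every test of the battery. The draw is
#' deterministic given the profile's seed and leaves the caller's RNG state
#' untouched.
#'
#' @param profile A one-row [impairment_profile()] (a list with the same
#'   fields also works).
#' @param battery An [battery()] object.
#' @param subject_id,session Identifiers written into the output rows.
#' @return A long subject-table tibble (`subject_id`, `session`,
#'   `test_name`, `z_score`) with one row per battery test.
#' @export
#' @examples
#' simulate_session(impairment_profile(1, 1, 0), subject_id = "ideal")
simulate_session <- function(profile, battery = default_battery(),
                             subject_id = "sim1", session = "sim") {
  stopifnot(nrow(as_tibble(profile)) == 1 || is.list(profile))
  p <- as.list(as_tibble(profile)[1, ])
  deterministic <- -(p$vp_severity * battery$vp_weight +
                       p$vmc_severity * battery$vmc_weight) / 100
  eps <- if (p$noise_sd > 0) {
    .with_seed(p$seed, rnorm(nrow(battery), 0, p$noise_sd))
  } else {
    numeric(nrow(battery))
  }
  tibble(
    subject_id = subject_id,
    session = session,
    test_name = battery$name,
    z_score = deterministic + eps
  )
}

#' Simulate a cohort of subjects
#'
#' One session per profile row. Each subject draws from its own random
#' stream, derived from `seed` by a counter-based mix, so a subject's
#' z-scores do not depend on how many draws other subjects consumed; a
#' profile row carrying an explicit `seed` uses it directly (two identical
#' profiles with the same seed yield identical sessions). Tests are dropped
#' independently with probability `missing_rate`, emulating refusals of
#' single instruments; a draw that would drop every test is redrawn, so
#' each session retains at least one test.
#'
#' @param profiles An [impairment_profile()] tibble, one row per subject.
#' @param battery An [battery()] object.
#' @param missing_rate Probability in `[0, 1)` that any given test is
#'   missing from a session.
#' @param seed Global seed for the cohort.
#' @param session Session label written into the output.
#' @return A long subject-table tibble; subjects are labelled
#'   `sim001, sim002, ...`.
#' @export
simulate_cohort <- function(profiles, battery = default_battery(),
                            missing_rate = 0, seed = 1L, session = "sim") {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1)")
  }
  n <- nrow(profiles)
  ids <- sprintf("sim%03d", seq_len(n))
  purrr::map_dfr(seq_len(n), function(i) {
    p <- profiles[i, ]
    if (is.na(p$seed)) p$seed <- .derive_seed(seed, i)
    sess <- simulate_session(p, battery, subject_id = ids[i],
                             session = session)
    if (missing_rate > 0) {
      keep <- .with_seed(.derive_seed(p$seed, 777L), {
        k <- runif(nrow(sess)) >= missing_rate
        tries <- 0L
        while (!any(k) && tries < 1000L) {  # guarantee a nonempty session
          k <- runif(nrow(sess)) >= missing_rate
          tries <- tries + 1L
        }
        if (!any(k)) k[1] <- TRUE
        k
      })
      sess <- sess[keep, ]
    }
    sess
  })
}

#' Parameter-recovery experiment
#'
#' Simulates a homogeneous cohort with known severities, scores and
#' classifies every subject, and reports the fraction assigned to each
#' deficit class together with the correlation between the absolute index
#' excess `|delta_eta|` and the absolute average z across subjects. A
#' near-zero correlation supports the design premise that the detected
#' VP/VMC imbalance is not driven by the subject's overall level of
#' impairment.
#'
#' @param n_subjects Number of simulated subjects.
#' @param vp_severity,vmc_severity,noise_sd Profile parameters shared by the
#'   cohort, see [impairment_profile()].
#' @param tolerance Balanced-band half-width for classification.
#' @param seed Global seed.
#' @param battery An [battery()] object.
#' @return A one-row tibble with the generating parameters, the expected
#'   class (`sign(vp_severity - vmc_severity)`), per-class classification
#'   rates, and `cor_abs_delta_avg_z` (`NA` when either quantity is
#'   constant, e.g. in noiseless runs).
#' @export
#' @examples
#' recovery_experiment(50, vp_severity = 2, vmc_severity = 0, noise_sd = 0.3,
#'                     seed = 42)
recovery_experiment <- function(n_subjects, vp_severity, vmc_severity,
                                noise_sd = 0, tolerance = 2, seed = 1L,
                                battery = default_battery()) {
  stopifnot(n_subjects >= 1)
  profiles <- impairment_profile(
    vp_severity = rep(vp_severity, n_subjects),
    vmc_severity = rep(vmc_severity, n_subjects),
    noise_sd = noise_sd
  )
  cohort <- simulate_cohort(profiles, battery, seed = seed)
  scores <- suppressWarnings(
    score_sessions(cohort, battery, tolerance = tolerance)
  )
  cls <- scores$classification
  rho <- if (nrow(scores) > 1) {
    suppressWarnings(cor(abs(scores$delta_eta), abs(scores$avg_z)))
  } else {
    NA_real_
  }
  true_class <- if (vp_severity > vmc_severity) {
    "VP_PREVALENT"
  } else if (vmc_severity > vp_severity) {
    "VMC_PREVALENT"
  } else {
    "BALANCED"
  }
  tibble(
    n_subjects = n_subjects,
    vp_severity = vp_severity, vmc_severity = vmc_severity,
    noise_sd = noise_sd, tolerance = tolerance,
    true_class = true_class,
    rate_vp_prevalent = mean(cls == "VP_PREVALENT", na.rm = TRUE),
    rate_vmc_prevalent = mean(cls == "VMC_PREVALENT", na.rm = TRUE),
    rate_balanced = mean(cls == "BALANCED", na.rm = TRUE),
    rate_unclassified = mean(is.na(cls)),
    cor_abs_delta_avg_z = rho
  )
}

# run `code` under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.na(seed)) abort("a seed is required for noisy simulation")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# counter-based seed mix: deterministic per-subject streams below 2^31
.derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(i) * 104729 + 12345) %% 2147483629L)
}
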