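# shared fixtures and an independent scoring oracle

fixture <- function(name) {
  system.file("extdata", name, package = "etamu")
}

read_fixture <- function(name) {
  suppressWarnings(read_subject_table(fixture(name)))
}

# independent oracle: explicit per-term loop summation, no vectorised reuse
# of the implementation's code path
oracle_indices <- function(z, battery) {
  stopifnot(!is.null(names(z)))
  eta_sum <- 0
  mu_sum <- 0
  for (nm in names(z)) {
    row <- which(battery$name == nm)
    eta_sum <- eta_sum + battery$vp_weight[row] * z[[nm]]
    mu_sum <- mu_sum + battery$vmc_weight[row] * z[[nm]]
  }
  n <- length(z)
  list(eta = -eta_sum / n, mu = -mu_sum / n)
}

# random session over a random subset of the battery
random_session <- function(battery, n_tests = NULL) {
  if (is.null(n_tests)) n_tests <- sample.int(nrow(battery), 1)
  tests <- sample(battery$name, n_tests)
  setNames(runif(n_tests, -4, 4), tests)
}

# subject table for a single named z vector
as_table <- function(z, subject_id = "s", session = "pre") {
  tibble::tibble(subject_id = subject_id, session = session,
                 test_name = names(z), z_score = unname(z))
}

expect_row_equal <- function(row, expected, tol = 1e-9) {
  for (col in names(expected)) {
    expect_equal(row[[col]], expected[[col]], tolerance = tol,
                 info = col, ignore_attr = TRUE)
  }
}
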