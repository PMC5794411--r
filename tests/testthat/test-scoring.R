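worked_example <- c(
  corsi_visual = -3, corsi_simultaneous = -2, corsi_sequential = -1.5,
  bhk_quality = -0.5, bhk_velocity = -0.5, tcm_velocity = -1.5,
  tcm_accuracy = -2, rocf_copy = -1.5, rocf_memory = -2, dem_ratio = -2
)

test_that("the worked-example profile reproduces every published quantity", {
  bat <- default_battery()
  expect_equal(average_z(worked_example), -1.65)
  expect_equal(compute_eta(worked_example, bat), 140.5)
  expect_equal(compute_mu(worked_example, bat), 24.5)
  exp_idx <- expected_indices(-1.65, 76, 24)
  expect_equal(exp_idx$eta_exp, 125.4)
  expect_equal(exp_idx$mu_exp, 39.6)
  res <- score_session(worked_example, bat)
  expect_equal(res$delta_eta, 15.1)
  expect_equal(res$classification, "VP_PREVALENT")
})

test_that("zero and uniform profiles behave as the model predicts", {
  bat <- default_battery()
  z0 <- setNames(rep(0, 10), bat$name)
  res0 <- score_session(z0, bat)
  expect_equal(res0$eta, 0)
  expect_equal(res0$mu, 0)
  expect_equal(res0$eta_exp, 0)
  expect_equal(res0$mu_exp, 0)
  expect_equal(res0$classification, "BALANCED")
  # ideal balanced subject: identical z on every test
  z1 <- setNames(rep(-1, 10), bat$name)
  res1 <- score_session(z1, bat)
  expect_equal(res1$eta, 76)
  expect_equal(res1$mu, 24)
  expect_equal(res1$delta_eta, 0)
  expect_equal(res1$delta_mu, 0)
})

test_that("expected indices scale linearly and reject bad weights", {
  e2 <- expected_indices(-2, 76, 24)
  expect_equal(e2$eta_exp, 152)
  expect_equal(e2$mu_exp, 48)
  expect_error(expected_indices(-1, 76, 30), "must equal 100")
})

test_that("incomplete sessions are reweighted over the administered subset", {
  bat <- default_battery()
  s3 <- c(bhk_quality = 0.21, bhk_velocity = -1.48, tcm_velocity = -0.44,
          tcm_accuracy = -3.28, rocf_copy = -0.05, rocf_memory = -2.31,
          dem_ratio = -0.78)
  res <- score_session(s3, bat)
  expect_equal(res$n_tests, 7)
  expect_equal(res$avg_z, -8.13 / 7)
  expect_equal(res$mean_vp, 460 / 7)
  expect_lt(abs(res$eta - 82.70), 0.005)
  expect_lt(abs(res$mu - 33.44), 0.005)
  expect_lt(abs(res$eta_exp - 76.32), 0.005)
  expect_lt(abs(res$mu_exp - 39.82), 0.005)
  expect_equal(res$classification, "VP_PREVALENT")
})

test_that("unknown tests and empty sessions are rejected by name", {
  bat <- default_battery()
  expect_error(compute_eta(c(not_a_test = -1), bat), "not_a_test")
  expect_error(compute_eta(setNames(numeric(0), character(0)), bat),
               "no z-scores")
  expect_error(score_session(c(-1, -2), bat), "named")
})

test_that("classification honours the tolerance band, inclusively at ties", {
  expect_equal(classify_deficit(2.0001, -2.0001, -1, tolerance = 2),
               "VP_PREVALENT")
  expect_equal(classify_deficit(2, -2, -1, tolerance = 2), "BALANCED")
  expect_equal(classify_deficit(-3, 3, -1, tolerance = 2), "VMC_PREVALENT")
  expect_equal(classify_deficit(0.21, -0.21, -0.91, tolerance = 2),
               "BALANCED")
})

test_that("a positive average z withholds classification with a warning", {
  bat <- default_battery()
  z <- setNames(rep(0.5, 10), bat$name)
  expect_warning(res <- score_session(z, bat), "no net impairment")
  expect_true(is.na(res$classification))
  expect_true(res$no_net_impairment)
})

test_that("implausible z-scores warn but are kept", {
  bat <- default_battery()
  z <- c(corsi_visual = -6, dem_ratio = -1)
  expect_warning(res <- score_session(z, bat), "corsi_visual")
  expect_equal(res$n_tests, 2)
})

test_that("eta/mu agree with the loop-summation oracle on random sessions", {
  bat <- default_battery()
  withr::with_seed(101, {
    for (i in 1:300) {
      z <- random_session(bat)
      o <- oracle_indices(z, bat)
      expect_equal(compute_eta(z, bat), o$eta, tolerance = 1e-9)
      expect_equal(compute_mu(z, bat), o$mu, tolerance = 1e-9)
    }
  })
})

test_that("algebraic identities hold on random sessions", {
  bat <- default_battery()
  withr::with_seed(202, {
    for (i in 1:300) {
      z <- random_session(bat)
      res <- suppressWarnings(score_session(z, bat))
      # eta + mu == -100 * avg_z
      expect_equal(res$eta + res$mu, -100 * res$avg_z, tolerance = 1e-9)
      # eta_exp + mu_exp == 100 * |avg_z|
      expect_equal(res$eta_exp + res$mu_exp, 100 * abs(res$avg_z),
                   tolerance = 1e-9)
      # complementarity of the deltas under net impairment
      if (res$avg_z <= 0) {
        expect_equal(res$delta_eta + res$delta_mu, 0, tolerance = 1e-9)
      }
    }
  })
})

test_that("indices scale linearly with the z-profile", {
  bat <- default_battery()
  withr::with_seed(404, {
    for (i in 1:100) {
      z <- -abs(random_session(bat))  # keep avg_z <= 0
      cc <- runif(1, 0.1, 3)
      r1 <- suppressWarnings(score_session(z, bat))
      r2 <- suppressWarnings(score_session(cc * z, bat))
      for (col in c("avg_z", "eta", "mu", "eta_exp", "mu_exp",
                    "delta_eta", "delta_mu")) {
        expect_equal(r2[[col]], cc * r1[[col]], tolerance = 1e-9)
      }
    }
  })
})

test_that("scoring against the full battery equals scoring the restriction", {
  bat <- default_battery()
  withr::with_seed(505, {
    for (i in 1:50) {
      z <- random_session(bat)
      restricted <- battery(bat[bat$name %in% names(z), ],
                            label = "restricted")
      r1 <- suppressWarnings(score_session(z, bat))
      r2 <- suppressWarnings(score_session(z, restricted))
      expect_equal(r1$eta, r2$eta, tolerance = 1e-9)
      expect_equal(r1$mu, r2$mu, tolerance = 1e-9)
      expect_equal(r1$eta_exp, r2$eta_exp, tolerance = 1e-9)
    }
  })
})

test_that("score_sessions scores each (subject, session) group independently", {
  bat <- default_battery()
  tab <- dplyr::bind_rows(
    as_table(worked_example, "a", "pre"),
    as_table(worked_example[1:4] + 0.5, "a", "post"),
    as_table(worked_example[3:10], "b", "pre")
  )
  res <- score_sessions(tab, bat)
  expect_s3_class(res, "etamu_scores")
  expect_equal(nrow(res), 3)
  expect_equal(res$n_tests[res$subject_id == "b"], 8)
  a_pre <- res[res$subject_id == "a" & res$session == "pre", ]
  expect_equal(a_pre$eta, 140.5)
  expect_error(score_sessions(tab[0, ], bat), "empty")
  expect_error(score_sessions(dplyr::bind_rows(tab, tab[1, ]), bat),
               "duplicate")
})

test_that("model lines evaluate the balanced baselines over a grid", {
  ml <- model_lines(c(-1, -2, 0))
  expect_equal(ml$eta_exp, c(76, 152, 0))
  expect_equal(ml$mu_exp, c(24, 48, 0))
  sub <- model_lines(-1, administered = c("bhk_quality", "bhk_velocity"))
  expect_equal(sub$eta_exp, 30)
  expect_equal(sub$mu_exp, 70)
  expect_error(model_lines(numeric(0)), "nonempty")
})

test_that("tidy and glance summarise scored sessions", {
  tab <- read_fixture("table3_pre.csv")
  s <- score_sessions(tab)
  td <- tidy(s)
  expect_equal(nrow(td), 4 * 8)
  expect_true(all(c("statistic", "value") %in% names(td)))
  g <- glance(s)
  expect_equal(g$n_sessions, 4)
  expect_equal(g$median_avg_z, tukey_hinges(s$avg_z)$median)
  expect_equal(g$tolerance, 2)
})
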