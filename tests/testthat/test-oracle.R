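test_that("the synthetic life table hits its life-expectancy target", {
  lt <- generate_life_table()
  a <- attr(lt, "gompertz_a"); b <- attr(lt, "gompertz_b"); A <- attr(lt, "makeham")
  # trapezoidal survivorship integral over the generating hazard
  x <- seq(0, 120, by = 0.05)
  S <- exp(-A * x - a / b * (exp(b * x) - 1))
  le <- sum((S[-1] + S[-length(S)]) / 2) * 0.05
  expect_lt(abs(le - 79), 2)
  expect_true(all(lt$annual_death_rate > 0))
  adult <- lt[lt$age_lo >= 30, ]
  expect_true(all(diff(adult$annual_death_rate) > 0))
  expect_error(generate_life_table(gompertz_b = -0.1), "increasing adult")
})

test_that("a pure Gompertz table is log-linear in age", {
  lt <- generate_life_table(makeham = 0)
  adult <- lt[lt$age_lo >= 40 & lt$age_hi <= 90, ]
  mid <- (adult$age_lo + adult$age_hi) / 2
  fit <- stats::lm(log(adult$annual_death_rate) ~ mid)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
})

test_that("polynomial fit and extrapolation recover the generator rates", {
  lt <- generate_life_table()
  m <- fit_life_table(lt)
  a <- attr(lt, "gompertz_a"); b <- attr(lt, "gompertz_b"); A <- attr(lt, "makeham")
  ages <- seq(0, 90, by = 1)
  truth <- A + a * exp(b * ages)
  fitted <- all_cause_rate(m, ages)
  expect_lt(sqrt(mean((fitted - truth)^2)), 0.05 * mean(truth))
})

test_that("synthetic survival curves sit on the model when noise-free", {
  p <- default_params()
  cv <- generate_survival_curves(p$crc_hazards, p$stage_mix, noise_sd = 0)
  expect_length(cv$stage_5yr, 4)
  expect_equal(nrow(cv$overall_curve), 11)
  for (s in names(cv$stage_5yr)) {
    expect_equal(cv$stage_5yr[[s]],
                 crc_survival(p$crc_hazards[p$crc_hazards$stage == s, ], 5),
                 tolerance = 1e-12)
  }
  expect_equal(cv$overall_curve$survival,
               overall_crc_survival(p$crc_hazards, p$stage_mix, 0:10),
               tolerance = 1e-12)
  # noisy curves are reproducible under a seed and stay in [0, 1]
  n1 <- generate_survival_curves(p$crc_hazards, p$stage_mix, 0.05, seed = 7)
  n2 <- generate_survival_curves(p$crc_hazards, p$stage_mix, 0.05, seed = 7)
  expect_identical(n1, n2)
  expect_true(all(n1$overall_curve$survival >= 0 & n1$overall_curve$survival <= 1))
})

test_that("the distant-stage breakpoint is recovered within a year under noise", {
  # only the distant stage's breakpoint is strongly identified from 15 noisy
  # points (its hazard is steep where the mixture still has curvature); the
  # other stages' breakpoints sit in nearly flat objective directions
  p <- default_params()
  light <- list(b_starts = c(1.5, 4.5, 7.5), permute = TRUE, top = 2)
  errs <- vapply(1:50, function(i) {
    cv <- generate_survival_curves(p$crc_hazards, p$stage_mix, 0.005,
                                   seed = 1000 + i)
    fit <- suppressWarnings(
      fit_breakpoint_model(cv$stage_5yr, cv$overall_curve, p$stage_mix,
                           control = light))
    est <- tidy(fit)
    abs(est$breakpoint[est$stage == "distant"] -
          p$crc_hazards$breakpoint[p$crc_hazards$stage == "distant"])
  }, numeric(1))
  expect_lt(stats::median(errs), 1)
})

test_that("with all rates zero and free colonoscopy every patient accrues identical QALYs", {
  p <- inert_params(zero_mortality = TRUE)
  p$costs$colonoscopy[] <- 0
  p$costs$adverse_event <- 0
  ms <- simulate_patients(200, p, screen_age = 50, follow_up = 10, seed = 3)
  expect_equal(ms$n_screened, 200)
  # closed form: 0.91/year, annual-bucket discounting over 50 years
  expected <- 0.91 * sum(exp(-p$discount_rate * (0:49)))
  expect_equal(ms$summary$estimate[ms$summary$metric == "total_qalys"], expected,
               tolerance = 1e-10)
  expect_equal(ms$summary$se[ms$summary$metric == "total_qalys"], 0, tolerance = 1e-12)
  expect_equal(ms$summary$estimate[ms$summary$metric == "total_cost"], 0)
})

test_that("single-lesion one-year transition shares match the annual table rates", {
  p <- colocea_params(life_table = zero_life_table())
  p$transition_rates[["No adenoma to diminutive"]]$max <- 0  # no arrivals
  p$model$start_age <- 50
  p$model$horizon_age <- 51
  n <- 100000
  ms <- simulate_patients(n, p, screen_age = 50, follow_up = numeric(0), seed = 11,
                          checkpoint_ages = 51,
                          init = list(n_diminutive = 1))
  # after 12 months a single diminutive adenoma has regressed with ~ the
  # annual regression probability and progressed with ~ the annual growth
  # probability (multi-step paths contribute second-order corrections only)
  ck <- ms$checkpoints
  expect_equal(ck$n_alive_undiagnosed, n)
  p_reg <- 0.0181
  se_reg <- sqrt(p_reg * (1 - p_reg) / n)
  expect_lt(abs(ck$p_no_neoplasia - p_reg), 3 * se_reg)
})

test_that("microsimulation standard errors shrink like one over root n", {
  p <- default_params()
  ns <- c(10000, 40000)
  ses <- vapply(ns, function(n) {
    ms <- simulate_patients(n, p, screen_age = 50, follow_up = 10, seed = 21,
                            checkpoint_ages = numeric(0))
    ms$summary$se[ms$summary$metric == "total_qalys"]
  }, numeric(1))
  ratio <- ses[1] / ses[2]
  expect_lt(abs(ratio - 2) / 2, 0.2)
})

test_that("seeded microsimulation runs are exactly reproducible", {
  p <- default_params()
  a <- simulate_patients(2000, p, screen_age = 50, follow_up = 6, seed = 99)
  b <- simulate_patients(2000, p, screen_age = 50, follow_up = 6, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$patients, b$patients)
})
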