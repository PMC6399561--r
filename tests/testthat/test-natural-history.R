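test_that("yearly/monthly probability conversion follows the constant-rate closed form", {
  expect_identical(yearly_to_monthly(0), 0)
  # closed form oracle: p_m solves 1 - (1 - p_m)^12 = p_y
  expect_equal(yearly_to_monthly(0.0163), 1 - (1 - 0.0163)^(1 / 12), tolerance = 1e-15)
  expect_equal(yearly_to_monthly(0.5), 1 - 0.5^(1 / 12), tolerance = 1e-15)
  # compounding twelve months recovers the yearly probability
  for (p in c(0.0163, 0.0181, 0.22, 0.5, 0.97)) {
    expect_equal(monthly_to_yearly(yearly_to_monthly(p)), p, tolerance = 1e-12)
  }
  expect_error(yearly_to_monthly(-0.1), "\\[0, 1\\)")
  expect_error(yearly_to_monthly(1), "\\[0, 1\\)")
})

test_that("adenoma appearance probability ramps linearly with age to its maximum", {
  p <- default_params()
  expect_equal(adenoma_appearance_probability(0, p), 0)
  expect_equal(adenoma_appearance_probability(20, p), 0)
  expect_equal(adenoma_appearance_probability(45, p), 0.04855)  # ramp midpoint
  expect_equal(adenoma_appearance_probability(70, p), 0.0971)
  expect_equal(adenoma_appearance_probability(90, p), 0.0971)
  ages <- seq(0, 100, by = 0.5)
  expect_true(all(diff(adenoma_appearance_probability(ages, p)) >= 0))
  expect_error(adenoma_appearance_probability(-1, p), "non-negative")
})

test_that("state enumeration matches brute-force counting and round-trips indices", {
  expect_error(enumerate_states(0), ">= 1")
  sp1 <- enumerate_states(1)
  crc_free <- sp1$states[sp1$states$stage == "none", ]
  expect_equal(nrow(crc_free), 8)  # 2^3 count combinations
  sp <- small_space()
  # independent brute-force enumerator: counts x stage/symptom configurations
  brute <- expand.grid(d = 0:3, m = 0:3, l = 0:3,
                       cfg = c("none", "loc-a", "loc-s", "reg-a", "reg-s",
                               "dis-a", "dis-s"))
  expect_equal(sp$n, nrow(brute))
  expect_equal(sum(sp$states$n_diminutive == 0 & sp$states$n_medium == 0 &
                     sp$states$n_large == 0 & sp$states$stage == "none"), 1)
  idx <- state_index(sp, sp$states$n_diminutive, sp$states$n_medium,
                     sp$states$n_large, sp$states$stage, sp$states$symptomatic)
  expect_identical(idx, sp$states$index)
})

test_that("kernel rows are stochastic and the yearly kernel is the monthly 12-fold composition", {
  p <- default_params()
  sp <- small_space()
  parts <- colocea:::kernel_parts(p, sp)
  for (age in c(30, 50, 80)) {
    K <- build_kernel(age, p, sp, "month", parts = parts)
    expect_true(all(abs(rowSums(K) - 1) < 1e-9))
    expect_true(all(K >= 0))
  }
  K <- build_kernel(50, p, sp, "month", parts = parts)
  Ky <- build_kernel(50, p, sp, "year", parts = parts)
  expect_true(all(abs(rowSums(Ky) - 1) < 1e-9))
  K12 <- Reduce(`%*%`, replicate(11, K, simplify = FALSE), K)
  expect_lt(max(abs(K12 - Ky)), 1e-8)
})

test_that("single- and two-lesion kernel entries match hand-computed products", {
  p <- default_params()
  sp <- small_space()
  parts <- colocea:::kernel_parts(p, sp)
  m <- yearly_to_monthly
  p_none <- m(0.0181)
  p_med <- m(0.0163) * (1 - p_none)  # growth thinned by regression
  # at age 20 the appearance probability is zero: pure single-lesion tree
  K20 <- build_kernel(20, p, sp, "month", parts = parts)
  i1 <- state_index(sp, 1, 0, 0)
  expect_equal(K20[i1, state_index(sp, 0, 1, 0)], p_med, tolerance = 1e-12)
  expect_equal(K20[i1, state_index(sp, 0, 0, 0)], p_none, tolerance = 1e-12)
  # at age 50 the same transition additionally requires no new arrival
  K50 <- build_kernel(50, p, sp, "month", parts = parts)
  p_arr <- m(adenoma_appearance_probability(50, p))
  expect_equal(K50[i1, state_index(sp, 0, 1, 0)], p_med * (1 - p_arr),
               tolerance = 1e-12)
  # two diminutive adenomas: both regress in one step with probability p_none^2
  i2 <- state_index(sp, 2, 0, 0)
  expect_equal(K50[i2, state_index(sp, 0, 0, 0)], p_none^2 * (1 - p_arr),
               tolerance = 1e-12)
})

test_that("with all transition rates zero the kernel is the identity and CRC never appears", {
  p <- inert_params()
  sp <- small_space()
  K <- build_kernel(50, p, sp, "month")
  expect_equal(K, diag(sp$n), ignore_attr = TRUE)
  dist <- new_cohort(sp, 20)
  dist$und[] <- 0
  dist$und[state_index(sp, 2, 1, 0)] <- 1  # adenomas but no cancer
  hz <- list(all_cause = 0, crc_hazards = p$crc_hazards)
  d <- dist
  for (i in 1:120) d <- propagate(d, K, hz)
  crc_mass <- sum(d$und[sp$states$stage != "none"]) + sum(d$dx) + d$dead_crc
  expect_equal(crc_mass, 0)
  expect_equal(d$und, dist$und)
  expect_equal(d$age, 30, tolerance = 1e-9)
})

test_that("probability mass is conserved over 1200 monthly steps", {
  p <- default_params()
  eng <- colocea:::cea_engine(p)
  dist <- new_cohort(eng$space, age = 0)
  dist <- colocea:::engine_advance(eng, dist, 1200)
  expect_equal(colocea:::total_mass(dist), 1, tolerance = 1e-9)
  expect_equal(dist$age, 100, tolerance = 1e-9)
  expect_true(all(dist$und >= 0) && all(dist$dx >= 0))
})

test_that("raising the adenoma cap from 3 to 5 barely changes 50-year CRC prevalence", {
  prev <- vapply(c(3L, 5L), function(cap) {
    p <- colocea_params()
    p$model$adenoma_cap <- cap
    eng <- colocea:::cea_engine(p)
    d <- colocea:::engine_advance(eng, new_cohort(eng$space, 20), 360)
    st <- d$space$states
    sum(d$und[st$stage != "none"]) + sum(d$dx) + d$dead_crc
  }, numeric(1))
  expect_lt(abs(prev[2] - prev[1]) / prev[1], 0.01)
})

test_that("cohort state marginals agree with the microsimulation oracle", {
  p <- default_params()
  n <- 30000
  ms <- simulate_patients(n, p, screen_age = 50, seed = 101,
                          checkpoint_ages = c(40, 50, 60, 70, 80))
  eng <- colocea:::cea_engine(p)
  # cohort-side marginals, conditioned the same way (alive, undiagnosed,
  # healthy-at-screening)
  d <- colocea:::engine_advance(eng, new_cohort(eng$space, 20), 240)
  marg <- function(d) {
    st <- d$space$states
    v <- d$und / sum(d$und)
    sum(v[st$n_diminutive == 0 & st$n_medium == 0 & st$n_large == 0 &
            st$stage == "none"])
  }
  expected <- c(age40 = marg(d))
  d <- colocea:::engine_advance(eng, d, 120)
  d <- condition_healthy_at_screening(d)
  d <- apply_colonoscopy(d, p$sensitivity)$dist
  expected <- c(expected, age50 = marg(d))
  for (a in c(60, 70, 80)) {
    d <- colocea:::engine_advance(eng, d, 120)
    expected <- c(expected, marg(d))
  }
  ck <- ms$checkpoints
  se <- sqrt(expected * (1 - expected) / ck$n_alive_undiagnosed)
  expect_true(all(abs(ck$p_no_neoplasia - expected) < 3 * se + 1e-12))
})
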