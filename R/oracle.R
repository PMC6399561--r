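#' Generate a synthetic period life table
#'
#' Emits age-banded annual all-cause death rates from a Gompertz-Makeham
#' hazard `h(x) = makeham + a exp(b x)`, with the Gompertz level `a`
#' calibrated so that the implied life expectancy at birth matches
#' `life_expectancy` (US-like, about 79 years, by default). Bands run 0-1,
#' 1-5, then 5-year bands to 90; older ages are left to polynomial
#' extrapolation by [fit_life_table()].
#'
#' @param life_expectancy Target life expectancy at birth (years).
#' @param makeham Age-independent hazard component (per year).
#' @param gompertz_b Exponential slope of the senescent component (per year).
#' @return A tibble with columns `age_lo`, `age_hi`, `annual_death_rate`;
#'   attributes `gompertz_a`, `gompertz_b`, `makeham` record the generating
#'   parameters.
#' @export
#' @examples
#' lt <- generate_life_table()
#' head(lt)
generate_life_table <- function(life_expectancy = 79, makeham = 5e-4,
                                gompertz_b = 0.095) {
  if (makeham < 0 || gompertz_b <= 0) {
    stop("Gompertz-Makeham parameters must imply increasing adult mortality",
         call. = FALSE)
  }
  surv <- function(x, a) exp(-makeham * x - (a / gompertz_b) * (exp(gompertz_b * x) - 1))
  le <- function(a) stats::integrate(surv, 0, 120, a = a, rel.tol = 1e-10)$value
  a <- stats::uniroot(function(la) le(exp(la)) - life_expectancy,
                      lower = log(1e-8), upper = log(1e-2), tol = 1e-12)$root
  a <- exp(a)
  lo <- c(0, 1, seq(5, 85, by = 5))
  hi <- c(1, seq(5, 90, by = 5))
  mid <- (lo + hi) / 2
  out <- tibble::tibble(age_lo = lo, age_hi = hi,
                        annual_death_rate = makeham + a * exp(gompertz_b * mid))
  attr(out, "gompertz_a") <- a
  attr(out, "gompertz_b") <- gompertz_b
  attr(out, "makeham") <- makeham
  out
}

#' Generate synthetic CRC survival data for fitting-recovery tests
#'
#' Produces the two data sources the breakpoint model is fitted to: the four
#' stage-wise 5-year survival points and eleven annual overall-survival
#' points (years 0-10), evaluated from the given breakpoint hazards and
#' stage mixture, with optional additive Gaussian noise truncated to
#' `[0, 1]`.
#'
#' @param hazards Tibble with `stage`, `k1`, `breakpoint`, `k2`.
#' @param mix Stage mixture (weights + normalizer).
#' @param noise_sd Standard deviation of the additive noise (0 = exact).
#' @param seed Optional RNG seed.
#' @return List with `stage_5yr` (named vector) and `overall_curve` (tibble
#'   `years_since_dx`, `survival`).
#' @export
generate_survival_curves <- function(hazards, mix, noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  stages <- names(mix$weights)
  s5 <- vapply(stages, function(s) crc_survival(hazards[hazards$stage == s, ], 5), 0)
  tt <- 0:10
  ov <- overall_crc_survival(hazards, mix, tt)
  if (noise_sd > 0) {
    s5 <- pmin(pmax(s5 + stats::rnorm(length(s5), 0, noise_sd), 0), 1)
    ov <- pmin(pmax(ov + stats::rnorm(length(ov), 0, noise_sd), 0), 1)
  }
  list(stage_5yr = s5,
       overall_curve = tibble::tibble(years_since_dx = tt, survival = ov))
}

#' Individual-level Monte-Carlo microsimulation
#'
#' Simulates patients one month at a time with the identical monthly
#' probabilities, step ordering, caps, and accounting conventions as the
#' cohort model, serving as its brute-force validation oracle: monthly
#' Bernoulli/ binomial draws for lesion transitions (sequential thinning in
#' the same fixed order), at most one new adenoma per month, symptom-triggered
#' immediate diagnosis, all-cause and post-diagnosis mortality, screening
#' conditioning, colonoscopy detection/polypectomy, and discounted cost/QALY
#' tallies from the screening age.
#'
#' @param n Number of patients (>= 1).
#' @param params A [colocea_params()] configuration.
#' @param screen_age Screening colonoscopy age.
#' @param follow_up Follow-up intervals (years after screening), possibly
#'   empty.
#' @param finding Optional finding stratum (one of
#'   `finding_categories()[1:5]`): patients with a different screening
#'   finding are dropped from the accounting cohort.
#' @param seed RNG seed; runs are reproducible for fixed `(n, seed)`.
#' @param checkpoint_ages Ages at which undiagnosed-state marginals are
#'   recorded (conditional on being alive and undiagnosed).
#' @param init Optional initial state shared by every patient: a list with
#'   any of `n_diminutive`, `n_medium`, `n_large`, `stage` (default: no
#'   neoplasia). Useful for single-lesion validation runs.
#' @return A list: `summary` (tibble of estimates with standard errors for
#'   discounted total cost and QALYs), `findings` (screening finding shares
#'   with SEs), `checkpoints` (state marginals by age), `patients` (tibble of
#'   per-patient tallies), `n`, `n_screened`.
#' @export
simulate_patients <- function(n, params = colocea_params(), screen_age = 50,
                              follow_up = numeric(0), finding = NULL,
                              seed = 1,
                              checkpoint_ages = c(40, 50, 60, 70, 80),
                              init = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  p <- params
  cap <- p$model$adenoma_cap
  mp <- monthly_lesion_probs(p)
  ltm <- fit_life_table(effective_life_table(p))
  r <- p$discount_rate
  start <- p$model$start_age
  horizon <- p$model$horizon_age
  n_months <- round((horizon - start) * 12)
  screen_m <- round((screen_age - start) * 12)
  fu_m <- screen_m + round(follow_up * 12)
  unit_colo <- cost_value(p$costs$colonoscopy) + p$costs$adverse_event
  init_cost <- vapply(c("local", "regional", "distant"),
                      function(s) cost_value(p$costs$initial[[s]]), 0)
  surv_cost <- vapply(c("local", "regional", "distant"),
                      function(s) cost_value(p$costs$surveillance[[s]]), 0)
  term_cost <- cost_value(p$costs$terminal)
  u_healthy <- p$utilities[["healthy"]]
  u_dx <- unname(p$utilities[c("local", "regional", "distant")])
  sens <- p$sensitivity

  # sequential-thinning conditionals (exactly the kernel's multinomials)
  c_dn <- mp$diminutive[["none"]]
  c_dm <- mp$diminutive[["medium"]] / (1 - c_dn)
  c_md <- mp$medium[["diminutive"]]
  c_ml <- mp$medium[["large"]] / (1 - c_md)
  c_mc <- mp$medium[["crc"]] / (1 - c_md - mp$medium[["large"]])
  c_lm <- mp$large[["medium"]]
  c_lc <- mp$large[["crc"]] / (1 - c_lm)
  p_sym <- unname(mp$symptom)                    # by stage 1..3
  c_prog <- unname(mp$progress) / (1 - p_sym)    # conditional on no symptoms

  hz <- p$crc_hazards
  k1 <- vapply(c("local", "regional", "distant"), function(s) hz$k1[hz$stage == s], 0)
  k2 <- vapply(c("local", "regional", "distant"), function(s) hz$k2[hz$stage == s], 0)
  bp_m <- vapply(c("local", "regional", "distant"),
                 function(s) hz$breakpoint[hz$stage == s], 0) * 12

  ages <- start + (0:(n_months - 1)) / 12
  q_ac_vec <- 1 - exp(-all_cause_rate(ltm, ages) / 12)
  p_arr_vec <- yearly_to_monthly(adenoma_appearance_probability(ages, p))
  checkpoint_m <- round((checkpoint_ages - start) * 12)

  nd <- nm <- nl <- integer(n)
  stage <- integer(n)            # 0 none, 1 local, 2 regional, 3 distant
  if (!is.null(init)) {
    if (!is.null(init$n_diminutive)) nd[] <- as.integer(init$n_diminutive)
    if (!is.null(init$n_medium)) nm[] <- as.integer(init$n_medium)
    if (!is.null(init$n_large)) nl[] <- as.integer(init$n_large)
    if (!is.null(init$stage)) {
      stage[] <- match(init$stage, c("local", "regional", "distant"), nomatch = 0L)
    }
  }
  dxstage <- integer(n)          # 0 undiagnosed
  mdx <- integer(n)
  alive <- rep(TRUE, n)
  excluded <- rep(FALSE, n)      # conditioned out at screening
  cost <- qaly <- numeric(n)
  death_cause <- rep(NA_character_, n)
  found <- rep(NA_character_, n)
  checkpoints <- vector("list", length(checkpoint_m))

  rbin <- function(size, prob) {
    out <- integer(length(size))
    pos <- size > 0L
    if (any(pos)) out[pos] <- stats::rbinom(sum(pos), size[pos], prob)
    out
  }
  do_colonoscopy <- function(idx, m, charge) {
    # detection, polypectomy, and diagnosis of detected cancers
    if (!length(idx)) return(invisible(NULL))
    disc <- if (m > screen_m || charge) exp(-r * max((m - screen_m - 1) %/% 12, 0)) else 1
    kd <- rbin(nd[idx], sens[["diminutive"]])
    km <- rbin(nm[idx], sens[["medium"]])
    kl <- rbin(nl[idx], sens[["large"]])
    has_crc <- stage[idx] > 0L
    crc_det <- logical(length(idx))
    crc_det[has_crc] <- stats::runif(sum(has_crc)) < sens[["crc"]]
    cat_idx <- adenoma_category(kd + km + kl, kl > 0)
    cat_idx[crc_det] <- 5L + stage[idx][crc_det]
    nd[idx] <<- nd[idx] - kd
    nm[idx] <<- nm[idx] - km
    nl[idx] <<- nl[idx] - kl
    det <- idx[crc_det]
    dxstage[det] <<- stage[det]
    mdx[det] <<- 0L
    if (charge) cost[idx] <<- cost[idx] + unit_colo * disc
    finding_categories()[cat_idx]
  }

  for (m in seq_len(n_months)) {
    post_screen <- m > screen_m
    disc <- if (post_screen) exp(-r * ((m - screen_m - 1) %/% 12)) else 1
    # 1. all-cause death
    la <- which(alive)
    die <- la[stats::runif(length(la)) < q_ac_vec[m]]
    alive[die] <- FALSE
    death_cause[die] <- "other"
    # 2. diagnosed-CRC death, then clock advance
    dxi <- which(alive & dxstage > 0L)
    if (length(dxi)) {
      k <- ifelse(mdx[dxi] < bp_m[dxstage[dxi]], k1[dxstage[dxi]], k2[dxstage[dxi]])
      cdie <- dxi[stats::runif(length(dxi)) < 1 - exp(-k / 12)]
      alive[cdie] <- FALSE
      death_cause[cdie] <- "crc"
      if (post_screen && !all(excluded[cdie])) {
        cc <- cdie[!excluded[cdie]]
        cost[cc] <- cost[cc] + term_cost * disc
      }
      srv <- dxi[alive[dxi]]
      mdx[srv] <- pmin(mdx[srv] + 1L, p$model$dx_month_cap)
    }
    # 3. natural-history transitions among the alive undiagnosed
    ui <- which(alive & dxstage == 0L)
    if (length(ui)) {
      # all class outflows are drawn from start-of-month counts; inflows are
      # added afterwards and the result capped (exactly the kernel's
      # convolution semantics)
      nd0 <- nd[ui]; nm0 <- nm[ui]; nl0 <- nl[ui]
      k_none <- rbin(nd0, c_dn)
      k_med <- rbin(nd0 - k_none, c_dm)
      k_dim <- rbin(nm0, c_md)
      k_lrg <- rbin(nm0 - k_dim, c_ml)
      k_crc <- rbin(nm0 - k_dim - k_lrg, c_mc)
      k_med2 <- rbin(nl0, c_lm)
      k_crc2 <- rbin(nl0 - k_med2, c_lc)
      nd[ui] <- pmin(nd0 - k_none - k_med + k_dim, cap)
      nm[ui] <- pmin(nm0 - k_dim - k_lrg - k_crc + k_med + k_med2, cap)
      nl[ui] <- pmin(nl0 - k_med2 - k_crc2 + k_lrg, cap)
      onset_new <- ui[(k_crc + k_crc2) > 0L & stage[ui] == 0L]
      # established cancer: symptom onset (diagnosis) preempts progression
      ci <- ui[stage[ui] > 0L]
      new_dx <- integer(0)
      if (length(ci)) {
        st0 <- stage[ci]
        usym <- stats::runif(length(ci))
        symp <- usym < p_sym[st0]
        prog <- !symp & stats::runif(length(ci)) < c_prog[st0]
        stage[ci[prog]] <- stage[ci[prog]] + 1L
        new_dx <- ci[symp]
      }
      # malignant transformation observed this month starts a local CRC
      stage[onset_new] <- 1L
      # at most one new adenoma per month
      arr <- ui[stats::runif(length(ui)) < p_arr_vec[m]]
      nd[arr] <- pmin(nd[arr] + 1L, cap)
      # symptom-triggered immediate diagnosis (diagnostic colonoscopy)
      if (length(new_dx)) {
        dxstage[new_dx] <- stage[new_dx]
        mdx[new_dx] <- 0L
        if (post_screen) {
          nn <- new_dx[!excluded[new_dx]]
          cost[nn] <- cost[nn] + unit_colo * disc
        }
      }
    }
    # screening: condition on healthy, then the screening colonoscopy
    if (m == screen_m) {
      excluded[!alive | dxstage > 0L] <- TRUE
      idx <- which(!excluded)
      found[idx] <- do_colonoscopy(idx, m, charge = TRUE)
      if (!is.null(finding)) excluded[!excluded & found != finding] <- TRUE
    }
    if (post_screen && m %in% fu_m) {
      idx <- which(!excluded & alive & dxstage == 0L)
      do_colonoscopy(idx, m, charge = TRUE)
    }
    # monthly accounting (post-screening, conditioned cohort)
    if (post_screen) {
      acc <- which(!excluded & alive)
      if (length(acc)) {
        dxa <- acc[dxstage[acc] > 0L]
        una <- acc[dxstage[acc] == 0L]
        qaly[una] <- qaly[una] + u_healthy / 12 * disc
        if (length(dxa)) {
          qaly[dxa] <- qaly[dxa] + u_dx[dxstage[dxa]] / 12 * disc
          ph_init <- dxa[mdx[dxa] < 12L]
          ph_surv <- dxa[mdx[dxa] >= 12L & mdx[dxa] < 60L]
          cost[ph_init] <- cost[ph_init] + init_cost[dxstage[ph_init]] / 12 * disc
          cost[ph_surv] <- cost[ph_surv] + surv_cost[dxstage[ph_surv]] / 12 * disc
        }
      }
    }
    ck <- match(m, checkpoint_m)
    if (!is.na(ck)) {
      au <- which(alive & dxstage == 0L & !excluded)
      checkpoints[[ck]] <- tibble::tibble(
        age = start + m / 12,
        n_alive_undiagnosed = length(au),
        p_no_neoplasia = mean(nd[au] == 0L & nm[au] == 0L & nl[au] == 0L &
                                stage[au] == 0L),
        p_crc = mean(stage[au] > 0L),
        p_alive = mean(alive[!excluded])
      )
    }
  }

  kept <- which(!excluded)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- tibble::tibble(
    metric = c("total_cost", "total_qalys"),
    estimate = c(mean(cost[kept]), mean(qaly[kept])),
    se = c(se(cost[kept]), se(qaly[kept]))
  )
  shares <- table(factor(found[kept], levels = finding_categories()))
  nk <- length(kept)
  findings <- tibble::tibble(
    category = finding_categories(),
    share = as.numeric(shares) / max(nk, 1),
    se = sqrt(pmax(as.numeric(shares) / nk * (1 - as.numeric(shares) / nk), 0) / nk)
  )
  list(
    summary = summary,
    findings = findings,
    checkpoints = dplyr::bind_rows(checkpoints),
    patients = tibble::tibble(
      patient = kept, cost = cost[kept], qaly = qaly[kept],
      finding = found[kept], dx_stage = dxstage[kept],
      alive = alive[kept], death_cause = death_cause[kept]
    ),
    n = n, n_screened = nk
  )
}
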