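# Engine: precomputed pieces shared by every scenario run under one
# parameter configuration (kernel parts, fitted life table, diagnosed-CRC
# monthly death probabilities, cost settings).
cea_engine <- function(params,
                       colonoscopy_setting = "base",
                       cancer_setting = "base",
                       discount = NULL) {
  validate_params(params)
  space <- enumerate_states(params$model$adenoma_cap)
  key <- rlang::hash(list("kparts", lesion_rates(params), params$model$adenoma_cap))
  kp <- .colocea_cache[[key]]
  if (is.null(kp)) {
    kp <- kernel_parts(params, space)
    .colocea_cache[[key]] <- kp
  }
  ltm <- fit_life_table(effective_life_table(params))
  list(
    params = params, space = kp$space, kp = kp, ltm = ltm,
    q_dx = dx_death_probs(params$crc_hazards),
    discount = if (is.null(discount)) params$discount_rate else discount,
    colonoscopy_setting = colonoscopy_setting,
    cancer_setting = cancer_setting,
    unit_colonoscopy = cost_value(params$costs$colonoscopy, colonoscopy_setting) +
      params$costs$adverse_event
  )
}

# Advance a cohort by `n_months` monthly steps without economic accounting.
engine_advance <- function(eng, dist, n_months) {
  K0 <- eng$kp$K0; K1 <- eng$kp$K1
  for (m in seq_len(n_months)) {
    age <- dist$age
    p_arr <- yearly_to_monthly(adenoma_appearance_probability(age, eng$params))
    q_ac <- 1 - exp(-all_cause_rate(eng$ltm, age) / 12)
    dist <- cohort_step(
      dist,
      und_transform = function(v) {
        (1 - p_arr) * as.numeric(v %*% K0) + p_arr * as.numeric(v %*% K1)
      },
      q_ac = q_ac, q_dx = eng$q_dx, months = 1L
    )
  }
  dist
}

# Conditioned cohort at the screening age (cached: identical across cost and
# discount settings).
engine_prescreen <- function(eng, screen_age) {
  p <- eng$params
  key <- rlang::hash(list("prescreen", lesion_rates(p),
                          p$transition_rates[["No adenoma to diminutive"]],
                          p$crc_hazards, p$model, effective_life_table(p), screen_age))
  cached <- .colocea_cache[[key]]
  if (!is.null(cached)) return(cached)
  dist <- new_cohort(eng$space, age = p$model$start_age)
  dist <- engine_advance(eng, dist, round((screen_age - p$model$start_age) * 12))
  dist <- condition_healthy_at_screening(dist)
  .colocea_cache[[key]] <- dist
  dist
}

# Post-screening run with full economic accounting. `dist` is the cohort
# immediately after the screening colonoscopy (dx may hold screen-detected
# cancers); scheduled follow-ups get P_colonoscopy = 1 among the alive
# undiagnosed. Returns the annual ledger plus discounted totals.
engine_post_run <- function(eng, dist, screen_age, follow_up_ages = numeric(0),
                            screening_cost_mass = 1) {
  p <- eng$params
  horizon <- p$model$horizon_age
  n_months <- round((horizon - screen_age) * 12)
  n_years <- ceiling(n_months / 12)
  fu_months <- sort(round((follow_up_ages - screen_age) * 12))
  cost_colo <- numeric(n_years); cost_crc <- numeric(n_years)
  qalys <- numeric(n_years); p_colo <- numeric(n_years)
  # screening colonoscopy itself (identical across compared arms)
  cost_colo[1] <- cost_colo[1] + screening_cost_mass * eng$unit_colonoscopy
  p_colo[1] <- p_colo[1] + screening_cost_mass
  init_cost <- vapply(c("local", "regional", "distant"),
                      function(s) cost_value(p$costs$initial[[s]], eng$cancer_setting), 0)
  surv_cost <- vapply(c("local", "regional", "distant"),
                      function(s) cost_value(p$costs$surveillance[[s]], eng$cancer_setting), 0)
  term_cost <- cost_value(p$costs$terminal, eng$cancer_setting)
  u <- p$utilities
  u_dx <- u[c("local", "regional", "distant")]
  K0 <- eng$kp$K0; K1 <- eng$kp$K1
  for (m in seq_len(n_months)) {
    yr <- (m - 1) %/% 12 + 1
    age <- dist$age
    p_arr <- yearly_to_monthly(adenoma_appearance_probability(age, eng$params))
    q_ac <- 1 - exp(-all_cause_rate(eng$ltm, age) / 12)
    dist <- cohort_step(
      dist,
      und_transform = function(v) {
        (1 - p_arr) * as.numeric(v %*% K0) + p_arr * as.numeric(v %*% K1)
      },
      q_ac = q_ac, q_dx = eng$q_dx, months = 1L
    )
    # symptom-triggered diagnostic colonoscopies
    p_sym <- sum(dist$flows$sym_dx)
    p_colo[yr] <- p_colo[yr] + p_sym
    cost_colo[yr] <- cost_colo[yr] + p_sym * eng$unit_colonoscopy
    # scheduled follow-up among the alive undiagnosed
    if (m %in% fu_months) {
      mass <- sum(dist$und)
      res <- apply_colonoscopy(dist, p$sensitivity)
      dist <- res$dist
      p_colo[yr] <- p_colo[yr] + mass
      cost_colo[yr] <- cost_colo[yr] + mass * eng$unit_colonoscopy
    }
    # phase-based CRC treatment costs (annual costs accrued monthly)
    dxm <- dist$dx
    m_init <- rowSums(dxm[, 1:12, drop = FALSE])
    m_surv <- rowSums(dxm[, 13:60, drop = FALSE])
    cost_crc[yr] <- cost_crc[yr] + sum(m_init * init_cost) / 12 +
      sum(m_surv * surv_cost) / 12 +
      sum(dist$flows$crc_deaths) * term_cost
    qalys[yr] <- qalys[yr] +
      (sum(dist$und) * u[["healthy"]] + sum(rowSums(dxm) * u_dx)) / 12
  }
  ledger <- tibble::tibble(
    age = screen_age + seq_len(n_years) - 1,
    p_colonoscopy = p_colo, cost_colonoscopy = cost_colo,
    cost_crc = cost_crc, qalys = qalys
  )
  totals <- lifetime_totals(ledger, rate = eng$discount, anchor = screen_age)
  list(totals = totals, ledger = ledger, dist = dist)
}

# Post-screening starting state for a finding stratum (or the whole cohort).
screening_state <- function(eng, screen_age, finding = "all findings") {
  pre <- engine_prescreen(eng, screen_age)
  scr <- apply_colonoscopy(pre, eng$params$sensitivity,
                           stratify = !identical(finding, "all findings"))
  if (identical(finding, "all findings")) {
    list(dist = scr$dist, findings = scr$findings)
  } else {
    if (!finding %in% finding_categories()[1:5]) {
      stop("unknown finding stratum: ", finding, call. = FALSE)
    }
    d <- scr$strata[[finding]]
    if (is.null(d)) stop("finding stratum has zero probability", call. = FALSE)
    list(dist = d, findings = scr$findings)
  }
}

#' Run a single screening / follow-up scenario
#'
#' Propagates a birth cohort to the screening age, conditions on being
#' healthy (undiagnosed and alive) at screening, applies the screening
#' colonoscopy, optionally conditions on a screening finding stratum, then
#' propagates to age 100 with symptom-triggered diagnosis and any scheduled
#' follow-up colonoscopies, accumulating discounted costs and QALYs.
#'
#' @param params A [colocea_params()] configuration.
#' @param screen_age Screening colonoscopy age (years).
#' @param follow_up Numeric vector of follow-up intervals in years after
#'   screening (possibly empty = screening-only control).
#' @param finding `"all findings"` or one of the five adenoma finding
#'   categories from [finding_categories()].
#' @param colonoscopy_setting,cancer_setting Cost settings: `"base"`,
#'   `"low"`, or `"high"`.
#' @param discount Annual discount rate; defaults to `params$discount_rate`.
#' @return An object of class `colocea_scenario`: discounted `totals`
#'   (cost, QALYs), the per-year `ledger`, and the screening `findings`
#'   distribution.
#' @export
#' @examples
#' \donttest{
#' sc <- run_scenario(colocea_params(), screen_age = 50, follow_up = 10)
#' sc$totals
#' }
run_scenario <- function(params = colocea_params(), screen_age = 50,
                         follow_up = numeric(0), finding = "all findings",
                         colonoscopy_setting = "base", cancer_setting = "base",
                         discount = NULL) {
  eng <- cea_engine(params, colonoscopy_setting, cancer_setting, discount)
  st <- screening_state(eng, screen_age, finding)
  run <- engine_post_run(eng, st$dist, screen_age,
                         follow_up_ages = screen_age + follow_up)
  structure(
    list(totals = run$totals, ledger = run$ledger, findings = st$findings,
         final = run$dist, screen_age = screen_age, follow_up = follow_up,
         finding = finding, discount = eng$discount),
    class = "colocea_scenario"
  )
}

#' @export
print.colocea_scenario <- function(x, ...) {
  cat("<colocea_scenario> screen age", x$screen_age,
      "| follow-up:", if (length(x$follow_up)) paste(x$follow_up, collapse = ", ") else "none",
      "| finding:", x$finding, "\n")
  cat(sprintf("  discounted totals: $%.2f, %.4f QALYs (r = %g)\n",
              x$totals$total_cost, x$totals$total_qalys, x$discount))
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `colocea_scenario`.
#' @param ... Unused.
#' @export
glance.colocea_scenario <- function(x, ...) {
  tibble::tibble(
    screen_age = x$screen_age,
    follow_up = paste(x$follow_up, collapse = ","),
    finding = x$finding, discount = x$discount,
    total_cost = x$totals$total_cost, total_qalys = x$totals$total_qalys
  )
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (cost_intervention - cost_control) / (QALY_intervention -
#' QALY_control)`. Dominance is flagged explicitly: `"dominant"` when the
#' intervention saves cost and gains QALYs, `"dominated"` when it costs more
#' and loses QALYs.
#'
#' @param intervention,control `colocea_scenario` objects (or one-row tibbles
#'   with `total_cost` and `total_qalys`).
#' @return A one-row tibble: `d_cost`, `d_qalys`, `icer`, `classification`.
#' @export
icer <- function(intervention, control) {
  g <- function(x) if (inherits(x, "colocea_scenario")) x$totals else x
  a <- g(intervention); b <- g(control)
  d_cost <- a$total_cost - b$total_cost
  d_qalys <- a$total_qalys - b$total_qalys
  if (abs(d_qalys) < 1e-12) {
    stop("ICER undefined: QALY difference is numerically zero", call. = FALSE)
  }
  classification <- if (d_cost <= 0 && d_qalys > 0) "dominant"
  else if (d_qalys < 0 && d_cost >= 0) "dominated"
  else "tradeoff"
  tibble::tibble(d_cost = d_cost, d_qalys = d_qalys,
                 icer = d_cost / d_qalys, classification = classification)
}

#' Per-interval cost-effectiveness grid
#'
#' Runs the screening-only control and every follow-up interval on the grid
#' (default 2-20 years in 2-year steps) for one screening age and finding
#' stratum, and computes each interval's incremental cost, QALYs, and ICER
#' against the control.
#'
#' @inheritParams run_scenario
#' @param intervals Follow-up intervals (years after screening) to evaluate.
#' @return A tibble of class `colocea_grid` with columns `interval`,
#'   `total_cost`, `total_qalys`, `d_cost`, `d_qalys`, `icer`; the control
#'   totals and the screening finding distribution are attached as
#'   attributes `control` and `findings`.
#' @export
interval_grid <- function(params = colocea_params(), screen_age = 50,
                          intervals = seq(2, 20, by = 2),
                          finding = "all findings",
                          colonoscopy_setting = "base", cancer_setting = "base",
                          discount = NULL) {
  eng <- cea_engine(params, colonoscopy_setting, cancer_setting, discount)
  st <- screening_state(eng, screen_age, finding)
  control <- engine_post_run(eng, st$dist, screen_age)
  rows <- purrr::map_dfr(intervals, function(iv) {
    run <- engine_post_run(eng, st$dist, screen_age,
                           follow_up_ages = screen_age + iv)
    tibble::tibble(interval = iv,
                   total_cost = run$totals$total_cost,
                   total_qalys = run$totals$total_qalys)
  })
  rows <- rows |>
    dplyr::mutate(
      d_cost = .data$total_cost - control$totals$total_cost,
      d_qalys = .data$total_qalys - control$totals$total_qalys,
      icer = ifelse(abs(.data$d_qalys) < 1e-12, NA_real_,
                    .data$d_cost / .data$d_qalys)
    )
  attr(rows, "control") <- control$totals
  attr(rows, "findings") <- st$findings
  attr(rows, "screen_age") <- screen_age
  attr(rows, "finding") <- finding
  class(rows) <- c("colocea_grid", class(rows))
  rows
}

#' Cost-effective follow-up window at a willingness-to-pay threshold
#'
#' Finds the maximal contiguous run of grid intervals with `ICER <= threshold`
#' and positive QALY gain, then refines both endpoints by linear interpolation
#' of the ICER-vs-interval curve at the threshold crossing (endpoints at the
#' grid edge stay at the edge).
#'
#' @param grid An [interval_grid()] result.
#' @param threshold Willingness-to-pay in USD per QALY gained.
#' @return A one-row tibble: `threshold`, `lo`, `hi` (NA when no interval is
#'   cost-effective), and `n_grid` (number of in-window grid points).
#' @export
cost_effective_window <- function(grid, threshold) {
  ok <- !is.na(grid$icer) & grid$icer <= threshold & grid$d_qalys > 0
  if (!any(ok)) {
    return(tibble::tibble(threshold = threshold, lo = NA_real_, hi = NA_real_,
                          n_grid = 0L))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  true_runs <- which(runs$values)
  best <- true_runs[which.max(runs$lengths[true_runs])]
  i0 <- starts[best]; i1 <- ends[best]
  interp <- function(i_out, i_in) {
    # threshold crossing between an out-of-window and an in-window grid point
    x0 <- grid$interval[i_out]; x1 <- grid$interval[i_in]
    y0 <- grid$icer[i_out]; y1 <- grid$icer[i_in]
    if (is.na(y0) || grid$d_qalys[i_out] <= 0) return(grid$interval[i_in])
    x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  }
  lo <- if (i0 == 1) grid$interval[1] else interp(i0 - 1, i0)
  hi <- if (i1 == nrow(grid)) grid$interval[nrow(grid)] else interp(i1 + 1, i1)
  tibble::tibble(threshold = threshold, lo = lo, hi = hi,
                 n_grid = i1 - i0 + 1L)
}

#' Quadratic-interpolation optimal follow-up interval
#'
#' Among cost-effective grid intervals, locates the one with the largest QALY
#' gain and fits a parabola through that point and its two grid neighbours;
#' the vertex is the recommended interval and the parabola's value there is
#' the QALY gain, reported per 10,000 persons. When the maximum sits at a
#' grid boundary (or the three points are collinear) the grid point itself is
#' returned with a flag.
#'
#' @param grid An [interval_grid()] result.
#' @param window A [cost_effective_window()] row restricting the candidate
#'   intervals; omit to optimize over the whole grid.
#' @return One-row tibble: `interval`, `d_qalys`, `d_qalys_per_10k`, `flag`
#'   (`"interior"`, `"boundary"`, or `"degenerate"`).
#' @export
optimal_interval <- function(grid, window = NULL) {
  cand <- seq_len(nrow(grid))
  if (!is.null(window)) {
    if (is.na(window$lo)) {
      return(tibble::tibble(interval = NA_real_, d_qalys = NA_real_,
                            d_qalys_per_10k = NA_real_, flag = "empty_window"))
    }
    cand <- which(grid$interval >= window$lo - 1e-9 &
                    grid$interval <= window$hi + 1e-9)
  }
  y_cand <- grid$d_qalys[cand]
  best_cands <- cand[y_cand >= max(y_cand) - 1e-15]
  i <- max(best_cands)  # ties: prefer the longer interval (fewer colonoscopies)
  if (i == 1 || i == nrow(grid)) {
    out <- tibble::tibble(interval = grid$interval[i], d_qalys = grid$d_qalys[i],
                          d_qalys_per_10k = grid$d_qalys[i] * 1e4, flag = "boundary")
    return(out)
  }
  x <- grid$interval[(i - 1):(i + 1)]
  y <- grid$d_qalys[(i - 1):(i + 1)]
  curv <- y[1] - 2 * y[2] + y[3]
  if (abs(curv) < 1e-18) {
    return(tibble::tibble(interval = x[2], d_qalys = y[2],
                          d_qalys_per_10k = y[2] * 1e4, flag = "degenerate"))
  }
  h <- x[2] - x[1]
  xv <- x[2] + h * (y[1] - y[3]) / (2 * curv)
  yv <- y[2] - (y[1] - y[3])^2 / (8 * curv)
  if (!is.null(window)) xv <- min(max(xv, window$lo), window$hi)
  tibble::tibble(interval = xv, d_qalys = yv, d_qalys_per_10k = yv * 1e4,
                 flag = "interior")
}

#' Optimize the follow-up interval for a screening age and finding
#'
#' End-to-end: interval grid, cost-effective window at the threshold, and the
#' quadratic-interpolated recommended interval with its QALY gain.
#'
#' @inheritParams interval_grid
#' @param threshold Willingness-to-pay threshold in USD per QALY.
#' @return A one-row tibble of class `cea_outcome`: screening age, finding,
#'   threshold, window endpoints, recommended `interval`, `d_qalys_per_10k`,
#'   and the minimum grid ICER. The full grid is attached as attribute
#'   `grid`.
#' @export
optimize_follow_up <- function(params = colocea_params(), screen_age = 50,
                               threshold = 1e5, finding = "all findings",
                               intervals = seq(2, 20, by = 2),
                               colonoscopy_setting = "base",
                               cancer_setting = "base", discount = NULL) {
  grid <- interval_grid(params, screen_age, intervals, finding,
                        colonoscopy_setting, cancer_setting, discount)
  win <- cost_effective_window(grid, threshold)
  opt <- optimal_interval(grid, win)
  out <- tibble::tibble(
    screen_age = screen_age, finding = finding, threshold = threshold,
    window_lo = win$lo, window_hi = win$hi,
    interval = opt$interval, d_qalys_per_10k = opt$d_qalys_per_10k,
    # the ICER floor among intervals that actually gain QALYs
    min_icer = {
      ok <- !is.na(grid$icer) & grid$d_qalys > 0
      if (any(ok)) min(grid$icer[ok]) else NA_real_
    },
    flag = opt$flag
  )
  attr(out, "grid") <- grid
  class(out) <- c("cea_outcome", class(out))
  out
}

#' Greedy multi-colonoscopy schedule optimization
#'
#' Accepts follow-up colonoscopies one at a time: at each round the next
#' exam's interval (after the previously accepted exam) is optimized exactly
#' as for a single follow-up, against the current schedule as control; the
#' exam is added while its marginal ICER stays within the threshold. Used
#' chiefly for the undiscounted sensitivity analysis, where several
#' follow-ups can be cost-effective.
#'
#' @inheritParams optimize_follow_up
#' @param max_follow_ups Safety cap on the number of accepted exams.
#' @return A list with `schedule` (accepted follow-up ages), `intervals`
#'   (years between consecutive exams), and `d_qalys_per_10k` (total gain of
#'   the full schedule vs screening only).
#' @export
optimize_schedule <- function(params = colocea_params(), screen_age = 50,
                              threshold = 1e5, finding = "all findings",
                              intervals = seq(2, 20, by = 2),
                              colonoscopy_setting = "base",
                              cancer_setting = "base", discount = NULL,
                              max_follow_ups = 6) {
  eng <- cea_engine(params, colonoscopy_setting, cancer_setting, discount)
  st <- screening_state(eng, screen_age, finding)
  schedule <- numeric(0)
  control <- engine_post_run(eng, st$dist, screen_age)$totals
  base_control <- control
  repeat {
    last <- if (length(schedule)) max(schedule) else screen_age
    cand <- intervals[last + intervals < eng$params$model$horizon_age]
    if (!length(cand) || length(schedule) >= max_follow_ups) break
    rows <- purrr::map_dfr(cand, function(iv) {
      run <- engine_post_run(eng, st$dist, screen_age,
                             follow_up_ages = c(schedule, last + iv))
      tibble::tibble(interval = iv,
                     total_cost = run$totals$total_cost,
                     total_qalys = run$totals$total_qalys)
    })
    rows <- rows |>
      dplyr::mutate(
        d_cost = .data$total_cost - control$total_cost,
        d_qalys = .data$total_qalys - control$total_qalys,
        icer = ifelse(abs(.data$d_qalys) < 1e-12, NA_real_,
                      .data$d_cost / .data$d_qalys)
      )
    win <- cost_effective_window(rows, threshold)
    if (is.na(win$lo)) break
    opt <- optimal_interval(rows, win)
    new_age <- last + opt$interval
    run <- engine_post_run(eng, st$dist, screen_age,
                           follow_up_ages = c(schedule, new_age))
    schedule <- c(schedule, new_age)
    control <- run$totals
  }
  list(
    schedule = schedule,
    intervals = diff(c(screen_age, schedule)),
    d_qalys_per_10k = (control$total_qalys - base_control$total_qalys) * 1e4
  )
}

#' One-way sensitivity analysis
#'
#' Re-runs the follow-up optimization varying exactly one axis at a time:
#' colonoscopy cost at its low/high bound, cancer treatment costs at their
#' low/high bounds, or a 0% discount rate.
#'
#' @inheritParams optimize_follow_up
#' @param axes Character vector from `"base"`, `"colonoscopy_low"`,
#'   `"colonoscopy_high"`, `"cancer_low"`, `"cancer_high"`, `"discount_0"`.
#' @param screen_ages Screening ages to evaluate.
#' @param thresholds Willingness-to-pay thresholds.
#' @return A tibble of `cea_outcome` rows with columns `axis`, `threshold`,
#'   `screen_age`, window endpoints, recommended interval and QALY gain.
#' @export
sensitivity_analysis <- function(params = colocea_params(),
                                 axes = c("base", "colonoscopy_low",
                                          "colonoscopy_high", "cancer_low",
                                          "cancer_high", "discount_0"),
                                 screen_ages = 50, thresholds = 1e5,
                                 finding = "all findings",
                                 intervals = seq(2, 20, by = 2)) {
  axes <- match.arg(axes, several.ok = TRUE)
  settings <- list(
    base = list(colo = "base", cancer = "base", discount = NULL),
    colonoscopy_low = list(colo = "low", cancer = "base", discount = NULL),
    colonoscopy_high = list(colo = "high", cancer = "base", discount = NULL),
    cancer_low = list(colo = "base", cancer = "low", discount = NULL),
    cancer_high = list(colo = "base", cancer = "high", discount = NULL),
    discount_0 = list(colo = "base", cancer = "base", discount = 0)
  )
  purrr::map_dfr(axes, function(ax) {
    s <- settings[[ax]]
    purrr::map_dfr(thresholds, function(thr) {
      purrr::map_dfr(screen_ages, function(sa) {
        out <- optimize_follow_up(params, sa, thr, finding, intervals,
                                  colonoscopy_setting = s$colo,
                                  cancer_setting = s$cancer,
                                  discount = s$discount)
        dplyr::mutate(tibble::as_tibble(out), axis = ax, .before = 1)
      })
    })
  })
}
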