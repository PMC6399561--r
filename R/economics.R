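#' Continuous discount multiplier
#'
#' Cash flows and QALYs at age `t` are discounted back to the anchor age
#' `anchor` (the screening age) with the continuous-compounding multiplier
#' `exp(-r (t - anchor))`; with `r = 0` nothing is discounted.
#'
#' @param t Age in years (vectorized), `>= anchor`.
#' @param rate Annual discount rate (default 0.03).
#' @param anchor Anchor age in years.
#' @return Discount multiplier in `(0, 1]`.
#' @export
#' @examples
#' discount_multiplier(60, rate = 0.03, anchor = 50)  # exp(-0.3)
discount_multiplier <- function(t, rate = 0.03, anchor = 0) {
  if (any(t < anchor)) stop("t must not precede the anchor age", call. = FALSE)
  exp(-rate * (t - anchor))
}

#' Expected colonoscopy cost for a step
#'
#' The unit cost of a colonoscopy (procedure plus the expected adverse-event
#' cost) times the probability of receiving one: 1 at scheduled screening and
#' follow-up exams, and the symptomatic-presentation probability otherwise.
#'
#' @param p_colonoscopy Probability of a colonoscopy in `[0, 1]`.
#' @param costs The `costs` block of [colocea_params()].
#' @param setting `"base"`, `"low"`, or `"high"` colonoscopy cost.
#' @return Expected cost in USD.
#' @export
colonoscopy_cost <- function(p_colonoscopy, costs, setting = "base") {
  stopifnot(all(p_colonoscopy >= 0 & p_colonoscopy <= 1))
  p_colonoscopy * (cost_value(costs$colonoscopy, setting) + costs$adverse_event)
}

#' CRC treatment cost for one annual step
#'
#' Phase-based costing: the first year after diagnosis accrues the stage's
#' initial cost, years 2-5 the surveillance cost, and a death from CRC
#' accrues the terminal cost in addition to the year's phase cost.
#'
#' @param diagnosed Tibble with columns `stage`, `year_since_dx` (1-based),
#'   `mass` (probability mass in the compartment for the year).
#' @param dying Named numeric: probability mass dying of CRC this year, by
#'   stage.
#' @param costs The `costs` block of [colocea_params()].
#' @param setting `"base"`, `"low"`, or `"high"` cancer costs.
#' @return Expected cost in USD for the step.
#' @export
crc_phase_costs <- function(diagnosed, dying, costs, setting = "base") {
  total <- 0
  if (!is.null(diagnosed) && nrow(diagnosed) > 0) {
    phase_cost <- function(stage, year) {
      ifelse(year <= 1, vapply(stage, function(s) cost_value(costs$initial[[s]], setting), 0),
             ifelse(year <= 5, vapply(stage, function(s) cost_value(costs$surveillance[[s]], setting), 0),
                    0))
    }
    total <- total + sum(phase_cost(diagnosed$stage, diagnosed$year_since_dx) * diagnosed$mass)
  }
  if (!is.null(dying)) {
    total <- total + sum(unlist(dying)) * cost_value(costs$terminal, setting)
  }
  total
}

#' Expected QALY accrual rate for a cohort distribution
#'
#' The utility-weighted average over health states: alive undiagnosed mass
#' (with or without adenomas or undiagnosed cancer) scores the healthy
#' utility, diagnosed cancer mass the stage utility, and the dead score zero.
#' CRC utilities apply from diagnosis onward.
#'
#' @param dist A `cohort_dist`.
#' @param utilities Named utility vector, e.g. `colocea_params()$utilities`.
#' @return QALYs accrued per year at this instant (expected utility).
#' @export
qaly_step <- function(dist, utilities) {
  sum(dist$und) * utilities[["healthy"]] +
    sum(rowSums(dist$dx) * utilities[c("local", "regional", "distant")]) +
    (dist$dead_other + dist$dead_crc) * utilities[["dead"]]
}

#' Discounted lifetime totals from a per-year ledger
#'
#' Sums discounted colonoscopy costs, CRC treatment costs, and QALYs over the
#' accounting horizon. The ledger rows are annual flows (undiscounted); each
#' year's flow is discounted at its starting age relative to the anchor.
#'
#' @param ledger Tibble with columns `age`, `cost_colonoscopy`, `cost_crc`,
#'   `qalys` (undiscounted annual flows), as produced by [run_scenario()].
#' @param rate Annual discount rate.
#' @param anchor Anchor age (screening age).
#' @return A one-row tibble: `total_cost`, `total_qalys` (discounted).
#' @export
lifetime_totals <- function(ledger, rate = 0.03, anchor = min(ledger$age)) {
  d <- discount_multiplier(ledger$age, rate, anchor)
  tibble::tibble(
    total_cost = sum((ledger$cost_colonoscopy + ledger$cost_crc) * d),
    total_qalys = sum(ledger$qalys * d)
  )
}
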