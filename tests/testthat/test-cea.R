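test_that("ICER arithmetic, dominance flags, and degeneracy errors", {
  a <- tibble::tibble(total_cost = 1100, total_qalys = 10.001)
  b <- tibble::tibble(total_cost = 1000, total_qalys = 10.000)
  out <- icer(a, b)
  expect_equal(out$icer, 100 / 0.001)
  expect_equal(out$classification, "tradeoff")
  expect_error(icer(b, b), "undefined")
  d <- tibble::tibble(total_cost = 900, total_qalys = 10.001)
  expect_equal(icer(d, b)$classification, "dominant")
  e <- tibble::tibble(total_cost = 1100, total_qalys = 9.999)
  expect_equal(icer(e, b)$classification, "dominated")
})

test_that("cost-effective window detection and interpolated endpoints", {
  g <- tibble::tibble(
    interval = seq(2, 20, 2),
    d_qalys = rep(0.01, 10),
    icer = c(150000, 130000, 120000, 90000, 80000, 70000, 75000, 85000, 95000, 120000)
  )
  # all above threshold: empty window
  w0 <- cost_effective_window(g, 5e4)
  expect_true(is.na(w0$lo) && is.na(w0$hi))
  # infinite threshold: the whole grid
  wInf <- cost_effective_window(g, Inf)
  expect_equal(c(wInf$lo, wInf$hi), c(2, 20))
  # at 100k the in-window run is 8..18 years; the threshold crossings sit
  # between grid points 6 and 8 (descending ICER) and 18 and 20 (ascending):
  # hand-solved line intersections
  w <- cost_effective_window(g, 1e5)
  lo_hand <- 6 + (1e5 - 120000) * (8 - 6) / (90000 - 120000)    # 7.333...
  hi_hand <- 18 + (1e5 - 95000) * (20 - 18) / (120000 - 95000)  # 18.4
  expect_equal(w$lo, lo_hand, tolerance = 1e-12)
  expect_equal(w$hi, hi_hand, tolerance = 1e-12)
  expect_equal(w$n_grid, 6L)
})

test_that("quadratic interpolation finds the closed-form vertex", {
  g <- tibble::tibble(interval = c(2, 4, 6, 8, 10, 12),
                      d_qalys = c(1, 2, 10, 12, 11, 3) * 1e-4,
                      icer = 1)
  opt <- optimal_interval(g)
  # vertex through (6,10),(8,12),(10,11): x2 + h (y1 - y3) / (2 (y1 - 2 y2 + y3))
  expect_equal(opt$interval, 8 + 2 * (10 - 11) / (2 * (10 - 24 + 11)), tolerance = 1e-12)
  expect_equal(opt$interval, 25 / 3, tolerance = 1e-12)
  expect_equal(opt$flag, "interior")
  # symmetric points: vertex at the centre
  g2 <- tibble::tibble(interval = c(6, 8, 10), d_qalys = c(1, 2, 1), icer = 1)
  expect_equal(optimal_interval(g2)$interval, 8)
  # collinear points: degenerate parabola, returns the max grid point
  g3 <- tibble::tibble(interval = c(6, 8, 10), d_qalys = c(1, 2, 3), icer = 1)
  o3 <- optimal_interval(g3)
  expect_equal(o3$flag, "boundary")  # maximum sits on the grid edge
  expect_equal(o3$interval, 10)
  g4 <- tibble::tibble(interval = c(4, 6, 8, 10), d_qalys = c(1, 2, 2, 1) * 1e-4,
                       icer = 1)
  # tie at the maximum: prefer the longer interval
  expect_equal(optimal_interval(g4)$interval, 8, tolerance = 0.5)
})

test_that("inert interventions leave QALYs at the no-intervention level", {
  # full lesion dynamics, but detection and symptoms disabled entirely
  p <- colocea_params()
  p$sensitivity <- c(diminutive = 0, medium = 0, large = 0, crc = 0)
  for (nm in grep("symptomatic", names(p$transition_rates), value = TRUE)) {
    p$transition_rates[[nm]] <- 0
  }
  with_fu <- run_scenario(p, 50, follow_up = 10)
  without <- run_scenario(p, 50)
  expect_equal(with_fu$totals$total_qalys, without$totals$total_qalys,
               tolerance = 1e-10)
  # colonoscopies still cost money even when they find nothing
  expect_gt(with_fu$totals$total_cost, without$totals$total_cost)
})

test_that("with zero cancer costs the follow-up arm costs exactly its extra colonoscopies", {
  p <- colocea_params()
  for (s in names(p$costs$initial)) {
    p$costs$initial[[s]][] <- 0
    p$costs$surveillance[[s]][] <- 0
  }
  p$costs$terminal[] <- 0
  ctrl <- run_scenario(p, 50)
  fu <- run_scenario(p, 50, follow_up = 10)
  expect_gt(fu$totals$total_cost, ctrl$totals$total_cost)
  expect_equal(sum(fu$ledger$cost_crc), 0)
  expect_equal(sum(ctrl$ledger$cost_crc), 0)
})

test_that("windows are nested across willingness-to-pay thresholds", {
  g <- grid50()
  w50 <- cost_effective_window(g, 5e4)
  w75 <- cost_effective_window(g, 7.5e4)
  w100 <- cost_effective_window(g, 1e5)
  contains <- function(outer, inner) {
    is.na(inner$lo) ||
      (!is.na(outer$lo) && outer$lo <= inner$lo + 1e-9 && outer$hi >= inner$hi - 1e-9)
  }
  expect_true(contains(w75, w50))
  expect_true(contains(w100, w75))
})

test_that("the recommended interval is invariant to joint rescaling of costs and threshold", {
  g <- grid50()
  w1 <- cost_effective_window(g, 1e5)
  o1 <- optimal_interval(g, w1)
  g2 <- g
  g2$d_cost <- g$d_cost * 3
  g2$icer <- g$icer * 3
  w2 <- cost_effective_window(g2, 3e5)
  o2 <- optimal_interval(g2, w2)
  expect_equal(o1$interval, o2$interval, tolerance = 1e-9)
})

test_that("scenario ledger sums match the discounted totals", {
  sc <- run_scenario(default_params(), 50, follow_up = 8)
  tot <- lifetime_totals(sc$ledger, rate = sc$discount, anchor = 50)
  expect_equal(tot$total_cost, sc$totals$total_cost, tolerance = 1e-8)
  expect_equal(tot$total_qalys, sc$totals$total_qalys, tolerance = 1e-8)
  expect_true(all(is.finite(unlist(sc$totals))))
  expect_lte(sc$totals$total_qalys, 0.91 * 50)
})

test_that("one-way sensitivity axes move ICERs in the expected directions", {
  p <- default_params()
  base <- optimize_follow_up(p, 50, 1e5)
  gb <- attr(base, "grid")
  # base axis through the sensitivity wrapper reproduces the base case
  sa <- sensitivity_analysis(p, axes = "base", screen_ages = 50, thresholds = 1e5)
  expect_equal(sa$interval, base$interval, tolerance = 1e-9)
  expect_equal(sa$d_qalys_per_10k, base$d_qalys_per_10k, tolerance = 1e-9)
  # high colonoscopy cost raises every ICER (QALY differences unchanged)
  gh <- interval_grid(p, 50, colonoscopy_setting = "high")
  expect_true(all(gh$icer > gb$icer))
  expect_equal(gh$d_qalys, gb$d_qalys, tolerance = 1e-9)
  # zero discount rate increases the QALY gain of the recommended follow-up
  g0 <- interval_grid(p, 50, discount = 0)
  expect_true(all(g0$d_qalys > gb$d_qalys))
})

test_that("the greedy schedule's first exam matches the single-follow-up optimum", {
  p <- default_params()
  single <- optimize_follow_up(p, 50, 1e5, discount = 0)
  sched <- optimize_schedule(p, 50, 1e5, discount = 0, max_follow_ups = 1)
  expect_length(sched$schedule, 1)
  expect_equal(sched$intervals[1], single$interval, tolerance = 1e-6)
  expect_gt(sched$d_qalys_per_10k, 0)
  # undiscounted gains exceed the 3%-discounted gain for the same policy
  expect_gt(sched$d_qalys_per_10k,
            optimize_follow_up(p, 50, 1e5)$d_qalys_per_10k)
})
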