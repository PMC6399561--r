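#' Breakpoint-hazard survival after CRC diagnosis
#'
#' Post-diagnosis survival follows `dP/dt = -k(t) P` with a piecewise-constant
#' mortality rate: `k1` per year up to the breakpoint, `k2` thereafter, so
#' `P(t) = exp(-k1 min(t, b) - k2 max(0, t - b))`.
#'
#' @param hazard A list or one-row data frame with `k1`, `breakpoint`, `k2`
#'   (e.g. one row of `colocea_params()$crc_hazards`).
#' @param t Years since diagnosis (vectorized, >= 0).
#' @return Survival probability in `[0, 1]`.
#' @export
#' @examples
#' local <- list(k1 = 0.025, breakpoint = 7.3, k2 = 0.018)
#' crc_survival(local, 5)  # exp(-0.125)
crc_survival <- function(hazard, t) {
  if (any(t < 0)) stop("time since diagnosis must be non-negative", call. = FALSE)
  b <- hazard$breakpoint
  exp(-hazard$k1 * pmin(t, b) - hazard$k2 * pmax(0, t - b))
}

#' Prevalence-weighted overall CRC survival
#'
#' Mixes the stage-specific survival curves by the stage-at-diagnosis
#' prevalence (local 0.44, regional 0.34, distant 0.18, unknown 0.05) and
#' divides by the weight total (1.01).
#'
#' @param hazards Tibble with columns `stage`, `k1`, `breakpoint`, `k2`
#'   covering local, regional, distant, and unknown.
#' @param mix List with `weights` (named by stage) and `normalizer`.
#' @param t Years since diagnosis (vectorized).
#' @return Overall survival probability.
#' @export
overall_crc_survival <- function(hazards, mix, t) {
  stages <- names(mix$weights)
  if (!all(stages %in% hazards$stage)) {
    stop("hazards must cover every stage in the mixture", call. = FALSE)
  }
  acc <- 0
  for (s in stages) {
    acc <- acc + mix$weights[[s]] * crc_survival(hazards[hazards$stage == s, ], t)
  }
  acc / mix$normalizer
}

# Sum-of-squares objective over both data sources: stage-wise 5-year survival
# points plus the overall (mixture) survival curve.
breakpoint_objective <- function(hazards, stage_5yr, overall_curve, mix) {
  stages <- names(mix$weights)
  ord <- match(stages, hazards$stage)
  bp_objective(hazards$k1[ord], hazards$breakpoint[ord], hazards$k2[ord],
               unlist(stage_5yr[stages]), overall_curve$years_since_dx,
               overall_curve$survival, unname(mix$weights), mix$normalizer)
}

# Fast objective on plain vectors (stage-aligned k1, b, k2).
bp_surv <- function(k1, b, k2, t) exp(-k1 * pmin(t, b) - k2 * pmax(0, t - b))
bp_objective <- function(k1, b, k2, s5, t_ov, s_ov, w, norm) {
  ss <- sum((bp_surv(k1, b, k2, 5) - s5)^2)
  mixpred <- numeric(length(t_ov))
  for (j in seq_along(k1)) {
    mixpred <- mixpred + w[j] * bp_surv(k1[j], b[j], k2[j], t_ov)
  }
  ss + sum((mixpred / norm - s_ov)^2)
}

#' Fit the stage-specific breakpoint survival model
#'
#' Jointly fits `(k1, breakpoint, k2)` for each stage to two data sources by
#' unweighted least squares: the stage-wise 5-year survival points and the
#' prevalence-weighted overall survival curve. Optimization is a deterministic
#' multi-start box-constrained quasi-Newton search over
#' `(log k1, breakpoint, log k2)` per stage, polished with Nelder-Mead.
#'
#' @param stage_5yr Named numeric vector of 5-year survival by stage (must
#'   include every stage in `mix$weights`).
#' @param overall_curve Tibble with columns `years_since_dx`, `survival`
#'   (>= 2 points).
#' @param mix Stage mixture as in `colocea_params()$stage_mix`.
#' @param constant_hazard If `TRUE`, constrain `k2 = k1` per stage (single
#'   exponential), for nested-model comparison.
#' @param control List of search settings: `b_starts` (breakpoint values
#'   crossed into the multi-start grid; default `c(1.5, 3.5, 5.5, 7.5)`),
#'   `permute` (restart from stage-permutations of the best candidates'
#'   breakpoints; default `TRUE`), `top` (number of candidates to permute).
#'   A smaller grid with `permute = FALSE` is much faster and adequate for
#'   noisy data.
#' @return An object of class `breakpoint_fit` with the fitted hazards tibble
#'   and the achieved objective; see [tidy.breakpoint_fit()].
#' @export
fit_breakpoint_model <- function(stage_5yr, overall_curve, mix,
                                 constant_hazard = FALSE, control = list()) {
  stages <- names(mix$weights)
  if (length(stage_5yr) < 4 || !all(stages %in% names(stage_5yr))) {
    stop("need a 5-year survival point for every stage in the mixture", call. = FALSE)
  }
  if (nrow(overall_curve) < 2) {
    stop("need at least 2 overall-survival points", call. = FALSE)
  }
  obs <- c(unlist(stage_5yr[stages]), overall_curve$survival)
  if (all(obs >= 1 - 1e-12)) {
    warning("all survival points are 1: objective is flat, returning the boundary solution")
    hz <- tibble::tibble(stage = stages, k1 = 0, breakpoint = 5, k2 = 0)
    return(new_breakpoint_fit(hz, 0, stage_5yr, overall_curve, mix, constant_hazard, 0L))
  }
  ns <- length(stages)
  s5 <- unlist(stage_5yr[stages])
  t_ov <- overall_curve$years_since_dx
  s_ov <- overall_curve$survival
  w <- unname(mix$weights)
  norm <- mix$normalizer
  obj <- function(k1, b, k2) bp_objective(k1, b, k2, s5, t_ov, s_ov, w, norm)
  k_anchor <- pmax(-log(pmax(s5, 1e-6)) / 5, 1e-6)

  if (constant_hazard) {
    fn <- function(lk) obj(exp(lk), rep(5, ns), exp(lk))
    best <- NULL
    for (s in c(1, 0.5, 2)) {
      fit <- stats::optim(log(k_anchor * s), fn, method = "L-BFGS-B",
                          lower = log(1e-8), upper = log(10),
                          control = list(maxit = 500))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    pol <- stats::optim(best$par, fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (pol$value < best$value) best <- pol
    k <- exp(best$par)
    hz <- tibble::tibble(stage = stages, k1 = k, breakpoint = 5, k2 = k)
    return(new_breakpoint_fit(hz, best$value, stage_5yr, overall_curve, mix,
                              TRUE, best$convergence))
  }

  # The least-squares surface of an exponential mixture is riddled with
  # label-exchange local minima whose objectives are within 1e-12 of the
  # global one, so the search has three deterministic phases:
  #   1. Levenberg-Marquardt (analytic Jacobian) from a coarse grid of
  #      breakpoint configurations, with the rates pre-optimized smoothly
  #      (analytic gradients) at each start.
  #   2. Restarts from every stage-permutation of the top candidates'
  #      breakpoints — the coarse phase typically finds the right breakpoint
  #      multiset assigned to the wrong stages.
  #   3. Iterated machine-tolerance LM polish of the winner.
  if (is.null(control$b_starts)) control$b_starts <- c(1.5, 3.5, 5.5, 7.5)
  if (is.null(control$permute)) control$permute <- TRUE
  if (is.null(control$top)) control$top <- 3L
  lowb <- c(rep(0, ns), rep(0.3, ns), rep(0, ns))
  upb <- rep(10, 3 * ns)
  ks <- function(p) p[seq_len(ns)]
  bs <- function(p) p[ns + seq_len(ns)]
  k2s <- function(p) p[2 * ns + seq_len(ns)]
  resid_fn <- function(p) {
    k1 <- ks(p); b <- bs(p); k2 <- k2s(p)
    S5 <- exp(-k1 * pmin(5, b) - k2 * pmax(0, 5 - b))
    A <- outer(t_ov, b, pmin); B <- pmax(outer(t_ov, b, `-`), 0)
    S <- exp(-A %*% diag(k1, ns) - B %*% diag(k2, ns))
    c(S5 - s5, as.numeric(S %*% w) / norm - s_ov)
  }
  jac_fn <- function(p) {
    k1 <- ks(p); b <- bs(p); k2 <- k2s(p)
    A5 <- pmin(5, b); B5 <- pmax(0, 5 - b)
    A <- outer(t_ov, b, pmin); B <- pmax(outer(t_ov, b, `-`), 0)
    S5 <- exp(-k1 * A5 - k2 * B5)
    S <- exp(-A %*% diag(k1, ns) - B %*% diag(k2, ns))
    nr <- ns + length(t_ov)
    J <- matrix(0, nr, 3 * ns)
    ov <- ns + seq_along(t_ov)
    for (j in seq_len(ns)) {
      J[j, j] <- -A5[j] * S5[j]
      J[j, ns + j] <- (k2[j] - k1[j]) * (5 > b[j]) * S5[j]
      J[j, 2 * ns + j] <- -B5[j] * S5[j]
      J[ov, j] <- -(w[j] / norm) * A[, j] * S[, j]
      J[ov, ns + j] <- (w[j] / norm) * (k2[j] - k1[j]) * (t_ov > b[j]) * S[, j]
      J[ov, 2 * ns + j] <- -(w[j] / norm) * B[, j] * S[, j]
    }
    J
  }
  ssq <- function(p) sum(resid_fn(p)^2)
  # smooth rate pre-fit at fixed breakpoints (analytic gradient)
  rates_at <- function(b) {
    A5 <- pmin(5, b); B5 <- pmax(0, 5 - b)
    A <- outer(t_ov, b, pmin); B <- pmax(outer(t_ov, b, `-`), 0)
    fn <- function(k) {
      S5 <- exp(-k[seq_len(ns)] * A5 - k[ns + seq_len(ns)] * B5)
      S <- exp(-A %*% diag(k[seq_len(ns)], ns) - B %*% diag(k[ns + seq_len(ns)], ns))
      sum((S5 - s5)^2) + sum((as.numeric(S %*% w) / norm - s_ov)^2)
    }
    gr <- function(k) {
      k1 <- k[seq_len(ns)]; k2 <- k[ns + seq_len(ns)]
      S5 <- exp(-k1 * A5 - k2 * B5)
      S <- exp(-A %*% diag(k1, ns) - B %*% diag(k2, ns))
      r5 <- S5 - s5
      r <- as.numeric(S %*% w) / norm - s_ov
      c(-2 * r5 * A5 * S5 - 2 * (w / norm) * as.numeric(t(A * S) %*% r),
        -2 * r5 * B5 * S5 - 2 * (w / norm) * as.numeric(t(B * S) %*% r))
    }
    stats::optim(c(k_anchor * 1.5, k_anchor * 0.5), fn, gr, method = "L-BFGS-B",
                 lower = 0, upper = 10,
                 control = list(maxit = 100, factr = 1e5))$par
  }
  lm_from_b <- function(b0) {
    k <- rates_at(b0)
    fit <- suppressWarnings(minpack.lm::nls.lm(
      c(k[seq_len(ns)], b0, k[ns + seq_len(ns)]),
      lower = lowb, upper = upb, fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)))
    list(v = ssq(fit$par), par = fit$par)
  }
  cfgs <- as.matrix(expand.grid(rep(list(control$b_starts), ns)))
  res <- lapply(seq_len(nrow(cfgs)), function(i) lm_from_b(cfgs[i, ]))
  vals <- vapply(res, `[[`, numeric(1), "v")
  top <- res[order(vals)[seq_len(min(control$top, length(res)))]]
  best <- top[[1]]
  if (control$permute) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(ns)), ns)))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == ns), ,
                   drop = FALSE]
    for (cand in top) {
      bset <- bs(cand$par)
      for (r in seq_len(nrow(perms))) {
        st <- lm_from_b(bset[perms[r, ]])
        if (st$v < best$v) best <- st
      }
    }
  }
  p0 <- best$par
  for (r in 1:6) {
    f <- suppressWarnings(minpack.lm::nls.lm(
      p0, lower = lowb, upper = upb, fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 2000,
                                           ftol = .Machine$double.eps,
                                           ptol = .Machine$double.eps,
                                           gtol = 0)))
    if (ssq(f$par) < ssq(p0) * (1 - 1e-12)) p0 <- f$par else break
  }
  hz <- tibble::tibble(stage = stages, k1 = ks(p0), breakpoint = bs(p0),
                       k2 = k2s(p0))
  new_breakpoint_fit(hz, ssq(p0), stage_5yr, overall_curve, mix, FALSE, 0L)
}

new_breakpoint_fit <- function(hazards, objective, stage_5yr, overall_curve,
                               mix, constant_hazard, convergence) {
  structure(
    list(hazards = hazards, objective = objective, stage_5yr = stage_5yr,
         overall_curve = overall_curve, mix = mix,
         constant_hazard = constant_hazard, convergence = convergence),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("<breakpoint_fit>",
      if (x$constant_hazard) "(constant-hazard constraint)" else "", "\n")
  print(x$hazards)
  cat("objective:", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Tidy the fitted breakpoint model
#'
#' @param x A [fit_breakpoint_model()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per stage with `k1`, `breakpoint`, `k2`.
#'   `glance()`: one row with the least-squares objective, the number of
#'   fitted points, and convergence info.
#' @export
tidy.breakpoint_fit <- function(x, ...) x$hazards

#' @rdname tidy.breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_points = length(x$stage_5yr) + nrow(x$overall_curve),
    constant_hazard = x$constant_hazard,
    convergence = x$convergence
  )
}

#' Fit the all-cause mortality polynomial to a life table
#'
#' Fits a sixth-order polynomial (ordinary least squares) to annual death
#' rates plotted against age-band midpoints. Rates above the last tabulated
#' band are extrapolated from the polynomial; negative fitted values clamp
#' to zero.
#'
#' @param life_table Tibble with columns `age_lo`, `age_hi`,
#'   `annual_death_rate`.
#' @param degree Polynomial degree (default 6).
#' @return An object of class `life_table_model`.
#' @export
fit_life_table <- function(life_table, degree = 6L) {
  lt <- tibble::as_tibble(life_table)
  stopifnot(all(c("age_lo", "age_hi", "annual_death_rate") %in% names(lt)))
  mid <- (lt$age_lo + lt$age_hi) / 2
  fit <- stats::lm(lt$annual_death_rate ~ poly(mid, degree, raw = TRUE))
  fitted_rate <- pmax(as.numeric(stats::fitted(fit)), 0)
  structure(
    list(coefficients = stats::coef(fit),
         table = lt, midpoints = mid, degree = degree,
         rmse = sqrt(mean((fitted_rate - lt$annual_death_rate)^2)),
         max_tabulated_age = max(lt$age_hi)),
    class = "life_table_model"
  )
}

#' @export
print.life_table_model <- function(x, ...) {
  cat("<life_table_model> degree", x$degree, "fit to", nrow(x$table), "age bands\n")
  cat("  RMSE:", format(x$rmse, digits = 4),
      " extrapolated beyond age", x$max_tabulated_age, "\n")
  invisible(x)
}

#' @rdname fit_life_table
#' @param x A `life_table_model`.
#' @param ... Unused.
#' @export
glance.life_table_model <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_bands = nrow(x$table), rmse = x$rmse,
                 max_tabulated_age = x$max_tabulated_age)
}

#' Annual all-cause death rate at an age
#'
#' Evaluates the fitted mortality polynomial, clamped at zero below; ages
#' beyond the tabulated range use polynomial extrapolation.
#'
#' @param model A [fit_life_table()] model.
#' @param age Age in years (vectorized), in `[0, 110]`.
#' @return Annual death rate (per year).
#' @export
all_cause_rate <- function(model, age) {
  if (any(age < 0 | age > 110)) stop("age must lie in [0, 110]", call. = FALSE)
  co <- model$coefficients
  val <- outer(age, 0:model$degree, `^`) %*% co
  pmax(as.numeric(val), 0)
}
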