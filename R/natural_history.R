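#' Convert between yearly and monthly transition probabilities
#'
#' Under a constant-rate (exponential waiting time) interpretation, a yearly
#' transition probability `p` corresponds to the monthly probability `p_m`
#' with `1 - (1 - p_m)^12 = p`.
#'
#' @param p_yearly,p_monthly Probability in `[0, 1)`.
#' @return The equivalent probability at the other time scale.
#' @export
#' @examples
#' yearly_to_monthly(0.0163)
#' monthly_to_yearly(yearly_to_monthly(0.0163))
yearly_to_monthly <- function(p_yearly) {
  if (any(p_yearly < 0 | p_yearly >= 1)) {
    stop("yearly probability must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - p_yearly)^(1 / 12)
}

#' @rdname yearly_to_monthly
#' @export
monthly_to_yearly <- function(p_monthly) {
  if (any(p_monthly < 0 | p_monthly >= 1)) {
    stop("monthly probability must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - p_monthly)^12
}

#' Age-dependent annual probability of a new adenoma
#'
#' The annual probability that a new diminutive adenoma appears rises linearly
#' with age from 0 at `ramp_start_age` to the maximum (0.0971 by default) at
#' `plateau_age`, and is constant thereafter. The profile parameters live in
#' `params$transition_rates[["No adenoma to diminutive"]]`.
#'
#' @param age Age in years (vectorized), in `[0, 100]`.
#' @param params A [colocea_params()] object.
#' @return Annual appearance probability in `[0, max]`.
#' @export
adenoma_appearance_probability <- function(age, params = colocea_params()) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  prof <- params$transition_rates[["No adenoma to diminutive"]]
  frac <- (age - prof$ramp_start_age) / (prof$plateau_age - prof$ramp_start_age)
  prof$max * pmin(pmax(frac, 0), 1)
}

# CRC configuration codes for the undiagnosed state space: stage crossed with
# the symptomatic flag (symptomatic only when a cancer is present).
crc_configs <- function() {
  tibble::tibble(
    crc = 1:7,
    stage = c("none", "local", "local", "regional", "regional", "distant", "distant"),
    symptomatic = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Enumerate the colonic state space
#'
#' Every combination of adenoma counts (0..cap per size class) crossed with
#' the CRC configuration (no CRC, or one of local/regional/distant, each
#' asymptomatic or symptomatic) is a state. Counts above the cap are
#' aggregated at the cap by the transition kernel.
#'
#' @param cap Per-size-class adenoma count cap (>= 1).
#' @return An object of class `colon_state_space` with a `states` tibble
#'   (`index`, `n_diminutive`, `n_medium`, `n_large`, `stage`, `symptomatic`)
#'   and an index lookup.
#' @export
#' @examples
#' sp <- enumerate_states(cap = 3)
#' nrow(sp$states)  # (3 + 1)^3 * 7
enumerate_states <- function(cap = 3L) {
  if (!is.numeric(cap) || cap < 1) stop("cap must be >= 1", call. = FALSE)
  cap <- as.integer(cap)
  cfg <- crc_configs()
  grid <- expand.grid(
    n_diminutive = 0:cap, n_medium = 0:cap, n_large = 0:cap,
    crc = 1:7, KEEP.OUT.ATTRS = FALSE
  )
  states <- tibble::as_tibble(grid) |>
    dplyr::left_join(cfg, by = "crc") |>
    dplyr::mutate(index = dplyr::row_number(), .before = 1)
  structure(
    list(cap = cap, states = states, n = nrow(states), n_adenoma = (cap + 1L)^3),
    class = "colon_state_space"
  )
}

#' @export
print.colon_state_space <- function(x, ...) {
  cat("<colon_state_space> cap", x$cap, "-", x$n, "states\n")
  invisible(x)
}

#' Look up the index of a state (and back)
#'
#' @param space A `colon_state_space`.
#' @param n_diminutive,n_medium,n_large Adenoma counts (vectorized).
#' @param stage CRC stage: `"none"`, `"local"`, `"regional"`, `"distant"`.
#' @param symptomatic Logical; only meaningful when `stage != "none"`.
#' @return `state_index()`: integer indices. `state_at()`: a tibble row.
#' @export
state_index <- function(space, n_diminutive, n_medium, n_large,
                        stage = "none", symptomatic = FALSE) {
  cap <- space$cap
  stopifnot(all(n_diminutive >= 0 & n_diminutive <= cap),
            all(n_medium >= 0 & n_medium <= cap),
            all(n_large >= 0 & n_large <= cap))
  if (any(symptomatic & stage == "none")) {
    stop("symptomatic requires a CRC stage", call. = FALSE)
  }
  stage_base <- c(none = 1L, local = 2L, regional = 4L, distant = 6L)
  crc <- stage_base[stage] + as.integer(symptomatic)
  k <- cap + 1L
  as.integer(n_diminutive + k * n_medium + k^2 * n_large + (crc - 1L) * k^3 + 1L)
}

#' @rdname state_index
#' @param index State index.
#' @export
state_at <- function(space, index) space$states[index, ]

# Monthly per-lesion outcome probabilities. Within a month, competing
# outcomes of one lesion are resolved by sequential thinning in a fixed
# order (regression first, then growth, then malignant transformation;
# for an established cancer, symptom onset preempts stage progression).
monthly_lesion_probs <- function(params) {
  r <- lesion_rates(params)
  m <- yearly_to_monthly
  p_dn <- m(r$dim_to_none)
  p_dm <- m(r$dim_to_med) * (1 - p_dn)
  p_md <- m(r$med_to_dim)
  p_ml <- m(r$med_to_lrg) * (1 - p_md)
  p_mc <- m(r$med_to_crc) * (1 - p_md) * (1 - p_ml)
  p_lm <- m(r$lrg_to_med)
  p_lc <- m(r$lrg_to_crc) * (1 - p_lm)
  sym <- c(local = m(r$sym_local), regional = m(r$sym_regional), distant = m(r$sym_distant))
  prog <- c(local = m(r$loc_to_reg) * (1 - sym[["local"]]),
            regional = m(r$reg_to_dis) * (1 - sym[["regional"]]),
            distant = 0)
  list(
    diminutive = c(none = p_dn, medium = p_dm),
    medium = c(diminutive = p_md, large = p_ml, crc = p_mc),
    large = c(medium = p_lm, crc = p_lc),
    symptom = sym, progress = prog
  )
}

# Joint distribution of outcome counts for n i.i.d. lesions of one class:
# columns are the named outcomes plus `stay`, with multinomial probability.
multinomial_outcomes <- function(n, p_out) {
  k <- length(p_out)
  if (n == 0L) {
    df <- as.data.frame(as.list(stats::setNames(rep(0L, k), names(p_out))))
    df$stay <- 0L
    df$prob <- 1
    return(df)
  }
  grid <- expand.grid(rep(list(0:n), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(p_out)
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  grid$stay <- n - rowSums(grid[, names(p_out), drop = FALSE])
  pv <- c(p_out, stay = 1 - sum(p_out))
  grid$prob <- apply(grid[, c(names(p_out), "stay"), drop = FALSE], 1,
                     function(x) stats::dmultinom(x, prob = pv))
  rownames(grid) <- NULL
  grid
}

# Per-(d, m, l) adenoma-block transition table: destination counts after one
# monthly step (capped), plus whether any lesion transformed to cancer.
adenoma_transition_tables <- function(probs, cap) {
  dim_tab <- lapply(0:cap, multinomial_outcomes, p_out = probs$diminutive)
  med_tab <- lapply(0:cap, multinomial_outcomes, p_out = probs$medium)
  lrg_tab <- lapply(0:cap, multinomial_outcomes, p_out = probs$large)
  out <- vector("list", (cap + 1L)^3)
  for (l in 0:cap) for (m in 0:cap) for (d in 0:cap) {
    dt <- dim_tab[[d + 1L]]; mt <- med_tab[[m + 1L]]; lt <- lrg_tab[[l + 1L]]
    idx <- expand.grid(i = seq_len(nrow(dt)), j = seq_len(nrow(mt)),
                       k = seq_len(nrow(lt)), KEEP.OUT.ATTRS = FALSE)
    d2 <- pmin(dt$stay[idx$i] + mt$diminutive[idx$j], cap)
    m2 <- pmin(mt$stay[idx$j] + dt$medium[idx$i] + lt$medium[idx$k], cap)
    l2 <- pmin(lt$stay[idx$k] + mt$large[idx$j], cap)
    onset <- (mt$crc[idx$j] + lt$crc[idx$k]) > 0
    prob <- dt$prob[idx$i] * mt$prob[idx$j] * lt$prob[idx$k]
    key <- d2 + (cap + 1L) * m2 + (cap + 1L)^2 * l2 + (cap + 1L)^3 * onset
    agg <- rowsum(prob, group = key)
    keys <- as.integer(rownames(agg))
    out[[d + (cap + 1L) * m + (cap + 1L)^2 * l + 1L]] <- data.frame(
      a_idx = (keys %% (cap + 1L)^3) + 1L,
      onset = keys %/% (cap + 1L)^3 == 1L,
      prob = as.numeric(agg)
    )
  }
  out
}

# Monthly transition matrix over the 7 CRC configurations (rows = from).
# Symptomatic configurations are absorbing here; the propagation step
# harvests them into the diagnosed compartments.
crc_config_kernel <- function(probs) {
  C <- diag(7)
  # local asymptomatic (2): symptom onset (-> 3) preempts progression (-> 4)
  C[2, 3] <- probs$symptom[["local"]]
  C[2, 4] <- probs$progress[["local"]]
  C[2, 2] <- 1 - C[2, 3] - C[2, 4]
  # regional asymptomatic (4)
  C[4, 5] <- probs$symptom[["regional"]]
  C[4, 6] <- probs$progress[["regional"]]
  C[4, 4] <- 1 - C[4, 5] - C[4, 6]
  # distant asymptomatic (6)
  C[6, 7] <- probs$symptom[["distant"]]
  C[6, 6] <- 1 - C[6, 7]
  C
}

# Precomputed kernel pieces: K0 = monthly kernel without adenoma arrival,
# K1 = K0 followed by the arrival of one diminutive adenoma (capped). The
# age-dependent monthly kernel is (1 - p) K0 + p K1 with p the monthly
# appearance probability at that age.
kernel_parts <- function(params, space) {
  cap <- space$cap
  na <- space$n_adenoma
  probs <- monthly_lesion_probs(params)
  atab <- adenoma_transition_tables(probs, cap)
  C <- crc_config_kernel(probs)
  S <- space$n
  K0 <- matrix(0, S, S)
  for (crc in 1:7) {
    off <- (crc - 1L) * na
    if (crc %in% c(3L, 5L, 7L)) {       # symptomatic: absorbing
      for (a in seq_len(na)) K0[off + a, off + a] <- 1
      next
    }
    dests <- which(C[crc, ] > 0)
    for (a in seq_len(na)) {
      tab <- atab[[a]]
      if (crc == 1L) {
        # no cancer: malignant transformation starts a local asymptomatic CRC
        to <- ifelse(tab$onset, na + tab$a_idx, tab$a_idx)
        agg <- rowsum(tab$prob, group = to)
        K0[off + a, as.integer(rownames(agg))] <-
          K0[off + a, as.integer(rownames(agg))] + as.numeric(agg)
      } else {
        # established cancer: a transforming lesion simply leaves the adenoma
        # pool (one cancer at a time); stage evolves independently
        agg <- rowsum(tab$prob, group = tab$a_idx)
        a2 <- as.integer(rownames(agg))
        pa <- as.numeric(agg)
        for (c2 in dests) {
          K0[off + a, (c2 - 1L) * na + a2] <-
            K0[off + a, (c2 - 1L) * na + a2] + pa * C[crc, c2]
        }
      }
    }
  }
  # arrival shift: one new diminutive adenoma, capped
  st <- space$states
  shift_to <- state_index(space,
                          pmin(st$n_diminutive + 1L, cap), st$n_medium, st$n_large,
                          st$stage, st$symptomatic)
  K1 <- matrix(0, S, S)
  for (i in seq_len(S)) K1[, shift_to[i]] <- K1[, shift_to[i]] + K0[, i]
  list(K0 = K0, K1 = K1, space = space, probs = probs, params = params)
}

#' Build the one-step transition kernel at a given age
#'
#' Combines per-lesion monthly transitions (independent across lesions, joined
#' by multinomial convolution), CRC stage progression and symptom onset, and
#' the age-dependent arrival of at most one new diminutive adenoma per month.
#' The yearly kernel is the 12-fold composition of the monthly kernel with the
#' appearance probability frozen at `age`.
#'
#' @param age Age in years.
#' @param params A [colocea_params()] object.
#' @param space A [enumerate_states()] state space (defaults to the params cap).
#' @param step `"month"` or `"year"`.
#' @param parts Optional precomputed internal kernel pieces (for repeated calls).
#' @return A row-stochastic matrix over the state space, with attributes
#'   `age` and `step_years`.
#' @export
build_kernel <- function(age, params = colocea_params(), space = NULL,
                         step = c("month", "year"), parts = NULL) {
  step <- match.arg(step)
  if (is.null(space)) space <- enumerate_states(params$model$adenoma_cap)
  if (is.null(parts)) parts <- kernel_parts(params, space)
  p <- yearly_to_monthly(adenoma_appearance_probability(age, params))
  K <- (1 - p) * parts$K0 + p * parts$K1
  if (step == "year") {
    K <- Reduce(`%*%`, replicate(11, K, simplify = FALSE), K)
  }
  attr(K, "age") <- age
  attr(K, "step_years") <- if (step == "month") 1 / 12 else 1
  K
}

#' Initialize a cohort distribution
#'
#' All probability mass starts in the neoplasia-free state at `age`.
#'
#' @param space A `colon_state_space`.
#' @param age Starting age in years.
#' @return An object of class `cohort_dist`: probabilities over the
#'   undiagnosed state space, diagnosed-CRC compartments indexed by stage and
#'   months since diagnosis, and death compartments (other-cause and CRC).
#' @export
new_cohort <- function(space, age = 20) {
  und <- numeric(space$n)
  und[state_index(space, 0L, 0L, 0L)] <- 1
  dx <- matrix(0, nrow = 3, ncol = 121,
               dimnames = list(c("local", "regional", "distant"), NULL))
  structure(
    list(age = age, und = und, dx = dx, dead_other = 0, dead_crc = 0,
         space = space, flows = NULL),
    class = "cohort_dist"
  )
}

#' @export
print.cohort_dist <- function(x, ...) {
  cat("<cohort_dist> age", round(x$age, 3), "\n")
  cat("  undiagnosed:", format(sum(x$und), digits = 6),
      " diagnosed:", format(sum(x$dx), digits = 6), "\n")
  cat("  dead (other):", format(x$dead_other, digits = 6),
      " dead (CRC):", format(x$dead_crc, digits = 6), "\n")
  invisible(x)
}

# Total probability mass of a cohort distribution (should be 1).
total_mass <- function(dist) {
  sum(dist$und) + sum(dist$dx) + dist$dead_other + dist$dead_crc
}

# Stage-specific post-diagnosis mortality rate at a time since diagnosis.
crc_rate_at <- function(hazards, stage, years_since_dx) {
  row <- hazards[hazards$stage == stage, ]
  ifelse(years_since_dx < row$breakpoint, row$k1, row$k2)
}

# Monthly diagnosed-CRC death probabilities by (stage, months-since-dx bin).
dx_death_probs <- function(crc_hazards, dt = 1 / 12, n_bins = 121) {
  t_years <- (seq_len(n_bins) - 1) / 12
  q <- matrix(0, 3, n_bins, dimnames = list(c("local", "regional", "distant"), NULL))
  for (s in rownames(q)) {
    q[s, ] <- 1 - exp(-crc_rate_at(crc_hazards, s, t_years) * dt)
  }
  q
}

# One propagation step with preassembled ingredients (shared by propagate()
# and the scenario runner). Order within a step: all-cause death, then
# diagnosed-CRC death + clock advance, then the natural-history kernel on the
# undiagnosed, then harvest of newly symptomatic mass into the diagnosed
# compartments (diagnosis is immediate on symptom onset).
cohort_step <- function(dist, und_transform, q_ac, q_dx, months) {
  alive <- sum(dist$und) + sum(dist$dx)
  ac_deaths <- q_ac * alive
  dist$dead_other <- dist$dead_other + ac_deaths
  dist$und <- dist$und * (1 - q_ac)
  dx <- dist$dx * (1 - q_ac)
  deaths_by_stage <- rowSums(dx * q_dx)
  dist$dead_crc <- dist$dead_crc + sum(deaths_by_stage)
  dx <- dx * (1 - q_dx)
  nb <- ncol(dx)
  if (months >= 1) {
    adv <- matrix(0, nrow(dx), nb, dimnames = dimnames(dx))
    keep <- seq_len(nb - months)
    adv[, keep + months] <- dx[, keep]
    adv[, nb] <- adv[, nb] + rowSums(dx[, (nb - months + 1):nb, drop = FALSE])
    dx <- adv
  }
  dist$und <- und_transform(dist$und)
  space <- dist$space
  sym_dx <- c(local = 0, regional = 0, distant = 0)
  for (s in names(sym_dx)) {
    idx <- which(space$states$stage == s & space$states$symptomatic)
    m <- sum(dist$und[idx])
    if (m > 0) {
      dist$und[idx] <- 0
      dx[s, 1] <- dx[s, 1] + m
      sym_dx[[s]] <- m
    }
  }
  dist$dx <- dx
  dist$age <- dist$age + months / 12
  dist$flows <- list(sym_dx = sym_dx, crc_deaths = deaths_by_stage, ac_deaths = ac_deaths)
  dist
}

#' Propagate a cohort distribution by one step
#'
#' Applies competing all-cause mortality, post-diagnosis CRC mortality with
#' the months-since-diagnosis clock advance, the natural-history kernel, and
#' immediate diagnosis of newly symptomatic cancers. Mass is conserved across
#' the live and death compartments.
#'
#' @param dist A [new_cohort()] distribution.
#' @param kernel A [build_kernel()] matrix on the same state space.
#' @param hazards List with `all_cause` (annual death rate: scalar, or a
#'   function of age) and `crc_hazards` (tibble as in
#'   `colocea_params()$crc_hazards`).
#' @return The advanced `cohort_dist`; `$flows` holds this step's
#'   symptom-triggered diagnoses, CRC deaths, and other-cause deaths.
#' @export
propagate <- function(dist, kernel, hazards) {
  if (length(dist$und) != nrow(kernel)) {
    stop("kernel and distribution are defined on different supports", call. = FALSE)
  }
  dt <- attr(kernel, "step_years")
  if (is.null(dt)) dt <- 1 / 12
  h <- hazards$all_cause
  if (is.function(h)) h <- h(dist$age)
  if (is.null(h)) h <- 0
  q_ac <- 1 - exp(-h * dt)
  n_bins <- ncol(dist$dx)
  if (!is.null(hazards$crc_hazards)) {
    t_years <- (seq_len(n_bins) - 1) / 12
    q_dx <- rbind(
      local = 1 - exp(-crc_rate_at(hazards$crc_hazards, "local", t_years) * dt),
      regional = 1 - exp(-crc_rate_at(hazards$crc_hazards, "regional", t_years) * dt),
      distant = 1 - exp(-crc_rate_at(hazards$crc_hazards, "distant", t_years) * dt)
    )
  } else {
    q_dx <- matrix(0, 3, n_bins, dimnames = list(c("local", "regional", "distant"), NULL))
  }
  cohort_step(dist,
              und_transform = function(v) as.numeric(v %*% kernel),
              q_ac = q_ac, q_dx = q_dx, months = round(dt * 12))
}

#' Tidy view of a cohort distribution
#'
#' @param x A `cohort_dist`.
#' @param ... Unused.
#' @return A tibble with one row per compartment group: the undiagnosed
#'   states joined to their definitions, plus diagnosed-by-stage and death
#'   compartments.
#' @export
tidy.cohort_dist <- function(x, ...) {
  st <- x$space$states |>
    dplyr::mutate(probability = x$und, compartment = "undiagnosed") |>
    dplyr::select("compartment", "n_diminutive", "n_medium", "n_large",
                  "stage", "symptomatic", "probability")
  dx <- tibble::tibble(
    compartment = "diagnosed",
    n_diminutive = NA_integer_, n_medium = NA_integer_, n_large = NA_integer_,
    stage = rownames(x$dx), symptomatic = NA,
    probability = rowSums(x$dx)
  )
  dead <- tibble::tibble(
    compartment = c("dead_other", "dead_crc"),
    n_diminutive = NA_integer_, n_medium = NA_integer_, n_large = NA_integer_,
    stage = NA_character_, symptomatic = NA,
    probability = c(x$dead_other, x$dead_crc)
  )
  dplyr::bind_rows(st, dx, dead)
}
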