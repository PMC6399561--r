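#' The eight clinical finding categories
#'
#' Colonoscopy results are classified by the detected lesions only: detected
#' adenoma count (1-2 vs 3+), whether any detected adenoma is advanced
#' (large, >= 10 mm), and detected CRC by stage.
#'
#' @return Character vector of the eight category labels, in canonical order.
#' @export
finding_categories <- function() {
  c("no adenomas",
    "1-2 nonadvanced only",
    "3+ nonadvanced only",
    "1-2 with some advanced",
    "3+ with some advanced",
    "local CRC",
    "regional CRC",
    "distant CRC")
}

# Category index (1..5) from detected adenoma counts.
adenoma_category <- function(n_detected, any_large) {
  ifelse(n_detected == 0, 1L,
         ifelse(n_detected <= 2, ifelse(any_large, 4L, 2L),
                ifelse(any_large, 5L, 3L)))
}

# Joint distribution of detected counts for one state: binomial per class.
detection_grid <- function(n_dim, n_med, n_lrg, sens) {
  g <- expand.grid(kd = 0:n_dim, km = 0:n_med, kl = 0:n_lrg,
                   KEEP.OUT.ATTRS = FALSE)
  g$prob <- stats::dbinom(g$kd, n_dim, sens[["diminutive"]]) *
    stats::dbinom(g$km, n_med, sens[["medium"]]) *
    stats::dbinom(g$kl, n_lrg, sens[["large"]])
  g
}

#' Observe a single colonic state through colonoscopy
#'
#' Each lesion is detected independently with its size-class sensitivity; an
#' asymptomatic cancer is detected with the CRC sensitivity. The finding
#' category is computed from detected lesions only, with detected CRC taking
#' precedence over any adenoma finding.
#'
#' @param state A list or one-row tibble with `n_diminutive`, `n_medium`,
#'   `n_large`, `stage` (and optionally `symptomatic`).
#' @param sens Named sensitivity vector (`diminutive`, `medium`, `large`,
#'   `crc`), e.g. `colocea_params()$sensitivity`.
#' @return A tibble over detection configurations: detected counts per class,
#'   `crc_detected`, the resulting `category`, and `prob` (summing to 1).
#' @export
#' @examples
#' observe(list(n_diminutive = 1, n_medium = 0, n_large = 0, stage = "none"),
#'         colocea_params()$sensitivity)
observe <- function(state, sens) {
  g <- detection_grid(state$n_diminutive, state$n_medium, state$n_large, sens)
  has_crc <- !is.null(state$stage) && state$stage != "none"
  p_crc <- if (has_crc) {
    if (isTRUE(state$symptomatic)) 1 else sens[["crc"]]
  } else 0
  out <- tibble::tibble(
    n_diminutive_detected = rep(g$kd, 2),
    n_medium_detected = rep(g$km, 2),
    n_large_detected = rep(g$kl, 2),
    crc_detected = rep(c(FALSE, TRUE), each = nrow(g)),
    prob = c(g$prob * (1 - p_crc), g$prob * p_crc)
  )
  cat_adeno <- adenoma_category(out$n_diminutive_detected + out$n_medium_detected +
                                  out$n_large_detected,
                                out$n_large_detected > 0)
  crc_cat <- c(local = 6L, regional = 7L, distant = 8L)
  out$category <- finding_categories()[
    ifelse(out$crc_detected, crc_cat[[if (has_crc) state$stage else "local"]], cat_adeno)
  ]
  out[out$prob > 0, ]
}

# Observation operator over the whole state space: for each adenoma finding
# category k (1..5), U[[k]] maps pre-colonoscopy undiagnosed mass to
# post-polypectomy mass (detected adenomas removed, cancer undetected);
# crc_det[i] is the probability that state i's cancer is detected (routing
# that mass to the diagnosed compartment of its true stage).
obs_operator <- function(space, sens) {
  key <- paste(space$cap, paste(signif(sens, 12), collapse = "_"))
  cached <- .colocea_cache[[key]]
  if (!is.null(cached)) return(cached)
  S <- space$n
  st <- space$states
  U <- lapply(1:5, function(k) matrix(0, S, S))
  crc_det <- numeric(S)
  for (i in seq_len(S)) {
    if (st$symptomatic[i]) next  # never presented for screening
    g <- detection_grid(st$n_diminutive[i], st$n_medium[i], st$n_large[i], sens)
    p_crc <- if (st$stage[i] != "none") sens[["crc"]] else 0
    crc_det[i] <- p_crc
    cats <- adenoma_category(g$kd + g$km + g$kl, g$kl > 0)
    dest <- state_index(space,
                        st$n_diminutive[i] - g$kd,
                        st$n_medium[i] - g$km,
                        st$n_large[i] - g$kl,
                        st$stage[i], FALSE)
    w <- g$prob * (1 - p_crc)
    for (r in seq_len(nrow(g))) {
      U[[cats[r]]][i, dest[r]] <- U[[cats[r]]][i, dest[r]] + w[r]
    }
  }
  op <- list(U = U, crc_det = crc_det, stage = st$stage)
  .colocea_cache[[key]] <- op
  op
}

.colocea_cache <- new.env(parent = emptyenv())

#' Apply a colonoscopy to a cohort distribution
#'
#' Detected adenomas are removed (polypectomy); undetected lesions persist.
#' Detected cancer mass moves to the diagnosed compartment of its true stage
#' with time-since-diagnosis zero; missed cancers remain undiagnosed. Total
#' mass is conserved.
#'
#' @param dist A `cohort_dist`.
#' @param sens Sensitivity vector as in [observe()].
#' @param stratify If `TRUE`, also return the post-colonoscopy distribution
#'   conditioned on each of the five adenoma finding categories.
#' @return A list with `dist` (post-intervention), `findings` (tibble of the
#'   eight category probabilities among the colonoscoped mass), and, when
#'   `stratify = TRUE`, `strata` (named list of conditioned `cohort_dist`).
#' @export
apply_colonoscopy <- function(dist, sens, stratify = FALSE) {
  op <- obs_operator(dist$space, sens)
  und <- dist$und
  cats <- finding_categories()
  post_by_cat <- lapply(op$U, function(M) as.numeric(und %*% M))
  p_cat <- vapply(post_by_cat, sum, numeric(1))
  det_mass <- und * op$crc_det
  crc_by_stage <- c(
    local = sum(det_mass[op$stage == "local"]),
    regional = sum(det_mass[op$stage == "regional"]),
    distant = sum(det_mass[op$stage == "distant"])
  )
  out <- dist
  out$und <- Reduce(`+`, post_by_cat)
  out$dx[, 1] <- out$dx[, 1] + crc_by_stage
  findings <- tibble::tibble(
    category = factor(cats, levels = cats),
    probability = c(p_cat, unname(crc_by_stage))
  )
  res <- list(dist = out, findings = findings)
  if (stratify) {
    res$strata <- lapply(stats::setNames(1:5, cats[1:5]), function(k) {
      d <- dist
      if (p_cat[k] <= 0) return(NULL)
      d$und <- post_by_cat[[k]] / p_cat[k]
      d$dx[] <- 0; d$dead_other <- 0; d$dead_crc <- 0
      d
    })
  }
  res
}

#' One step of symptom-triggered presentation
#'
#' Converts asymptomatic cancer mass to diagnosed at the stage-specific
#' annual symptom-onset probabilities (compounded to the step length), in
#' isolation from all other dynamics. Diagnosis is immediate on symptom
#' onset and implies a diagnostic colonoscopy.
#'
#' @param dist A `cohort_dist`.
#' @param params A [colocea_params()] object (symptom rows of the transition
#'   table).
#' @param step `"month"` or `"year"`.
#' @return A list with `dist` (updated) and `diagnosed` (named vector of
#'   newly diagnosed mass by stage; its sum is the diagnostic-colonoscopy
#'   probability for the step).
#' @export
symptom_presentation <- function(dist, params = colocea_params(),
                                 step = c("month", "year")) {
  step <- match.arg(step)
  r <- lesion_rates(params)
  p_year <- c(local = r$sym_local, regional = r$sym_regional, distant = r$sym_distant)
  p <- if (step == "month") yearly_to_monthly(p_year) else p_year
  st <- dist$space$states
  diagnosed <- c(local = 0, regional = 0, distant = 0)
  for (s in names(diagnosed)) {
    idx <- which(st$stage == s & !st$symptomatic)
    m <- sum(dist$und[idx]) * p[[s]]
    dist$und[idx] <- dist$und[idx] * (1 - p[[s]])
    dist$dx[s, 1] <- dist$dx[s, 1] + m
    diagnosed[[s]] <- m
  }
  list(dist = dist, diagnosed = diagnosed)
}

#' Condition the cohort on being healthy at screening
#'
#' Patients who died or whose cancer was diagnosed (via symptoms) before the
#' screening age are removed from the pool and the remaining undiagnosed
#' mass is renormalized to 1: each hypothetical patient is considered healthy
#' until the screening colonoscopy.
#'
#' @param dist A `cohort_dist` at the screening age.
#' @return The conditioned `cohort_dist`.
#' @export
condition_healthy_at_screening <- function(dist) {
  st <- dist$space$states
  dist$und[st$symptomatic] <- 0
  alive <- sum(dist$und)
  if (alive <= 0) stop("no surviving undiagnosed mass to condition on", call. = FALSE)
  dist$und <- dist$und / alive
  dist$dx[] <- 0
  dist$dead_other <- 0
  dist$dead_crc <- 0
  dist$flows <- NULL
  dist
}
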