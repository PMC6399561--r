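#' Default model parameters
#'
#' Builds the full parameter configuration for the cohort model: annual
#' adenoma/CRC transition probabilities, stage-specific breakpoint mortality
#' rates, the stage prevalence mixture, colonoscopy sensitivities, cost and
#' utility tables, the discount rate, and structural settings (per-class
#' adenoma count cap, model age span).
#'
#' The `transition_rates` block is keyed by the clinical transition names
#' (e.g. `"Diminutive to medium adenoma"`). Adenoma appearance
#' (`"No adenoma to diminutive"`) is age-dependent: a linear ramp from 0 at
#' `ramp_start_age` to the maximum annual probability `max` at `plateau_age`,
#' constant thereafter.
#'
#' @param life_table Optional life table (tibble with columns `age_lo`,
#'   `age_hi`, `annual_death_rate`). Defaults to the bundled synthetic
#'   Gompertz-Makeham table calibrated to a US-like life expectancy of
#'   about 79 years (see [generate_life_table()]).
#' @return A list of class `colocea_params`.
#' @export
#' @examples
#' p <- colocea_params()
#' p$transition_rates[["Diminutive to medium adenoma"]]
colocea_params <- function(life_table = NULL) {
  p <- list(
    transition_rates = list(
      "No adenoma to diminutive" = list(max = 0.0971, ramp_start_age = 20, plateau_age = 70),
      "Diminutive to no adenoma" = 0.0181,
      "Diminutive to medium adenoma" = 0.0163,
      "Medium to diminutive adenoma" = 0.0716,
      "Medium to large adenoma" = 0.0377,
      "Medium adenoma to CRC" = 0.0025,
      "Large to medium adenoma" = 0.0047,
      "Large adenoma to local CRC" = 0.0028,
      "Local CRC to regional CRC" = 0.22,
      "Regional CRC to distant CRC" = 0.50,
      "Asymptomatic local CRC to symptomatic local CRC" = 0.17,
      "Asymptomatic regional CRC to symptomatic regional CRC" = 0.22,
      "Asymptomatic distant CRC to symptomatic distant CRC" = 0.50
    ),
    crc_hazards = tibble::tibble(
      stage = c("local", "regional", "distant", "unknown"),
      k1 = c(0.025, 0.068, 0.600, 0.155),
      breakpoint = c(7.3, 5.3, 1.6, 4.8),
      k2 = c(0.018, 0.025, 0.085, 2.2e-06)
    ),
    stage_mix = list(
      weights = c(local = 0.44, regional = 0.34, distant = 0.18, unknown = 0.05),
      normalizer = 1.01
    ),
    sensitivity = c(diminutive = 0.39, medium = 0.70, large = 0.958, crc = 0.958),
    costs = list(
      colonoscopy = c(base = 1068.59, low = 303, high = 2627),
      adverse_event = 92.06,
      initial = list(
        local = c(base = 20247.20, low = 13848, high = 25527.02),
        regional = c(base = 26007.50, low = 15398, high = 37639.27),
        distant = c(base = 30085.20, low = 17223, high = 42401)
      ),
      surveillance = list(
        local = c(base = 1305.04, low = 425, high = 2353.26),
        regional = c(base = 2346.72, low = 1424, high = 4014.69),
        distant = c(base = 15057, low = 2702, high = 26855)
      ),
      terminal = c(base = 23002.35, low = 11188, high = 50920)
    ),
    utilities = c(healthy = 0.91, dead = 0, local = 0.74, regional = 0.70, distant = 0.25),
    discount_rate = 0.03,
    model = list(
      adenoma_cap = 5L,       # per-size-class count cap; states beyond aggregate at the cap;
                              # 3 distorts finding-stratified results (see vignette)
      start_age = 20,         # adenoma appearance is zero before this age
      horizon_age = 100,      # accounting horizon
      dx_month_cap = 120L     # months-since-diagnosis clock cap (hazard constant beyond)
    ),
    life_table = life_table
  )
  structure(p, class = "colocea_params")
}

#' @export
print.colocea_params <- function(x, ...) {
  cat("<colocea_params>\n")
  cat("  transition rates:", length(x$transition_rates), "entries\n")
  cat("  adenoma cap:", x$model$adenoma_cap,
      " ages:", x$model$start_age, "-", x$model$horizon_age, "\n")
  cat("  discount rate:", x$discount_rate, "\n")
  cat("  life table:", if (is.null(x$life_table)) "synthetic default" else "user-supplied", "\n")
  invisible(x)
}

#' Read / write a parameter configuration
#'
#' Parameter files are JSON or YAML with the same nesting as
#' [colocea_params()]; any block present in the file overrides the default.
#'
#' @param path File path; format inferred from the `.json` / `.yaml` / `.yml`
#'   extension.
#' @return `read_colocea_params()` returns a `colocea_params` object;
#'   `write_colocea_params()` returns `path` invisibly.
#' @export
read_colocea_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- unclass(colocea_params())
  p <- utils::modifyList(p, raw)
  # coerce tabular blocks back to their canonical containers
  if (!is.null(raw$crc_hazards)) p$crc_hazards <- tibble::as_tibble(raw$crc_hazards)
  if (!is.null(raw$life_table)) p$life_table <- tibble::as_tibble(raw$life_table)
  for (nm in c("sensitivity", "utilities")) p[[nm]] <- unlist(p[[nm]])
  p$costs$colonoscopy <- unlist(p$costs$colonoscopy)
  p$costs$terminal <- unlist(p$costs$terminal)
  p$costs$adverse_event <- as.numeric(p$costs$adverse_event)
  for (nm in c("initial", "surveillance")) {
    p$costs[[nm]] <- lapply(p$costs[[nm]], unlist)
  }
  p$stage_mix$weights <- unlist(p$stage_mix$weights)
  validate_params(structure(p, class = "colocea_params"))
}

#' @rdname read_colocea_params
#' @param params A `colocea_params` object.
#' @export
write_colocea_params <- function(params, path) {
  # named atomic vectors must become maps, not arrays, in both formats
  to_map <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, to_map)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  x <- to_map(unclass(params))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Validate a parameter configuration
#'
#' Checks the structural invariants: probabilities in \[0, 1\] with positive
#' self-transition remainder per lesion class, non-negative mortality rates,
#' cost low <= base <= high ordering, utilities in \[0, 1\] with dead = 0, and
#' stage-mix weights summing to the normalizer.
#'
#' @param params A `colocea_params` object.
#' @return `params`, invisibly, or an error describing the violated invariant.
#' @export
validate_params <- function(params) {
  tr <- params$transition_rates
  app <- tr[["No adenoma to diminutive"]]
  stopifnot(
    app$max >= 0, app$max <= 0.0971 + 1e-12,
    app$plateau_age > app$ramp_start_age
  )
  scalars <- unlist(tr[setdiff(names(tr), "No adenoma to diminutive")])
  if (any(scalars < 0 | scalars >= 1)) {
    stop("transition probabilities must lie in [0, 1)", call. = FALSE)
  }
  out_by_class <- list(
    diminutive = c("Diminutive to no adenoma", "Diminutive to medium adenoma"),
    medium = c("Medium to diminutive adenoma", "Medium to large adenoma", "Medium adenoma to CRC"),
    large = c("Large to medium adenoma", "Large adenoma to local CRC")
  )
  for (cls in names(out_by_class)) {
    if (sum(unlist(tr[out_by_class[[cls]]])) >= 1) {
      stop("outgoing yearly probabilities from the ", cls,
           " class must sum to < 1", call. = FALSE)
    }
  }
  hz <- params$crc_hazards
  stopifnot(all(hz$k1 >= 0), all(hz$k2 >= 0), all(hz$breakpoint > 0))
  mx <- params$stage_mix
  if (abs(sum(mx$weights) - mx$normalizer) > 1e-12) {
    stop("stage-mix weights must sum to the normalizer", call. = FALSE)
  }
  s <- params$sensitivity
  stopifnot(all(s >= 0 & s <= 1), s[["diminutive"]] <= s[["medium"]],
            s[["medium"]] <= s[["large"]])
  u <- params$utilities
  stopifnot(all(u >= 0 & u <= 1), u[["dead"]] == 0)
  for (blk in c("initial", "surveillance")) {
    for (st in names(params$costs[[blk]])) {
      v <- params$costs[[blk]][[st]]
      stopifnot(v[["low"]] <= v[["base"]], v[["base"]] <= v[["high"]], all(v >= 0))
    }
  }
  stopifnot(params$discount_rate >= 0, params$model$adenoma_cap >= 1)
  invisible(params)
}

# Internal compact view of the lesion-level annual rates.
lesion_rates <- function(params) {
  tr <- params$transition_rates
  list(
    dim_to_none = tr[["Diminutive to no adenoma"]],
    dim_to_med = tr[["Diminutive to medium adenoma"]],
    med_to_dim = tr[["Medium to diminutive adenoma"]],
    med_to_lrg = tr[["Medium to large adenoma"]],
    med_to_crc = tr[["Medium adenoma to CRC"]],
    lrg_to_med = tr[["Large to medium adenoma"]],
    lrg_to_crc = tr[["Large adenoma to local CRC"]],
    loc_to_reg = tr[["Local CRC to regional CRC"]],
    reg_to_dis = tr[["Regional CRC to distant CRC"]],
    sym_local = tr[["Asymptomatic local CRC to symptomatic local CRC"]],
    sym_regional = tr[["Asymptomatic regional CRC to symptomatic regional CRC"]],
    sym_distant = tr[["Asymptomatic distant CRC to symptomatic distant CRC"]]
  )
}

# Life table in effect: user-supplied or the synthetic default.
effective_life_table <- function(params) {
  if (!is.null(params$life_table)) {
    return(tibble::as_tibble(params$life_table))
  }
  generate_life_table()
}

# Cost value under a sensitivity setting ("base", "low", "high").
cost_value <- function(v, which = "base") unname(v[[which]])
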