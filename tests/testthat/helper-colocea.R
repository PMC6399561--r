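# Shared fixtures, memoised so expensive objects are built once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_params <- function() memo("params", colocea_params())

small_space <- function() memo("space", enumerate_states(cap = 3))

# Zero-mortality life table (flat zero rates) for closed-form checks.
zero_life_table <- function() {
  tibble::tibble(age_lo = seq(0, 95, by = 5), age_hi = seq(5, 100, by = 5),
                 annual_death_rate = 0)
}

# Parameters with every lesion/CRC transition switched off.
inert_params <- function(zero_mortality = TRUE) {
  p <- colocea_params(life_table = if (zero_mortality) zero_life_table())
  for (nm in setdiff(names(p$transition_rates), "No adenoma to diminutive")) {
    p$transition_rates[[nm]] <- 0
  }
  p$transition_rates[["No adenoma to diminutive"]]$max <- 0
  p
}

# The default age-50 interval grid (used by several acceptance checks).
grid50 <- function() memo("grid50", interval_grid(default_params(), screen_age = 50))

# Stratified optimization outcomes at age 50, $100k threshold.
strata50 <- function() {
  memo("strata50", {
    purrr::map_dfr(finding_categories()[1:5], function(f) {
      tibble::as_tibble(optimize_follow_up(default_params(), 50, 1e5, finding = f))
    })
  })
}
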