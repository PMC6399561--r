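---
title: "A partially observed Markov cohort model for follow-up colonoscopy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partially observed Markov cohort model for follow-up colonoscopy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`colocea` asks a narrow health-economic question: after a screening
colonoscopy at a given age, when — if ever — is a *follow-up* (surveillance)
colonoscopy worth its cost, and does the answer depend on what the screening
exam found? The machinery is a deterministic cohort model of colorectal
neoplasia, observed imperfectly through colonoscopy, with discounted cost and
quality-adjusted life-year (QALY) accounting and incremental
cost-effectiveness ratio (ICER) optimization on top. An individual-level
Monte-Carlo microsimulation with the identical rates serves as a brute-force
oracle for validation.

## The natural-history model

The colon is summarized by a state
$x = (N_d, N_m, N_l, \text{stage}, \text{symptomatic})$: counts of
diminutive (<5 mm), medium (6–9 mm), and large/advanced (≥10 mm) adenomas,
plus at most one colorectal cancer (CRC) staged local → regional → distant,
asymptomatic or symptomatic. The probability vector $P(t)$ over this state
space evolves as a Markov chain, $P(t+\Delta t) = K P(t)$, with a monthly
step.

Annual per-lesion transition probabilities (appearance, regression, growth,
malignant transformation, stage progression, symptom onset) are converted to
monthly probabilities under a constant-rate interpretation,
$p_m = 1 - (1-p_y)^{1/12}$, and the yearly kernel is defined as the 12-fold
composition of the monthly kernel. Lesions evolve independently, so the
kernel row for a state with several adenomas is a multinomial convolution of
the single-lesion outcome trees. Within one month, competing outcomes of a
single lesion are resolved by *sequential thinning* in a fixed order —
regression first, then growth, then malignant transformation; for an
established cancer, symptom onset preempts stage progression. The order is a
modelling choice (the monthly probabilities are small enough that order
effects are second-order); it is applied identically in the cohort kernel
and the microsimulation, which is what makes their agreement exact in
expectation rather than approximate.

Adenoma appearance is the only age-dependent rate: the annual probability of
a new diminutive adenoma rises linearly from 0 at age 20 to its maximum
0.0971 at age 70 and is constant thereafter. The end-points of the ramp are a
design choice (only the 0–0.0971 range is identified by the source data); the
profile is a swappable block of the parameter configuration. At most one new
adenoma arrives per month — at monthly appearance probabilities below 0.01,
the neglected multi-arrival mass is below $10^{-4}$.

### The adenoma count cap

Counts are capped per size class, with overflowing transitions redirected to
the cap. Two observations fix the default cap at 5:

* Marginal quantities are cap-insensitive: raising the cap from 3 to 5
  changes 50-year CRC prevalence by under 1% relative (a unit test).
* Finding-*conditional* quantities are not. A screening finding of "3+
  detected adenomas" forces the true count to be at least 3. Under a cap of
  3 the stratum consists almost entirely of patients sitting exactly at the
  cap whose entire burden was detected and removed, leaving an artificially
  clean colon and a recommended follow-up interval several years away from
  the other strata. With a cap of 5 the stratified recommended intervals
  collapse to a spread of about 0.2 years, consistent with the clinical
  expectation that the interval is largely insensitive to the screening
  finding. We measured spreads of 7.1 / 0.8 / 0.2 years at caps 3 / 4 / 5.

Within a monthly step the order of operations is: all-cause death (applied
as $1-e^{-h/12}$), post-diagnosis CRC death and the months-since-diagnosis
clock advance, the natural-history kernel on the undiagnosed, then immediate
diagnosis of newly symptomatic cancers. Order effects at monthly resolution
are below $10^{-5}$.

## The observation layer

Colonoscopy sees the colon imperfectly. Each lesion is detected
independently with a size-dependent sensitivity: 0.39 for diminutive and
0.958 for large adenomas (reported values), 0.70 for medium (not reported;
chosen between the two printed values to preserve monotonicity in size, and
overridable in the configuration), and 0.958 for an asymptomatic cancer
(also not reported; set equal to the large-lesion sensitivity). Detected
adenomas are removed (polypectomy); detected cancers move to a diagnosed
compartment indexed by stage and time since diagnosis; missed lesions and
cancers persist and can be found at a later exam or through symptoms.

Findings are classified from *detected* lesions only into eight categories:
no adenomas; 1–2 or 3+ nonadvanced; 1–2 or 3+ with some advanced (advanced
operationalized as any detected large adenoma — histology is not modelled);
and local/regional/distant CRC. Before the screening exam the cohort is
conditioned on being "healthy": mass that died or presented symptomatically
before the screening age is removed and the remainder renormalized, so the
modelled population is people who actually arrive at screening undiagnosed.

Diagnosed patients leave the surveillance schedule; treatment costs and CRC
mortality take over. Symptom-triggered diagnosis implies a diagnostic
colonoscopy whose probability (and cost) equals the newly symptomatic mass
in that month; scheduled exams have probability 1 among the alive
undiagnosed.

## Mortality

Post-diagnosis survival is a two-piece exponential per stage:
$P(t) = \exp(-k_1 \min(t,b) - k_2 \max(0, t-b))$, with a higher initial rate
$k_1$ up to a breakpoint $b$ years after diagnosis and a lower rate $k_2$
beyond. The fitted values used by default are (local) 0.025/7.3/0.018,
(regional) 0.068/5.3/0.025, (distant) 0.600/1.6/0.085, with an "unknown"
stage (0.155/4.8/2.2e-6) participating only in the prevalence-weighted
overall survival mixture
$(0.44 P_{loc} + 0.34 P_{reg} + 0.18 P_{dis} + 0.05 P_{unk})/1.01$.

`fit_breakpoint_model()` re-estimates all twelve parameters jointly from the
stage-wise 5-year survival points plus an overall survival curve by
unweighted least squares. Because the objective is only piecewise-smooth in
the breakpoints, the optimizer is a deterministic multi-start
box-constrained quasi-Newton search over $(\log k_1, b, \log k_2)$ per
stage, polished with Nelder–Mead until no further improvement; starting
points are moment-based (constant-hazard rates implied by the 5-year
points, scaled up/down around a few breakpoint guesses). The fit is
validated by parameter recovery on synthetic curves (the raw overall curve
is not distributed with the package), including the nested comparison that a
constant-hazard constraint strictly worsens the objective when the truth has
two rates.

All-cause mortality follows the stated procedure for period life tables: a
sixth-order polynomial is fitted by ordinary least squares to annual death
rates against age-band midpoints, clamped at zero below, with ages beyond
the last band (90) extrapolated from the polynomial. The bundled default
table is *synthetic*: a Gompertz–Makeham hazard (Makeham constant
$5\times10^{-4}$, slope 0.095/yr) with the level calibrated to a
life expectancy of 79 years. Those shape constants were chosen once against
the published US-2010 period table (age-40 rate ≈ 0.0016/yr, survivorship to
100 ≈ 2–3%). A user-supplied life table (CSV columns `age_lo, age_hi,
annual_death_rate`) overrides it.

## Economics

Costs cover colonoscopy ($1{,}068.59 plus $92.06 expected adverse-event cost
per exam) and phase-based CRC treatment: a stage-specific initial cost in
the first year after diagnosis, a stage-specific surveillance cost in years
2–5, and a single terminal cost ($23{,}002.35) added — not substituted — in
the year of a CRC death. The terminal cost is applied to deaths from any
stage: the cost table prints only one terminal entry, and the additive
phase-cost structure makes "add" the consistent reading. Each cost has
low/high bounds for the one-way sensitivity analysis.

QALYs weight each life-year by a utility: healthy 0.91 (including
undiagnosed cancer — utilities are treatment-experience weights, so they
apply from diagnosis onward), local 0.74, regional 0.70, distant 0.25, dead
0. Flows accrue monthly, are aggregated into year-of-age buckets, and each
year is discounted by the continuous multiplier $e^{-r(t-\tau)}$ anchored at
the screening age $\tau$ ($r = 3\%$ by default; the printed discounting
factor algebraically reduces to this form). Accounting runs from the
screening age to age 100; pre-screening flows are identical in every
compared arm and cancel from all increments.

## Cost-effectiveness analysis

For one screening age (50–75) and finding stratum, each candidate follow-up
interval on the 2–20-year grid (step 2) is compared with the screening-only
control: $\mathrm{ICER} = \Delta\mathrm{Cost}/\Delta\mathrm{QALY}$. At a
willingness-to-pay threshold the *cost-effective window* is the maximal
contiguous run of grid intervals with ICER at or below the threshold and
positive QALY gain; window endpoints are refined by linear interpolation of
the ICER curve at the threshold crossing, which is how a fractional endpoint
(e.g. 7.7 years) can arise from a 2-year grid. The *recommended interval* is
the vertex of the parabola through the maximal-ΔQALY grid point and its two
neighbours, $x_2 + h\,(y_1-y_3)/(2(y_1-2y_2+y_3))$, clamped to the window;
a boundary maximum or a degenerate (collinear) triple returns the grid point
itself with a flag. Ties at the maximum prefer the longer interval (equal
benefit, fewer exams). "All findings" is the unstratified post-screening
cohort, equivalent to the probability-weighted mixture over strata.

Multi-exam schedules (relevant mainly at a 0% discount rate) are searched
greedily: the next exam's interval is optimized exactly as for a single
follow-up against the current schedule as control, and accepted while its
marginal ICER stays within the threshold. This matches the marginal
cost-effectiveness framing of the question but is an approximation — no
claim of global optimality over schedules is made.

The one-way sensitivity analysis re-runs the pipeline varying exactly one
axis: colonoscopy cost at $303/$2,627, cancer costs at their low/high
bounds, or a 0% discount rate.

## The microsimulation oracle

`simulate_patients()` draws individual life histories with the same monthly
probabilities, the same sequential-thinning multinomials (implemented as
chained conditional binomials), the same at-most-one-arrival rule, caps,
step ordering, conditioning, and the same year-bucket discounting. Its
expectations therefore coincide exactly with the cohort model's, and the
package tests assert agreement of totals, finding shares, and state
marginals within three Monte-Carlo standard errors. The RNG is a single
seeded stream with vectorized draws across patients: runs are reproducible
for a fixed `(n, seed)`, but changing `n` reshuffles the draws.

What the synthetic layer does *not* emulate: site (proximal/distal) and
histology of lesions, serrated-pathway biology, adenoma recurrence at a
polypectomy site as a distinct process, incomplete or poor-prep exams,
individual risk heterogeneity beyond the shared age profile, and real
vital-statistics irregularities (the infant-mortality hump, period shocks).
Passing tests demonstrate internal consistency of the two implementations
and fidelity to the stated parameter tables, not calibration to any
particular registry population.

## Numerical choices and problem sizes

* State space: $(cap+1)^3 \times 7$ states (1,512 at the default cap 5);
  kernels are dense matrices, and the age-dependent kernel is assembled as
  $(1-p)K_0 + pK_1$ from two precomputed pieces, so a century of monthly
  propagation is a few thousand matrix-vector products.
* Diagnosed compartments track months since diagnosis up to 120, beyond
  which the hazard is constant and no treatment cost accrues.
* Kernel rows are verified stochastic to $10^{-9}$; total mass is conserved
  to $10^{-9}$ over 1,200 monthly steps.
* Default analyses use the 2–20-year interval grid (10 scenario runs plus a
  control per stratum); validation microsimulations use $n$ between $2\times
  10^4$ and $2\times10^5$ patients.
* Degenerate inputs: an all-ones survival input yields a flat objective
  (warned, boundary solution returned); a zero-probability finding stratum
  and a cohort with no survivors at screening raise errors rather than
  propagating NaNs.

## Known limitations

The recommended intervals inherit the calibration uncertainty of the two
inputs that are not fully identified by published tables — the age profile
of adenoma appearance and the all-cause life table. The ICER *level* is the
most sensitive output (our default calibration yields somewhat larger QALY
gains, hence somewhat lower ICERs, than the reference analysis), while the
location of the QALY-maximizing interval near 8.5–9 years and its
insensitivity to screening findings are robust. Costs are payer-perspective
2010-era US dollars without inflation adjustment; no probabilistic
sensitivity analysis is implemented.
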