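---
title: "Model methods: cost-utility analysis of rapid respiratory panel testing in COPD exacerbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdcea)
```

## The decision problem

Acute exacerbations of chronic obstructive pulmonary disease (AECOPD) are
mostly managed empirically in primary care: over two thirds of presenting
patients receive antibiotics on clinical judgement alone, although many
exacerbations are viral. A point-of-care multiplex respiratory panel (the
RP2.1 test, £94 per patient) can rule bacterial infection in or out within
the consultation, so that in a tested cohort essentially only true bacterial
exacerbations receive antibiotics. The package quantifies, from a UK NHS and
personal social services perspective in 2022 GBP, whether testing is worth
paying for — in quality-adjusted life years (QALYs) gained and lifetime
costs — and what the downstream antimicrobial-resistance (AMR) consequences
of the avoided prescribing are worth.

Two strategies are compared: **intervention** (test-guided prescribing; the
probability of an antibiotic at first presentation is $1 - \text{test
sensitivity} = 0.03$) and **control** (usual practice; antibiotic
probability 0.80). The result is reported as incremental cost
$\Delta C$, incremental effect $\Delta Q$, the ICER $\Delta C / \Delta Q$
where a ratio is meaningful, and net monetary benefit
$\mathrm{NMB}(\lambda) = \lambda \Delta Q - \Delta C$ at a willingness to
pay of £20,000/QALY.

## Model structure

### Short-run decision tree

Each arm's first year is a pathway tree with identical topology; the arms
differ only in the first-line antibiotic probability, the arm-specific
improvement and hospitalisation probabilities, and the test cost, which is
charged exactly once at the intervention root. The pathway narrative is:

1. **First-line treatment** — antibiotics alone (with the arm's antibiotic
   probability) or steroids plus antibiotics. Patients improve
   (probabilities per arm: 0.85/0.80 after antibiotics, 0.92/0.89 after
   steroids+antibiotics) and are classed as **mild** exacerbations.
2. **Second-line treatment** — antibiotic-only failures are routed (50/50
   by default, configurable) to a second antibiotic course or to
   antibiotics with an A&E attendance; steroid+antibiotic failures receive
   a second steroid+antibiotic course. Recoverers are classed **moderate**.
3. **Third treatment** — improvement probability 0.89 in both arms;
   recoverers are classed **severe, fully recovered**.
4. **Admission stage** — third-treatment failures are admitted with the
   arm- and pathway-specific hospitalisation probabilities (control 0.20
   antibiotic-first / 0.10 steroid pathway; intervention 0.15 / 0.10);
   non-admitted patients partially recover in the community. Admitted
   patients die with probability 0.05, otherwise recover fully or
   partially (50/50 by default, an assumption flag).

Terminal payoffs are the recovery utilities (fully recovered 0.6607,
partially recovered 0.5558, dead 0). Tree results are undiscounted (the
episode is under one year) and the utility payoff is credited for one
quarter-year when converted to QALYs, matching the first Markov cycle
length. Expected values are computed by recursive rollback; an exhaustive
path-enumeration oracle in the test suite confirms equality to 1e-12 on
hundreds of random parameter sets. Zero-probability branches are pruned
before expectation.

Costs accrue per node from configurable bundles of the nineteen published
unit costs (e.g. first-line treatment = GP consultation + prescription +
drug courses). The bundles are the package's own assumption — published
per-pathway resource use is not available — and are therefore defined in
the configuration, not in code, and flagged in every run manifest.

### Lifetime Markov cohort model

Survivors enter a 10-state cohort model: three severity levels (stable,
mild exacerbation, moderate exacerbation) crossed with GOLD stages II–IV,
plus an absorbing dead state. The cohort runs 160 quarterly cycles from age
60 to 100. Tree severity classes seed the entry occupancy: mild recoveries
enter the mild states, all other alive classes enter the moderate states
(configurable class map), spread uniformly across GOLD stages (the initial
stage mix is not published; uniform is the default and flagged).

Per cycle, the transition matrix combines:

* a severity transition block (stable/mild/moderate movement),
* GOLD-stage progression with severity-specific intensity (stage regression
  is not modelled),
* disease-specific death probabilities by state, and
* age-specific all-cause mortality, converted from annual to quarterly via
  $1-(1-q)^{1/4}$ and combined with disease mortality as independent
  competing risks: $q = 1-(1-q_{ac})(1-q_{ds})$.

Every resolved row sums to one (enforced to 1e-12). Severe exacerbations
are modelled as per-cycle admission events within the exacerbation states
(admission probability times the hospital-stay cost enters the state cost)
rather than as a persistent state, preserving the 3-severity × GOLD
description while keeping the severity concept from the tree.

State costs are unit costs × per-severity and per-stage resource-use
quantities per cycle; state utilities are GOLD-stage utilities scaled by
severity multipliers (stable 1.0, mild 0.90, moderate 0.75). QALYs accrue
as occupancy × utility × 0.25 years from start-of-cycle occupancy.

### Discounting

All Markov costs and QALYs are discounted at 3.5% per year using mid-cycle
(half-cycle) discounting: the cycle-$t$ increment is multiplied by
$(1+r)^{-(t+0.5)\,\ell}$ with $\ell = 0.25$ years. This is the package's
chosen reading of the half-cycle method: increments are computed from
full-cycle start-of-cycle occupancy and discounted to the cycle midpoint,
isolated in one function (`discount_half_cycle()`) so the alternative
(averaging adjacent occupancies) can be substituted without touching the
engine.

## Parameter handling

All inputs live in one YAML configuration
(`default_config_path()`), validated strictly: unknown keys are rejected,
every published item must be present, and ranges are enforced. Sampling
distributions are fitted by the method of moments — the standard
health-economics convention, uniquely determined by the published mean and
standard error:

* costs: Gamma with shape $(\mu/\sigma)^2$, scale $\sigma^2/\mu$;
* probabilities and utilities: Beta with
  $\nu = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu\nu$, $\beta = (1-\mu)\nu$,
  feasible only when $\sigma^2 < \mu(1-\mu)$.

One published control-arm probability (improvement after initial
antibiotics, mean 0.80) is printed with a standard error of 0.8, which is
infeasible for any Beta distribution; every other pathway probability's
standard error is 20% of its mean, so the shipped default uses 0.16. For
configurations that insist on infeasible values, the Beta policy is
configurable: `raise` (error) or `clamp` (shrink the standard error to
$0.95\sqrt{\mu(1-\mu)}$ with a logged warning; the default).

The intervention-arm antibiotic probability is an enforced identity, not a
free number: loading fails unless it equals one minus the configured test
sensitivity (0.97).

Currency is GBP 2022 throughout; the shipped values are the published ones
(spirometry costs were published pre-inflated) and no internal inflation
adjustment is applied.

## Sensitivity analyses

**One-way (deterministic).** Each of twelve short-run drivers is varied to
`base × (1 ∓ 0.392)` — a 95% interval under a standard error of 20% of the
mean — with probabilities capped at 1.0, and the full pipeline re-run at
each extreme. The rule is overridable per item.

**Threshold analysis.** The break-even test price solves
$\mathrm{NMB}(\lambda) = 0$ at £20,000/QALY by bisection to £0.01. The
price enters the intervention cost once and linearly, so NMB is strictly
decreasing in it; the generic bisection is retained (and tested against the
analytic solution) so the search survives structural edits.

**Probabilistic.** 10,000 Monte-Carlo draws sample every
distribution-carrying parameter independently (no correlation structure is
published); parameters shared across arms use the same draw within an
iteration, avoiding spurious incremental noise. A master seed spawns one
deterministic substream per draw, so results are reproducible and
independent of draw order. Because the synthetic transition block carries
no sampling distributions, the cohort propagation operator
$D = \sum_t \delta_t A_t$ (the discounted sum of entry-to-cycle-$t$ alive
maps) is precomputed once; each draw then costs two tree rollbacks and a
handful of 9×9 products, which keeps the full 10,000-draw analysis under a
minute. The acceptability curve reports, at each willingness-to-pay value
on a £0–£50,000 grid (£1,000 steps), the fraction of draws with positive
NMB, counting boundary ties one half.

## Accounting for antimicrobial resistance

**Approach 1 — per-prescription penalty.** A projected \$100 trillion
global GDP loss over 35 years is annualised (\$2.8 trillion, truncated to
two significant figures for display parity), divided by annual prescription
volume (14.1 DDD/1000/day × 7.8 billion people × 365 days ÷ 5-day courses
≈ 8.0 billion prescriptions/year), converted at 0.800769 GBP/USD and scaled
by a resistance modulating factor (RMf) of 0.37 — the fraction of
resistance cost attributable to human antibiotic consumption. The RMf is
not published; 0.37 is the unique two-decimal value mapping the published
£285.84 to the published £105.76, and is configurable. The published
per-prescription figure (\$356.96) is not exactly consistent with its own
upstream constants (≈\$349); the chain therefore carries both a *canonical*
mode (published figures, the default) and a *computed* mode (full-chain
arithmetic), with a divergence flag. The world population behind the
published DDD total is likewise not printed (it back-solves to ≈7.79
billion); the shipped default is 7.8 billion, flagged. The resulting
penalty — or the broad/narrow-spectrum alternatives of £7.45 and £14.89 —
is added to both antibiotic-course cost items and applied per course
dispensed, and the pipeline re-run.

**Approach 2 — trajectory-scaled savings.** Yearly resistance costs are
anchored at 2023 (GDP basis £2.2 trillion/year with RMf applied; hospital
£554 billion and productivity £155 billion bases without RMf, as they are
already human-population costs) and scale in proportion to a pathogen's
resistance-rate trajectory, 2023–2040. The COPD-attributable share is 7.5%
of prescriptions. Testing scenarios multiply the whole trajectory by
$1 - \text{reduction}$ for reductions of 1/5/10/25%; the reduced stream is
anchored to the *usual-care* base-year rate, since the base-year cost is
incurred at that rate — anchoring each stream to its own base year would
cancel the reduction out of the ratio. Annual savings are the mean yearly
difference between the streams ("adjusted to an annual value" is read as
the mean over 2023–2040; alternatives are configuration options). UK
scenarios scale savings by 100/50/25% shares; published tables for reduced
UK shares are not exact halves/quarters of their 100% rows, so pure scaling
is implemented and the divergence documented here rather than
reverse-engineered. The testing-cost comparison multiplies 115,000 yearly
UK COPD diagnoses by 30% or 50% exacerbation fractions and the £94 unit
cost.

## Synthetic inputs: what they emulate, and what they do not

Three inputs the model needs exist only in external sources and are
generated synthetically, each a pure function of its specification
(seed included) and flagged in run manifests:

* **Resistance trajectories** (`generate_amr_trajectory()`): geometric or
  additive drift from a 2023 start rate, optional seeded Gaussian noise,
  clipped to [0.001, 0.999]. Defaults — MRSA starting at 6% declining 2%
  per year (UK MRSA incidence has fallen for two decades), PRSP starting
  at 5% rising 2% per year — are chosen for qualitative realism only; no
  numbers are read off published figures.
* **All-cause mortality** (`generate_mortality_table()`): Gompertz hazard
  $h(a) = 2.7\times10^{-5} e^{0.095a}$, giving annual death probabilities
  rising from ≈0.008 at 60 to ≈0.35 at 100 — the shape of recent England &
  Wales all-cause mortality. It is not calibrated to the official life
  table.
* **Transition/resource-use block** (`generate_transition_defaults()`):
  the severity transition matrix (stable rows 0.85/0.12/0.03; mild
  0.35/0.45/0.20; moderate 0.10/0.25/0.65 per quarter), stage-progression
  intensities (0.003/0.012/0.045 per quarter by severity), disease-specific
  mortality, admission-event rates (2%/10% per quarter in mild/moderate),
  and per-state resource-use quantities. The shape encodes the
  frequent-exacerbator phenotype: exacerbation-prone states persist and
  accelerate GOLD progression. Two scalar intensities (exacerbation,
  progression) let sensitivity sweeps and property tests vary the block
  while rows remain stochastic by construction.

Because these stand-ins replace unpublished upstream inputs, the package's
passing tests demonstrate *internal* correctness (engines match independent
oracles; printed arithmetic chains reproduce) and the *direction* of the
base case (the tested arm is cheaper and more effective under the shipped
defaults, and the severity gradient prices moderate states above mild
ones). They do not validate the published lifetime magnitudes: per-arm
totals, the published break-even price and the published acceptability
probability depend on the unpublished resource-use and transition inputs
and are deliberately outside numeric acceptance.

## Numerical choices and degenerate inputs

* Mortality lookup uses `floor(age)`; ages outside the table raise an
  error rather than extrapolate.
* Chance-node probabilities must sum to 1 within 1e-12; occupancy rows are
  checked to 1e-9 in tests; the trace's dead column is monotone.
* Moment fits must round-trip mean and standard error to 1e-9.
* Bisection tolerance £0.01; no sign change over the bracket is an error
  reporting both bracket NMBs.
* CEAC ties (NMB exactly zero) count 0.5.
* Probabilities pushed to a boundary by the one-way analysis lose their
  Beta representation silently — deterministic re-runs never sample.
* `n = 0` probabilistic runs return an empty, valid sample set; the CEAC
  refuses them.

## Problem sizes

The shipped analysis runs 160 cycles × 10 states per arm; the one-way
table re-runs the pipeline 24 times; the probabilistic analysis uses
10,000 draws (seconds, thanks to the precomputed propagation operator).
The test suite's oracle sweeps use 200 random tree parameter sets, 100
random cohort configurations, 200 random generator seeds and one
million-draw moment-recovery pass per fitted distribution.

## Known limitations

* No GOLD-stage regression, treatment-effect waning, or parametric survival
  extrapolation beyond the Gompertz table.
* PSA samples parameters independently; any real correlation (e.g. between
  stage utilities) is ignored.
* The Markov transition block and resource-use quantities are assumptions,
  not estimates; all lifetime magnitudes inherit that uncertainty.
* Approach-2 savings assume a time-constant reduction applied to resistance
  levels (not growth increments) and linear cost-in-rate scaling; the
  consumption–resistance elasticity is not modelled.
* The tree models cohort expectations, not patient-level heterogeneity;
  treatment choice is not optimised.
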