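# copdcea

Cost-utility modelling of point-of-care multiplex respiratory panel
testing (the RP2.1 test, £94/patient) to guide antibiotic prescribing in
acute exacerbations of COPD, from a UK NHS perspective in 2022 GBP — for
health economists and HTA analysts who want a fully configuration-driven,
testable re-implementation of this class of diagnostic evaluation, with
the antimicrobial-resistance (AMR) consequences of prescribing priced in.

## The model

A short-run **decision tree** (first-line antibiotics or
steroids+antibiotics, up to three treatment rounds, hospital admission,
full/partial recovery or death) is rolled back to expected cost, expected
utility payoff, and a severity distribution. That distribution seeds a
lifetime **Markov cohort model** over 10 states — {stable, mild, moderate
exacerbation} × {GOLD II, III, IV} plus dead — run for 160 quarterly
cycles from age 60 with age-specific all-cause mortality and half-cycle
discounting at 3.5%/year. Results are reported as

- ΔC, ΔQ — incremental lifetime cost and QALYs of testing vs usual care,
- ICER = ΔC/ΔQ (with dominance classified before any ratio is reported),
- NMB(λ) = λ·ΔQ − ΔC at willingness to pay λ = £20,000/QALY,

plus one-way sensitivity analysis, a break-even test price, a
10,000-draw probabilistic sensitivity analysis (PSA) with
cost-effectiveness acceptability curve (CEAC), and two AMR costings:

- **Approach 1** — a per-prescription resistance penalty
  ($2.8tn/year ÷ ~8bn prescriptions × 0.800769 GBP/USD × RMf 0.37 =
  £105.76) added to antibiotic costs;
- **Approach 2** — annual resistance costs (GDP £2.2tn; hospital £554bn;
  productivity £155bn) scaled along MRSA/PRSP resistance trajectories
  2023–2040, compared between usual care and reduced-resistance testing
  scenarios (1–25% reductions, 100/50/25% UK shares), against the £3.2–5.4m
  annual cost of testing 30–50% of the exacerbating UK COPD population.

Inputs that exist only in unpublished upstream sources (Markov
transitions, per-state resource use, the mortality table, resistance
trajectories) ship as provenance-flagged synthetic defaults; see
`vignettes/model-methods.Rmd` for what that does and does not validate.

## Worked example

```r
library(copdcea)
params <- load_config()          # shipped defaults: published point estimates
run_base_case(params)$result
#> <ce_result>
#>   intervention: £14819.82, 8.6929 QALYs
#>   control:      £14850.60, 8.6666 QALYs
#>   increments:   £-30.79, 0.0263 QALYs
#>   classification: dominant
```

Testing is *dominant* under the shipped defaults: it saves £30.79 and
gains 0.0263 QALYs per patient over a lifetime — the test's £94 is more
than repaid by fewer failed treatment rounds, fewer admissions and a
milder long-run severity mix. The price at which that stops being true:

```r
threshold_price(params)          # bisection on NMB at £20,000/QALY
#> [1] 650.79
```

Uncertainty, reproducible from one seed:

```r
psa <- run_psa(params, n = 10000, seed = 1)
psa
#> <psa_samples> 10000 draws (seed 1)
#>   mean increments: £-30.88, 0.0264 QALYs; P(dominant) = 0.571
cc <- ceac(psa)
cc$probability[cc$lambda == 20000]
#> [1] 0.78
```

At £20,000/QALY the intervention is cost-effective in 78% of draws. The
AMR penalty chain, with its published-vs-computed divergence flagged:

```r
penalty_chain(params$amr)
#> <penalty_chain>
#>   annual loss: $2.857e+12 (displayed $2.8e+12); prescriptions/year: 8.029e+09
#>   per prescription: canonical $356.96 -> £285.84 -> £105.76 (RMf 0.37)
#>   computed chain:   $348.76 -> £279.27 -> £103.33  [diverges from canonical]
```

`run_full_suite(out_dir = "out", seed = 1)` writes every artifact —
parameter audit, base case, one-way table, threshold, CE plane, CEAC,
AMR tables, trajectories — plus a manifest listing all assumption flags.
A thin CLI wrapper with the same subcommands lives at
`inst/cli/copdcea.R`.

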