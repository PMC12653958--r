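# medialknee

Medial tibiofemoral contact mechanics and lifetime cartilage failure
risk, for researchers studying gait modifications (toe-in, toe-out,
lateral wedge insoles) as conservative interventions against medial
knee osteoarthritis.

The package implements the desk-side computational chain that sits
downstream of motion capture and musculoskeletal simulation:

1. **Gait features** — stance detection from vertical ground reaction
   force (20 N rule), zero-lag Butterworth filtering, foot progression
   angle from the centre-of-pressure chord, daily loading cycles,
   cumulative load, and centre-of-pressure offset at peak force.
2. **Contact mechanics** — an elastic-foundation (bed-of-springs)
   model of the medial compartment: a rigid two-arc femoral condyle
   pressed into 7326 nonlinear springs (grid 111 × 66 at 0.5 mm) with
   the logarithmic law σ = −E·ln(1 − ε), region-dependent moduli under
   and outside the meniscus, and a bisection solver that lowers the
   flexion axis until the spring assembly carries the target medial
   force.
3. **Failure model** — Weibull cumulative-damage fatigue with a
   competing Weibull repair process:
   t_f = c_p·Δt_cycle·(c_w·ε)^(−b),
   P(t) = 1 − exp(−(V/V_ref)(t/t_f)^(k/b)), and
   P_rep(T) = ∫₀ᵀ f(t)(1 − P_r(t)) dt over a 37-year horizon
   (k = 14.3, b = 12.9, c_w = 1.03, c_p = 1.0, repair time 5 y,
   repair exponent 5.2, V_ref = 78.5 mm³).
4. **Cohort pipeline** — a synthetic repeated-measures cohort
   generator (15 participants × 4 conditions × 5 trials), per-trial
   orchestration of stages 2–3, participant-first aggregation, and
   mixed-effects condition comparisons with paired Cohen's d.

## Worked example

Solve the contact problem at a reference load — the cohort-mean peak
medial force of 2.68 BW for a 69.31 kg adult at 18° of knee flexion:

```r
library(medialknee)
sol <- solve_contact(bw_to_newtons(2.68, 69.31), flexion_angle = 18)
sol
#> Elastic-foundation contact solution
#>   target force 1822.2 N (achieved 1821.90 N) at 18.0 deg flexion
#>   axis depth 1.104 mm | peak strain 0.221 | peak stress 2.03 MPa
#>   loaded area 1726 mm^2 | stressed volume 8632 mm^3 (6906/7326 elements)
```

The femoral surface must sink 1.10 mm into the 5 mm foundation to
carry 1822 N, compressing the deepest element to 22% strain — the
strain that drives the fatigue model.

Run the full chain on a synthetic cohort and compare conditions:

```r
res <- run_pipeline(generate_cohort(cohort_config(seed = 1)))
res
#> Medial knee cartilage pipeline result
#>   300 trials (0 quarantined) | config 8f62bdea
#>   terminal failure probability with repair (cohort means):
#>     neutral           13.28% (SD 13.24%)
#>     toe_in             7.83% (SD 7.81%)
#>     toe_out            6.09% (SD 6.21%)
#>     lateral_insoles   12.92% (SD 12.89%)

subset(res$comparisons, outcome == "p_terminal",
       c(contrast, estimate, p_value, cohens_d, significant))
#>                     contrast estimate  p_value cohens_d significant
#> 25          neutral - toe_in  0.05455 1.95e-03   0.7437        TRUE
#> 26         neutral - toe_out  0.07194 8.26e-05   0.9339        TRUE
#> 27 neutral - lateral_insoles  0.00369 8.24e-01   0.0993       FALSE
#> 28          toe_in - toe_out  0.01739 2.98e-01   0.4331       FALSE
#> 29  toe_in - lateral_insoles -0.05086 3.63e-03  -0.7514        TRUE
#> 30 toe_out - lateral_insoles -0.06824 1.66e-04  -0.9105        TRUE
```

Reading the output: toe-in and toe-out walking lower the 37-year
failure probability relative to neutral gait and lateral insoles
(smaller peak forces → smaller strains, amplified by the
strain^(−12.9) fatigue law), while insoles are indistinguishable from
neutral.  The large SDs are real: the fatigue law makes individual
risk extremely sensitive to strain, so cohort risk is dominated by the
most-loaded participants.  `res$curves` holds the condition-average
failure-probability time series with and without repair.

A thin command-line wrapper with subcommands (`simulate-cohort`,
`contact-solve`, `failure-risk`, `run-pipeline`,
`compare-conditions`) is installed at `inst/cli/medialknee.R`.

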