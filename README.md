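# vbpricer

Shortcut algorithms for value-based pricing (VBP) of pharmaceuticals from
trial-period evidence.

## The problem

Under VBP, a drug's price is set so that its incremental
cost-effectiveness ratio (ICER) against the comparator equals a
willingness-to-pay threshold λ. Because pivotal trials rarely observe
lifetime outcomes, health-technology assessments usually extrapolate
downstream costs — savings from avoided events and survival
(life-extension) costs — far beyond the trial window, at substantial
modeling cost and with contested structural assumptions. Yet under
specific, provable conditions those downstream components *cancel out of
the pricing condition entirely*, so the trial-period evaluation already
determines the price. `vbpricer` implements that algebra for analysts and
HTA modelers: it decomposes the multi-endpoint ICER, solves the threshold
price in closed form, checks the cancellation conditions, quantifies how
much deviation from them the pricing conclusion tolerates, and runs the
whole decision procedure end to end.

## The model

For endpoints *i* = 1..m with severity weights *w*, case fatality α,
signed event unit cost C_CE (negative = saving) and survival cost C_s,
with avoided events ΔCE_i = Inc_i × RRR_i × T:

```
ICER = ΔC_drug / ΔE  +  Σ ΔCE_i (1−α_i) C_CE,i / ΔE  +  Σ ΔCE_i α_i C_s,i / ΔE,
ΔE   = Σ ΔCE_i w_i
```

and the value-based price solving ICER = λ is

```
Δp = λ·ΔE − ΔC_nonprice − ΔC_downstream,        p_D = p_B + Δp.
```

The package's core results are eight cancellation propositions (single
endpoint; equal fatality / weights / costs; common-scalar RRR; common
post-trial scaling factors k_Inc, k_RRR, k_α, k_C; and a case-fatality
subcase) under which savings and/or survival costs drop out of this
pricing condition along the D→B→A comparison chain, plus an
admissible-deviation analysis for factors near 1. See the vignette
(`vignettes/vbp-shortcuts.Rmd`) for the full derivation-level account.

## Worked example

Two endpoints — one non-fatal (weight 0.2, saving 5,000 per avoided
event) and one fatal (weight 1.0, survival cost 30,000 per avoided death)
— with avoided events 0.10 and 0.02, non-price drug cost 1,000 and a
threshold of 50,000:

```r
library(vbpricer)
sc <- worked_example_scenario()
compute_icer(sc, price = 900)
#> <vbp_icer> d_vs_b, trial horizon
#>   drug term:          47500.00
#>   savings term:      -12500.00
#>   survival term:      15000.00
#>   total ICER:         50000.00 per weighted events
```

At a price of 900 the three terms sum exactly to the threshold: the
downstream cost is 0.10·(−5,000) + 0.02·30,000 = 100, the weighted effect
0.04, and the solved price λ·0.04 − 1,000 − 100 = 900. The scenario's
stipulated post-trial block (effect 0.02, downstream 1,000) has a
downstream-to-effect ratio equal to λ, so extending the horizon leaves
the price unchanged — which the decision engine detects:

```r
run_shortcut(sc)
#> <vbp_shortcut> outcome: price_invariant
#>   price (incremental): 900.0000
#>   trace:
#>     step 1: inputs validated (2 endpoint(s), threshold 50000)
#>     step 2: trial weighted effect 0.04, downstream cost 100, trial-based price 900
#>     step 3: propositions applicable: none
#>     step 4: two-horizon check: price 900 -> 900 (delta 0), invariant: TRUE
#>     step 4: price invariance established; price set to the trial solve
```

A generated scenario satisfying a cancellation condition, verified
numerically (price with vs without survival costs, both comparisons):

```r
sc2 <- generate_scenario(2, seed = 1)
check_proposition(sc2, 2)$applicable
#> [1] TRUE
verify_cancellation(sc2, "survival_costs")
#> [1] -9.094947e-13
```

The annual-price illustration (hospitalization incidence 0.15/person-year,
relative reduction 0.15, 10,000 per hospitalization, 0.04 QALYs/year,
λ = 50,000/QALY, 3-year trial) solves λ = (p·T − savings)/QALYs:

```r
do.call(solve_annual_price, as.list(hf_example_inputs()))
#> [1] 2225
```

Scenario configs are YAML (`read_scenario()` / `write_scenario()`),
per-period survival profiles CSV (`read_survival_profile()`), and a thin
CLI wraps the main verbs (`inst/cli/vbp.R`: `shortcut`, `price`, `check`,
`extrapolate`, `sensitivity`, `generate`).

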