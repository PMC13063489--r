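---
title: "When is extrapolation unnecessary for a value-based price?"
author: "vbpricer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{When is extrapolation unnecessary for a value-based price?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbpricer)
```

## The pricing model

Value-based pricing (VBP) sets a drug's price so that its incremental
cost-effectiveness ratio (ICER) against the comparator equals a
willingness-to-pay threshold $\lambda$. `vbpricer` works with a
multi-endpoint event model: a new drug D and its comparator B affect $m$
clinical event (CE) types indexed $i$, each with a severity weight $w_i$, a
baseline incidence $\mathrm{Inc}_i$, a case-fatality probability
$\alpha_i$, a signed unit cost $C_{\mathrm{CE},i}$ per non-fatal event
(negative when avoiding the event saves money), and a survival
(life-extension) cost $C_{s,i}$ per avoided death. Avoided events over the
trial window are $\Delta CE_i = \mathrm{Inc}_i \times \mathrm{RRR}_i \times
T$ (or supplied directly), and the ICER decomposes into three additive
terms:

$$
\mathrm{ICER} =
\frac{\Delta C_{\mathrm{drug}}}{\sum_i \Delta CE_i w_i}
+ \frac{\sum_i \Delta CE_i (1-\alpha_i) C_{\mathrm{CE},i}}{\sum_i \Delta CE_i w_i}
+ \frac{\sum_i \Delta CE_i \alpha_i C_{s,i}}{\sum_i \Delta CE_i w_i},
$$

a drug-cost term, a savings term and a survival-cost term
(`compute_icer()`). Setting the ICER equal to $\lambda$ and solving gives
the closed-form value-based price

$$
\Delta p = \lambda \,\Delta E - \Delta C_{\mathrm{nonprice}}
          - \Delta C_{\mathrm{downstream}},
$$

with $\Delta E = \sum_i \Delta CE_i w_i$ (`solve_vbp_price()`); the
absolute price is $p_D = p_B + \Delta p$ when the comparator price is
known.

### Sign conventions

Event unit costs are stored **signed**: avoiding a costly event enters as
a negative `event_cost`, so the savings term above is added, and the
worked example's downstream sum ($0.10 \times (-5{,}000) + 0.02 \times
30{,}000 = 100$) comes out with the right sign. The annual-price solver
`solve_annual_price()` deliberately uses the opposite, hospital-costing
convention (a positive cost per event whose savings are subtracted),
because that is how per-year threshold calculations are usually laid out;
a unit test pins the two conventions to each other on identical inputs.

### The pricing chain

The cancellation results below are statements about the D→B→A pricing
chain: B's own price is assumed value-based against a reference
intervention A, so both ICERs equal the same threshold. Accordingly, when
the scenario's B-vs-A comparison carries a price, `effective_threshold()`
evaluates the operative threshold *at each horizon* as the B-vs-A ICER at
that price; without a priced B-vs-A arm the fixed scenario threshold is
used. This is essential: with a threshold held fixed while the horizon is
extended, adding post-trial effects and costs changes the implied price in
general, and none of the cancellations would hold. If the comparator is
priced below value (e.g. genericized), the gap acts as a time-invariant
additive shift that cancels from the *change* in price across horizons, so
the shortcut logic is unaffected.

## The cancellation propositions

Each proposition is a sufficient condition under which a downstream
component drops out of the pricing condition, because its per-unit-effect
contribution is identical on both sides of the chain:

| id | conditions checked | cancels |
|----|--------------------|---------|
| 1 | single endpoint; equal case fatality across comparisons | savings + survival costs |
| 2 | equal case fatality; common-scalar RRR per comparison | survival costs |
| 3 | common post-trial scaling factors; common survival-cost ratio $\Phi$ | survival costs (change) |
| 4 | equal case fatality; equal weights; equal survival cost | survival costs |
| 5 | equal case fatality; common-scalar RRR per comparison | savings |
| 6 | common factors incl. event costs; common event-cost ratios | savings (change) |
| 7 | equal case fatality; equal weights; equal event unit costs | savings |
| subcase | common survival cost per avoided death; proportional expenditure growth | survival costs |

Two design points deserve explanation:

* **Proposition 4 checks equal survival costs across endpoints** in
  addition to equal fatality and weights. With per-endpoint survival costs
  and endpoint-varying RRRs, the weighted survival cost per unit effect
  differs between comparisons and the cancellation fails algebraically;
  the condition set here is the one under which the claim is actually
  provable (the derivation treats the survival cost as a common scalar).
* **Proposition 3's $\Phi$** — described in words as the common
  survival-cost ratio — is implemented explicitly as the weighted survival
  cost per unit of weighted effect, $\Phi_X = \sum_i \Delta CE_{X,i}
  \alpha_i C_{s,i} / \sum_i \Delta CE_{X,i} w_i$, and asserted equal
  across the two comparisons before cancellation is claimed. Symmetric
  structure is likewise imposed on both sides of the proposition-6
  derivation.

`check_proposition()` evaluates the conditions with a relative tolerance
(default `1e-9`, appropriate for constructed scenarios; loosen it for
noisy empirical inputs), and `verify_cancellation()` confirms each verdict
numerically: it solves the chain price with the full model and again with
the component removed from *both* comparisons, returning the signed
residual. The conditions are between-comparison equalities, which is why
the package's violation experiments perturb one comparison (or one
endpoint of one comparison) rather than shifting a parameter everywhere:
a symmetric shift often leaves the cancellation intact. For example, with
a common-scalar RRR, making one endpoint's fatality differ *in both
comparisons* still cancels — only asymmetric perturbations are decisive.

### The case-fatality subcase

When treatment also reduces the probability of dying once an event has
occurred (`delta_fatality`, with its own cost `survival_cost_fatality` per
death so averted), the pricing condition is evaluated per *avoided death*
rather than per weighted effect: the denominator is $\sum_i \Delta CE_i
\alpha_i + \Delta\alpha_i$. The package leaves this denominator
unweighted; with a single severity class (the typical subcase setting) the
distinction is immaterial, and weighting can be emulated by scaling the
inputs. Horizon invariance additionally requires that the two survival
expenditure streams evolve proportionally, which the scaling factors
express as `k_surv_fatality == k_surv`.

## Post-trial extrapolation

`extrapolation_factors()` scales the aggregate post-trial block:
avoided events pick up $k_{\mathrm{Inc}} k_{\mathrm{RRR}}$ per period,
fatality $k_\alpha$ (an error if any $k_\alpha \alpha_i > 1$), event costs
$k_C$, survival costs $k_{\mathrm{surv}}$. The factors multiply block
sums, not period recursions — that is the algebra the proofs use; a
per-period compounding reading would simply correspond to a different
effective $k$. Because $k_{\mathrm{Inc}} k_{\mathrm{RRR}}$ scales the
post-trial effect and its event-driven costs together, it cancels from
every post-trial cost-to-effect ratio exactly (a property test asserts
this to $10^{-12}$), which is why only *asymmetric* deviations between the
comparisons can move the price.

`price_invariance_check()` solves the price at both horizons;
`admissible_k_range()` finds the interval of one factor (others held at 1)
keeping the price change within a tolerance, read as *relative to the
baseline price* $\Delta p(1)$ (the alternative absolute reading differs
only by a constant factor and is recoverable by rescaling the tolerance).
The search expands a bracket by doubling/halving within $k \in [10^{-3},
10^3]$ and bisects to $10^{-6}$; a side where the bound is never exceeded
is reported open, and infeasible factor values (fatality bound) truncate
the interval at the feasibility edge. The price response is monotone in
each factor on either side of $k = 1$ in this model (each factor enters
one block term linearly), so bisection is adequate.
`linearized_sensitivity()` reports the central finite-difference
derivative at $k = 1$ with half-step $10^{-6}$, matching the observation
that the induced price change is approximately linear in $k - 1$.

## The decision procedure

`run_shortcut()` chains the steps: validate inputs → solve the trial
price → evaluate all condition reports → decide. When the scenario states
an explicit extension (a stipulated post-trial block or factors), the
numeric two-horizon check is the authority for the invariance verdict —
the propositions' algebra must agree with it, and a property test asserts
that it does. Without a stated extension, the verdict is algebraic: the
price is invariant when every nonzero downstream component is cancelled by
an applicable proposition and the RRR time path is common (with no stated
time variation this stability is an assumption, recorded in the trace).
Otherwise the engine reports a partial shortcut (which components may be
omitted; the remaining terms may still need extrapolation — the procedure
reports and stops rather than inventing an extrapolation method) or no
shortcut. Every decision carries an ordered trace of the steps executed,
and `shortcut_report_json()` renders it byte-deterministically, so the
branch taken can be audited.

## The scenario generator

`generate_scenario()` draws endpoint parameters from ranges a trial-based
evaluation would plausibly produce — incidence 0.01–0.5 per period,
severity weights 0.1–1, case fatality 0–0.9, event costs −20,000–0,
survival costs 0–50,000, RRR 0.05–0.5, non-price cost deltas 0–2,000,
threshold 50,000 per effect unit, one-period trials, scaling factors
0.5–2 over 1–5 post-trial periods — and then enforces the requested
proposition's equality/ratio constraints exactly. The comparator arm is
priced at value so the chain is active. Mirroring the derivations, the
generator zeroes the component a proposition is *not* about (event costs
for the survival-cost propositions, survival costs for the savings
propositions); the checker itself does not rely on this.

What the generator emulates is the *algebraic structure* of a summary
trial-period evaluation, which is what the propositions are claims about.
It does not emulate sampling noise in trial estimates, non-proportional
hazard patterns, endpoint correlation, or parameter uncertainty — so
passing property suites demonstrate the algebra and its implementation,
not that real evaluations satisfy the conditions. On empirical inputs the
conditions should be checked at a user-chosen tolerance, and the
admissible-deviation analysis used to judge how much violation the
pricing conclusion tolerates.

## Numerical choices and degenerate inputs

* Zero weighted effect raises a typed error (`vbp_undefined_icer`) rather
  than returning an infinite ICER.
* Discounting uses a constant per-period rate with the end-of-period
  convention, default 0 — the worked examples are undiscounted, and
  within-trial aggregates are treated as one block unless a per-period
  profile is supplied.
* When both direct avoided events and the incidence–RRR pathway are
  supplied, the direct values win and a consistency warning (classed
  `vbp_consistency_warning`) is emitted.
* Equality tolerances: `1e-9` relative for constructed scenarios
  (condition checks), `1e-12` for the exact-cancellation property tests,
  5% of the trial price as the default pricing tolerance.
* Money and effect units are labels only; formatted numbers with
  thousands separators are rejected at the config boundary.
* Property-suite sizes: 500 generated scenarios per proposition for the
  soundness suites, 100 perturbed siblings per proposition, 100 random
  survival curves for the lifetime-ICER invariance, 1,000 random
  scenarios for the price/ICER round trip.

## Known limitations

* No Markov or discrete-event simulation engine, no parametric
  survival-curve fitting, no probabilistic sensitivity analysis: the
  package's point is precisely to identify when those are unnecessary for
  the pricing conclusion, and to quantify tolerable deviations when they
  are nearly so.
* No QALY utility-mapping model: effects are weighted events; a unit
  labelled "QALYs" is accepted wherever the linear mapping from avoided
  events is defensible.
* Conditions are evaluated on summary parameters, not inferred from
  patient-level data, and no formal statistical test of proportionality
  over time is provided.
* Admissible ranges are computed factor-at-a-time; joint deviations in
  several factors can interact.

## A worked session

```{r example}
sc <- worked_example_scenario()
glance(compute_icer(sc, price = 900))
solve_vbp_price(sc)
solve_vbp_price(sc, "extended")
run_shortcut(sc)$outcome

inp <- as.list(hf_example_inputs())
do.call(solve_annual_price, inp)

sc2 <- generate_scenario(2, seed = 1)
tidy(check_proposition(sc2, 2))
verify_cancellation(sc2, "survival_costs")
```
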