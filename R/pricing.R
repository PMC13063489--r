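#' Operative willingness-to-pay threshold at a horizon
#'
#' Under value-based pricing the comparator B is itself priced so that its
#' ICER against the reference intervention A equals the threshold. When the
#' scenario's B-vs-A comparison carries a price, the operative threshold at
#' any horizon is therefore the B-vs-A ICER evaluated over that horizon at
#' that price (the D -> B -> A pricing chain); with a value-based `p_B` the
#' two coincide at the trial horizon. Without a priced B-vs-A comparison the
#' scenario's fixed `threshold` is used at every horizon.
#'
#' @inheritParams weighted_effect
#' @return Money per weighted-effect unit.
#' @export
effective_threshold <- function(scenario, horizon = "trial") {
  if (!is.na(scenario$b_vs_a$drug_price_delta)) {
    compute_icer(scenario, "b_vs_a", horizon = horizon)$total
  } else {
    scenario$threshold
  }
}

#' Solve for the value-based price
#'
#' Closed-form price at which the D-vs-B ICER equals the operative
#' threshold:
#' `delta_p = lambda * effect - nonprice - downstream`,
#' the rearrangement of the threshold condition. The absolute price is
#' `p_D = p_B + delta_p` when a comparator price is available.
#'
#' @inheritParams weighted_effect
#' @param horizon `"trial"` or `"extended"`.
#' @param absolute If `TRUE` return `p_B + delta_p` (requires
#'   `comparator_price`); default returns the incremental price `delta_p`.
#'   Negative implied prices are reported, not clamped: they are a
#'   meaningful pricing signal.
#' @return A single money amount.
#' @examples
#' solve_vbp_price(worked_example_scenario())              # 900
#' solve_vbp_price(worked_example_scenario(), "extended")  # 900, unchanged
#' @export
solve_vbp_price <- function(scenario, horizon = "trial", absolute = FALSE) {
  hs <- horizon_summary(scenario, "d_vs_b", horizon)
  if (!is.finite(hs$effect) || hs$effect <= 0) {
    abort("Weighted effect must be > 0 to solve for a price.",
          class = "vbp_undefined_icer")
  }
  lambda <- effective_threshold(scenario, horizon)
  dp <- lambda * hs$effect - scenario$d_vs_b$nonprice_cost_delta -
    hs$downstream
  if (absolute) {
    if (is.na(scenario$comparator_price)) {
      abort("`comparator_price` needed for an absolute price.",
            class = "vbp_pricing_error")
    }
    scenario$comparator_price + dp
  } else {
    dp
  }
}

#' Annual value-based price from trial-period totals
#'
#' Per-period (annual) price solving the trial-period threshold condition
#' `lambda = (p * T - savings) / effect`, i.e.
#' `p = (lambda * effect_per_year * T + savings) / T` with
#' `savings = incidence * rrr * T * event_cost`. Here `event_cost` is a
#' POSITIVE cost per event (hospitalization-cost style) and savings are
#' subtracted, unlike the signed event costs of the ICER decomposition
#' pathway; the two conventions are cross-tested against each other.
#'
#' @param incidence Baseline event incidence per person-year.
#' @param rrr Relative risk reduction.
#' @param event_cost Positive cost per event (money).
#' @param effect_per_year Health gain per year (e.g. QALYs/year).
#' @param threshold Willingness-to-pay threshold per effect unit.
#' @param duration Trial duration in years (> 0).
#' @return Money per year.
#' @examples
#' solve_annual_price(incidence = 0.15, rrr = 0.15, event_cost = 10000,
#'                    effect_per_year = 0.04, threshold = 50000,
#'                    duration = 3)   # 2225
#' @export
solve_annual_price <- function(incidence, rrr, event_cost, effect_per_year,
                               threshold, duration) {
  if (duration <= 0) {
    abort("`duration` must be > 0.", class = "vbp_pricing_error")
  }
  if (effect_per_year * duration <= 0) {
    abort("Total effect must be > 0 to solve for a price.",
          class = "vbp_undefined_icer")
  }
  savings <- incidence * rrr * duration * event_cost
  (threshold * effect_per_year * duration + savings) / duration
}

#' Pricing-chain residual
#'
#' Internal-consistency check of the D -> B -> A chain: the difference
#' `ICER_DvsB(price_d) - ICER_BvsA(stored price)` over a horizon. Zero when
#' both comparisons satisfy the value-based pricing condition at the same
#' threshold.
#'
#' @inheritParams weighted_effect
#' @param price_d Incremental price of D vs B to evaluate.
#' @param horizon `"trial"` or `"extended"`.
#' @return Money per weighted-effect unit (signed).
#' @export
pricing_chain_residual <- function(scenario, price_d, horizon = "trial") {
  if (is.na(scenario$b_vs_a$drug_price_delta)) {
    abort("B-vs-A must carry a price for a chain residual.",
          class = "vbp_pricing_error")
  }
  compute_icer(scenario, "d_vs_b", price = price_d,
               horizon = horizon)$total -
    compute_icer(scenario, "b_vs_a", horizon = horizon)$total
}
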