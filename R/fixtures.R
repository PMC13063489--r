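#' Two-endpoint worked example
#'
#' The stylized worked example contrasting a trial-only evaluation with an
#' extended-horizon evaluation: one non-fatal endpoint (severity weight
#' 0.2, saving 5,000 per avoided event) and one fatal endpoint (weight 1.0,
#' survival cost 30,000 per avoided death), avoided events 0.10 and 0.02,
#' non-price drug cost 1,000, threshold 50,000. The stipulated post-trial
#' block (weighted effect 0.02, downstream cost 1,000) is chosen so that
#' its downstream-to-effect ratio equals the threshold, making the implied
#' value-based price (900) invariant to extending the horizon.
#'
#' @return A [vbp_scenario()].
#' @examples
#' sc <- worked_example_scenario()
#' solve_vbp_price(sc)              # 900
#' solve_vbp_price(sc, "extended")  # 900
#' @export
worked_example_scenario <- function() {
  vbp_scenario(
    endpoints = tibble(
      id = c("nonfatal", "fatal"),
      weight = c(0.2, 1.0),
      incidence = NA_real_,
      fatality = c(0, 1),
      event_cost = c(-5000, 0),
      survival_cost = c(0, 30000),
      survival_cost_fatality = NA_real_
    ),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = c(0.10, 0.02),
                            nonprice_cost_delta = 1000),
    threshold = 50000,
    trial_duration = 1,
    effect_unit = "weighted events",
    post_trial = list(d_vs_b = list(effect = 0.02, downstream = 1000))
  )
}

#' Heart-failure hospitalization illustration inputs
#'
#' Inputs for the annual-price illustration modeled on a heart-failure
#' trial (sacubitril/valsartan vs valsartan in HFpEF, PARAGON-HF pattern):
#' reduced hospitalizations with no material survival difference. Control
#' hospitalization incidence 0.15 events/person-year, relative reduction
#' 0.15, cost 10,000 per hospitalization, annual QALY gain 0.04, threshold
#' 50,000 per QALY, trial duration 3 years.
#'
#' @return A one-row tibble of the annual-price solver's inputs.
#' @examples
#' inp <- hf_example_inputs()
#' do.call(solve_annual_price, as.list(inp))   # 2225 per year
#' @export
hf_example_inputs <- function() {
  tibble(
    incidence = 0.15,
    rrr = 0.15,
    event_cost = 10000,
    effect_per_year = 0.04,
    threshold = 50000,
    duration = 3
  )
}
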