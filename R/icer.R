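#' Avoided events per endpoint
#'
#' Incremental events avoided over the trial period for one comparison. When
#' the comparison supplies avoided events directly (`delta_ce`) those are
#' returned; otherwise avoided events are the product of baseline incidence,
#' relative risk reduction, and duration: `Inc_i * RRR_i * T`.
#'
#' @param scenario A [vbp_scenario()].
#' @param comparison `"d_vs_b"` (default) or `"b_vs_a"`, or a
#'   [vbp_comparison()] object.
#' @param endpoint Optional endpoint id(s) to restrict to; all endpoints by
#'   default. Unknown ids are an error.
#' @param duration Duration in periods; defaults to the scenario's trial
#'   duration.
#'
#' @return A tibble with columns `id` and `events_avoided`.
#' @examples
#' # 0.15 events/person-year, 15% relative reduction, 3 years -> 0.0675
#' sc <- vbp_scenario(
#'   endpoints = vbp_endpoint("hosp", weight = 1, incidence = 0.15),
#'   d_vs_b = vbp_comparison("d_vs_b", rrr = 0.15),
#'   threshold = 50000, trial_duration = 3
#' )
#' avoided_events(sc)
#' @export
avoided_events <- function(scenario, comparison = "d_vs_b", endpoint = NULL,
                           duration = NULL) {
  cmp <- get_comparison(scenario, comparison)
  sc <- scenario
  if (!is.null(duration)) sc$trial_duration <- duration
  tb <- trial_block(sc, cmp)
  if (!is.null(endpoint)) {
    unknown <- setdiff(endpoint, tb$id)
    if (length(unknown)) {
      abort(paste0("Unknown endpoint id(s): ",
                   paste(unknown, collapse = ", ")),
            class = "vbp_scenario_error")
    }
    tb <- tb[tb$id %in% endpoint, , drop = FALSE]
  }
  tibble(id = tb$id, events_avoided = tb$delta_ce)
}

#' Weighted incremental effect
#'
#' The ICER denominator: severity-weighted avoided events
#' `sum(delta_ce_i * w_i)` for one comparison over the chosen horizon.
#'
#' @inheritParams avoided_events
#' @param horizon `"trial"` (default) or `"extended"` (trial plus post-trial
#'   block).
#' @return A single number in the scenario's effect unit.
#' @export
weighted_effect <- function(scenario, comparison = "d_vs_b",
                            horizon = "trial") {
  horizon_summary(scenario, comparison, horizon)$effect
}

#' Downstream cost
#'
#' The event-driven cost components of the ICER numerator: savings from
#' avoided non-fatal events, `sum(delta_ce_i * (1 - alpha_i) * C_CE_i)`, plus
#' survival costs of avoided deaths, `sum(delta_ce_i * alpha_i * C_s_i)`,
#' plus -- when the case-fatality subcase fields are present -- survival
#' costs of deaths averted through reduced case fatality,
#' `sum(delta_alpha_i * C_s(alpha)_i)`. Event costs are signed, so a
#' negative `event_cost` contributes negative downstream cost (a saving).
#'
#' @inheritParams weighted_effect
#' @return A single money amount.
#' @export
downstream_cost <- function(scenario, comparison = "d_vs_b",
                            horizon = "trial") {
  horizon_summary(scenario, comparison, horizon)$downstream
}

#' ICER decomposition
#'
#' Decomposes the incremental cost-effectiveness ratio of one comparison at
#' a given incremental drug price into its three additive terms: the drug
#' cost term `(price + nonprice) / effect`, the savings term, and the
#' survival-cost term. The total is
#' `(price + nonprice + downstream) / weighted effect`.
#'
#' @inheritParams weighted_effect
#' @param price Incremental acquisition price to evaluate at; defaults to
#'   the comparison's stored `drug_price_delta`.
#' @return An object of class `vbp_icer` with fields `term_drug`,
#'   `term_savings`, `term_survival`, `weighted_effect`, `downstream_cost`
#'   and `total`. With a stipulated (aggregate) post-trial block the
#'   savings/survival split is unavailable and those terms are `NA`; the
#'   total is always defined.
#' @examples
#' sc <- worked_example_scenario()
#' compute_icer(sc, price = 900)$total   # equals the 50,000 threshold
#' @export
compute_icer <- function(scenario, comparison = "d_vs_b", price = NULL,
                         horizon = "trial") {
  cmp <- get_comparison(scenario, comparison)
  price <- price %||% cmp$drug_price_delta
  if (is.null(price) || is.na(price)) {
    abort("No price supplied and the comparison carries none.",
          class = "vbp_pricing_error")
  }
  hs <- horizon_summary(scenario, cmp, horizon)
  if (!is.finite(hs$effect) || hs$effect <= 0) {
    abort("Weighted effect must be > 0 for a defined ICER.",
          class = "vbp_undefined_icer")
  }
  structure(
    list(
      comparison = cmp$label,
      horizon = horizon,
      price = price,
      term_drug = (price + cmp$nonprice_cost_delta) / hs$effect,
      term_savings = hs$savings / hs$effect,
      term_survival = hs$survival / hs$effect,
      weighted_effect = hs$effect,
      downstream_cost = hs$downstream,
      total = (price + cmp$nonprice_cost_delta + hs$downstream) / hs$effect,
      effect_unit = scenario$effect_unit
    ),
    class = "vbp_icer"
  )
}

#' @export
print.vbp_icer <- function(x, ...) {
  cat("<vbp_icer> ", x$comparison, ", ", x$horizon, " horizon\n", sep = "")
  cat(sprintf("  drug term:      %12.2f\n", x$term_drug))
  cat(sprintf("  savings term:   %12.2f\n", x$term_savings))
  cat(sprintf("  survival term:  %12.2f\n", x$term_survival))
  cat(sprintf("  total ICER:     %12.2f per %s\n", x$total, x$effect_unit))
  invisible(x)
}

#' Present value of a per-period stream
#'
#' Discounts a stream of per-period amounts at a constant per-period rate
#' with the end-of-period convention: `sum(v_t / (1 + rate)^t)`, t = 1..n.
#'
#' @param values Numeric vector of per-period amounts (money or effects).
#' @param rate Per-period discount rate (>= 0).
#' @param times Period indices; defaults to `1:length(values)`.
#' @return The present value (a single number).
#' @examples
#' discount_stream(rep(100, 10), rate = 0.03)
#' @export
discount_stream <- function(values, rate = 0, times = seq_along(values)) {
  if (rate < 0) {
    abort("`rate` must be >= 0.", class = "vbp_scenario_error")
  }
  sum(values / (1 + rate)^times)
}

#' Build a per-period survival profile
#'
#' A per-period table for lifetime ICER computation: survival weight,
#' incremental effect, savings, and (optionally per-period) incremental
#' price and non-price cost.
#'
#' @param data Data frame with columns `period`, `survival`, `effect`,
#'   `savings` and optionally `price`, `nonprice`.
#' @param price,nonprice Per-period incremental price / non-price cost used
#'   when `data` lacks the corresponding columns (recycled).
#' @return A tibble of class `vbp_survival_profile`.
#' @export
survival_profile <- function(data, price = NULL, nonprice = 0) {
  df <- as_tibble(data)
  need <- c("period", "survival", "effect", "savings")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Survival profile lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vbp_scenario_error")
  }
  if (!"price" %in% names(df)) {
    if (is.null(price)) {
      abort("Supply `price` (per period) or a `price` column.",
            class = "vbp_scenario_error")
    }
    df$price <- rep_len(as.numeric(price), nrow(df))
  }
  if (!"nonprice" %in% names(df)) {
    df$nonprice <- rep_len(as.numeric(nonprice), nrow(df))
  }
  df <- df[order(df$period), , drop = FALSE]
  if (any(df$survival < 0 | df$survival > 1)) {
    abort("Survival must lie in [0, 1].", class = "vbp_scenario_error")
  }
  if (is.unsorted(rev(df$survival), strictly = FALSE)) {
    abort("Survival must be non-increasing over periods.",
          class = "vbp_scenario_error")
  }
  class(df) <- c("vbp_survival_profile", class(df))
  df
}

#' Read a survival profile from CSV
#'
#' Expects a header row `period,survival,effect,savings` with optional
#' `price` and `nonprice` columns; plain decimal numbers only.
#'
#' @param path Path to the CSV file.
#' @inheritParams survival_profile
#' @return A tibble of class `vbp_survival_profile`.
#' @export
read_survival_profile <- function(path, price = NULL, nonprice = 0) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("survival", "effect", "savings", "price",
                          "nonprice"), names(df))) {
    df[[col]] <- as_money(df[[col]], col)
  }
  survival_profile(df, price = price, nonprice = nonprice)
}

#' Survival-weighted lifetime ICER
#'
#' Lifetime ICER from a per-period profile:
#' `sum(S_t * (price_t + nonprice_t - savings_t)) / sum(S_t * effect_t)`.
#' With constant per-period increments the survival weighting is common to
#' the numerator and denominator and cancels: the ratio equals the single
#' per-period ratio for any non-increasing survival curve, which is why a
#' trial-period price solve can stand in for a lifetime model under the
#' stability conditions.
#'
#' @param profile A [survival_profile()].
#' @return Money per effect unit.
#' @examples
#' pr <- survival_profile(
#'   data.frame(period = 1:20, survival = 0.97^(1:20),
#'              effect = 0.04, savings = 225),
#'   price = 2225
#' )
#' lifetime_icer(pr)   # 50,000 regardless of the survival curve
#' @export
lifetime_icer <- function(profile) {
  stopifnot(inherits(profile, "vbp_survival_profile"))
  denom <- sum(profile$survival * profile$effect)
  if (!is.finite(denom) || denom <= 0) {
    abort("Survival-weighted effect mass must be > 0.",
          class = "vbp_undefined_icer")
  }
  num <- sum(profile$survival *
               (profile$price + profile$nonprice - profile$savings))
  num / denom
}
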