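# Scenario <-> plain-list conversion used by the YAML config reader/writer.

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

comparison_to_list <- function(cmp) {
  drop_null(list(
    rrr = cmp$rrr,
    delta_ce = cmp$delta_ce,
    drug_price_delta = if (!is.na(cmp$drug_price_delta))
      cmp$drug_price_delta,
    nonprice_cost_delta = cmp$nonprice_cost_delta,
    fatality = cmp$fatality,
    delta_fatality = cmp$delta_fatality
  ))
}

factors_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  if (inherits(f, "vbp_factors")) {
    drop_null(unclass(f))
  } else {
    purrr::map(f, ~ drop_null(unclass(.x)))
  }
}

comparison_from_list <- function(label, x) {
  x <- x %||% list()
  num <- function(v, what) if (is.null(v)) NULL else
    vapply(v, as_money, numeric(1), what = what)
  vbp_comparison(
    label,
    rrr = num(x$rrr, "rrr"),
    delta_ce = num(x$delta_ce, "delta_ce"),
    drug_price_delta = if (is.null(x$drug_price_delta)) NA_real_ else
      as_money(x$drug_price_delta, "drug_price_delta"),
    nonprice_cost_delta = as_money(x$nonprice_cost_delta %||% 0,
                                   "nonprice_cost_delta"),
    fatality = num(x$fatality, "fatality"),
    delta_fatality = num(x$delta_fatality, "delta_fatality")
  )
}

factors_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  one <- function(y) do.call(extrapolation_factors, y)
  if (any(c("d_vs_b", "b_vs_a") %in% names(x))) {
    purrr::map(x, one)
  } else {
    one(x)
  }
}

#' Write a scenario configuration
#'
#' Serializes a scenario to a YAML config mirroring the domain types:
#' endpoint fields, the two comparisons, threshold and horizon settings,
#' and any stipulated post-trial block or scaling factors. The round trip
#' through [read_scenario()] reproduces the scenario exactly.
#'
#' @inheritParams weighted_effect
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "vbp_scenario"))
  eps <- purrr::map(seq_len(nrow(scenario$endpoints)), function(i) {
    row <- as.list(scenario$endpoints[i, ])
    drop_null(list(
      id = row$id, weight = row$weight,
      incidence = if (!is.na(row$incidence)) row$incidence,
      fatality = row$fatality,
      event_cost = row$event_cost,
      survival_cost = row$survival_cost,
      survival_cost_fatality = if (!is.na(row$survival_cost_fatality))
        row$survival_cost_fatality
    ))
  })
  cfg <- drop_null(list(
    threshold = scenario$threshold,
    comparator_price = if (!is.na(scenario$comparator_price))
      scenario$comparator_price,
    trial_duration = scenario$trial_duration,
    discount_rate = scenario$discount_rate,
    effect_unit = scenario$effect_unit,
    endpoints = eps,
    comparisons = list(
      d_vs_b = comparison_to_list(scenario$d_vs_b),
      b_vs_a = comparison_to_list(scenario$b_vs_a)
    ),
    post_trial = scenario$post_trial,
    factors = factors_to_list(scenario$factors)
  ))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration
#'
#' Reads a YAML scenario config written by [write_scenario()] (or by
#' hand). Money fields must be plain decimals; values with thousands
#' separators (which YAML parses as strings) are rejected with a parse
#' error.
#'
#' @param path Path to the YAML file.
#' @return A [vbp_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$endpoints) || !length(cfg$endpoints)) {
    abort("Config contains no endpoints.", class = "vbp_parse_error")
  }
  endpoints <- dplyr::bind_rows(purrr::map(cfg$endpoints, function(e) {
    vbp_endpoint(
      id = e$id, weight = e$weight,
      incidence = e$incidence %||% NA_real_,
      fatality = e$fatality %||% 0,
      event_cost = e$event_cost %||% 0,
      survival_cost = e$survival_cost %||% 0,
      survival_cost_fatality = e$survival_cost_fatality %||% NA_real_
    )
  }))
  vbp_scenario(
    endpoints = endpoints,
    d_vs_b = comparison_from_list("d_vs_b", cfg$comparisons$d_vs_b),
    b_vs_a = comparison_from_list("b_vs_a", cfg$comparisons$b_vs_a),
    threshold = as_money(cfg$threshold, "threshold"),
    comparator_price = if (is.null(cfg$comparator_price)) NA_real_ else
      as_money(cfg$comparator_price, "comparator_price"),
    trial_duration = cfg$trial_duration %||% 1,
    discount_rate = cfg$discount_rate %||% 0,
    effect_unit = cfg$effect_unit %||% "weighted events",
    post_trial = cfg$post_trial,
    factors = factors_from_list(cfg$factors)
  )
}
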