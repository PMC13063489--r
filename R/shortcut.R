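#' Run the shortcut decision procedure
#'
#' End-to-end decision procedure determining whether extrapolation beyond
#' the trial period is needed for the implied value-based price:
#'
#' 1. validate the trial-period inputs (endpoints, threshold);
#' 2. compute the trial-period ICER components and solve for the
#'    trial-based price `p^(T)`;
#' 3. check the applicability conditions of every cancellation proposition;
#' 4. if the applicable propositions imply price invariance (every nonzero
#'    downstream component cancels and the RRR time path is common) -- or
#'    the scenario carries an explicit post-trial block whose two-horizon
#'    price check passes -- set the price to `p^(T)` and stop;
#' 5. otherwise report which downstream component(s) can be omitted
#'    (partial shortcut) or that no shortcut applies.
#'
#' @inheritParams check_proposition
#' @param price_tolerance Fraction of the trial price within which the
#'   two-horizon price change counts as invariant (default 0.05).
#' @return An object of class `vbp_shortcut`: `outcome` (one of
#'   `"price_invariant"`, `"partial_shortcut"`, `"no_shortcut"`), `price`
#'   (the trial-based incremental price; also `price_absolute` when a
#'   comparator price is available), `omitted_components`, the full list of
#'   condition `reports`, the numeric `invariance` check when an extension
#'   is stated, and an ordered `trace` of the steps executed.
#' @examples
#' run_shortcut(worked_example_scenario())
#' @export
run_shortcut <- function(scenario, tolerance = 1e-9,
                         price_tolerance = 0.05) {
  trace <- character(0)
  log_step <- function(msg) trace <<- c(trace, msg)

  # step 1: inputs
  if (!inherits(scenario, "vbp_scenario") ||
      is.null(scenario$endpoints) || nrow(scenario$endpoints) < 1L) {
    abort("step 1: scenario must contain at least one endpoint.",
          class = "vbp_scenario_error")
  }
  if (is.null(scenario$threshold) || !is.finite(scenario$threshold)) {
    abort("step 1: scenario lacks a willingness-to-pay threshold.",
          class = "vbp_scenario_error")
  }
  log_step(sprintf("step 1: inputs validated (%d endpoint(s), threshold %g)",
                   nrow(scenario$endpoints), scenario$threshold))

  # step 2: trial-period components and price
  icer_terms <- compute_icer(scenario, "d_vs_b", price = 0,
                             horizon = "trial")
  p_trial <- solve_vbp_price(scenario, "trial")
  log_step(sprintf(
    "step 2: trial weighted effect %.6g, downstream cost %.6g, trial-based price %.6g",
    icer_terms$weighted_effect, icer_terms$downstream_cost, p_trial))

  # step 3: applicability conditions
  reports <- applicable_propositions(scenario, tolerance)
  applicable <- purrr::keep(reports, ~ .x$applicable)
  log_step(sprintf(
    "step 3: propositions applicable: %s",
    if (length(applicable))
      paste(vapply(applicable, `[[`, "", "proposition"), collapse = ", ")
    else "none"))

  cancelled_union <- unique(unlist(purrr::map(applicable, "cancelled")))
  hs <- horizon_summary(scenario, "d_vs_b", "trial")
  present <- c(
    if (isTRUE(abs(hs$savings) > 0)) "savings",
    if (isTRUE(abs(hs$survival) > 0)) "survival_costs"
  )
  stable <- rrr_path_common(scenario, tolerance)
  invariant_by_prop <- stable && all(present %in% cancelled_union)

  has_extension <- !is.null(scenario$post_trial) ||
    !is.null(scenario$factors)
  invariance <- NULL
  if (has_extension) {
    invariance <- price_invariance_check(scenario,
                                         tolerance = price_tolerance)
    log_step(sprintf(
      "step 4: two-horizon check: price %.6g -> %.6g (delta %.3g), invariant: %s",
      invariance$price_trial, invariance$price_extended,
      invariance$delta_price, invariance$invariant))
  }

  invariant <- if (has_extension) {
    # an explicit extension is the authority; propositions must agree with it
    isTRUE(invariance$invariant)
  } else {
    invariant_by_prop
  }

  if (invariant) {
    log_step("step 4: price invariance established; price set to the trial solve")
    outcome <- "price_invariant"
    omitted <- cancelled_union
  } else if (length(cancelled_union)) {
    log_step(sprintf(
      "step 5: partial shortcut; component(s) omissible: %s; remaining terms may need extrapolation",
      paste(cancelled_union, collapse = ", ")))
    outcome <- "partial_shortcut"
    omitted <- cancelled_union
  } else {
    log_step("step 5: no cancellation condition holds; full extrapolation required")
    outcome <- "no_shortcut"
    omitted <- character(0)
  }

  structure(
    list(
      outcome = outcome,
      price = if (outcome == "price_invariant") p_trial else NULL,
      price_trial = p_trial,
      price_absolute = if (outcome == "price_invariant" &&
                           !is.na(scenario$comparator_price))
        scenario$comparator_price + p_trial,
      omitted_components = omitted,
      reports = reports,
      invariance = invariance,
      trace = trace,
      tolerance = tolerance,
      price_tolerance = price_tolerance
    ),
    class = "vbp_shortcut"
  )
}

#' @export
print.vbp_shortcut <- function(x, ...) {
  cat("<vbp_shortcut> outcome: ", x$outcome, "\n", sep = "")
  if (!is.null(x$price)) {
    cat(sprintf("  price (incremental): %.4f\n", x$price))
  }
  if (!is.null(x$price_absolute)) {
    cat(sprintf("  price (absolute):    %.4f\n", x$price_absolute))
  }
  if (length(x$omitted_components)) {
    cat("  omissible components:",
        paste(x$omitted_components, collapse = ", "), "\n")
  }
  cat("  trace:\n")
  for (s in x$trace) cat("    ", s, "\n", sep = "")
  invisible(x)
}

#' Deterministic JSON report for a shortcut decision
#'
#' Serializes a [run_shortcut()] result (outcome, prices, omitted
#' components, per-proposition condition tables and the step trace) as a
#' canonical JSON string: identical inputs yield byte-identical reports.
#'
#' @param decision A `vbp_shortcut` object.
#' @param digits Significant digits for numeric fields (default 10).
#' @return A JSON string (class `json`).
#' @export
shortcut_report_json <- function(decision, digits = 10) {
  stopifnot(inherits(decision, "vbp_shortcut"))
  payload <- list(
    outcome = decision$outcome,
    price = decision$price,
    price_trial = decision$price_trial,
    price_absolute = decision$price_absolute,
    omitted_components = as.list(decision$omitted_components),
    propositions = purrr::map(decision$reports, function(r) {
      list(
        proposition = r$proposition,
        applicable = r$applicable,
        price_invariant = r$price_invariant,
        cancelled = as.list(r$cancelled),
        conditions = purrr::map(seq_len(nrow(r$conditions)), function(i) {
          list(
            condition = r$conditions$condition[i],
            holds = r$conditions$holds[i],
            deviation = unname(r$conditions$deviation[i])
          )
        })
      )
    }),
    invariance = if (!is.null(decision$invariance)) {
      list(
        price_trial = decision$invariance$price_trial,
        price_extended = decision$invariance$price_extended,
        delta_price = decision$invariance$delta_price,
        invariant = decision$invariance$invariant,
        tolerance = decision$invariance$tolerance
      )
    },
    trace = as.list(decision$trace)
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = digits,
                   null = "null", na = "null")
}
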