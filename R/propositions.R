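# Per-comparison structural ratios used by the cancellation conditions.
# All "per unit" quantities are per unit of weighted effect; the per-death
# survival cost is per avoided death (case-fatality subcase denominator).
comparison_ratios <- function(scenario, comparison) {
  tb <- trial_block(scenario, comparison)
  eff <- sum(tb$delta_ce * tb$weight)
  deaths <- sum(tb$delta_ce * tb$fatality) + sum(tb$delta_fatality)
  list(
    fatality = tb$fatality,
    weight = tb$weight,
    event_cost = tb$event_cost,
    survival_cost = tb$survival_cost,
    rrr_ratio = if (all(!is.na(scenario$endpoints$incidence)) &&
                    all(scenario$endpoints$incidence > 0)) {
      tb$delta_ce / (scenario$endpoints$incidence * scenario$trial_duration)
    },
    savings_rate = sum(tb$delta_ce * (1 - tb$fatality) * tb$event_cost) / eff,
    gross_cost_rate = sum(tb$delta_ce * tb$event_cost) / eff,
    fatal_cost_rate = sum(tb$delta_ce * tb$fatality * tb$event_cost) / eff,
    survival_rate = sum(tb$delta_ce * tb$fatality * tb$survival_cost) / eff,
    death_cost_rate = if (deaths > 0) {
      (sum(tb$delta_ce * tb$fatality * tb$survival_cost) +
         sum(tb$delta_fatality * tb$survival_cost_fatality)) / deaths
    } else NA_real_,
    effect = eff,
    deaths = deaths
  )
}

cond_row <- function(name, dev, tolerance, holds = NULL) {
  dev <- suppressWarnings(as.numeric(dev))
  tibble(
    condition = name,
    deviation = dev,
    holds = holds %||% (is.finite(dev) && dev <= tolerance)
  )
}

# Is the RRR time path common to both comparisons? With no extrapolation
# factors the scenario specifies no time variation, so the stability
# assumption holds by construction; with common factors it holds; with
# per-comparison factors it requires a common avoided-event growth
# k_inc * k_rrr * periods.
rrr_path_common <- function(scenario, tolerance = 1e-9) {
  f <- scenario$factors
  if (is.null(f) || inherits(f, "vbp_factors")) return(TRUE)
  g <- vapply(c("d_vs_b", "b_vs_a"), function(l) {
    fi <- f[[l]] %||% extrapolation_factors()
    fi$k_inc * fi$k_rrr * fi$periods
  }, numeric(1))
  rel_spread(g) <= tolerance
}

factors_common_dev <- function(scenario) {
  f <- scenario$factors
  if (is.null(f)) return(NA_real_)
  if (inherits(f, "vbp_factors")) return(0)
  fd <- f$d_vs_b %||% extrapolation_factors()
  fb <- f$b_vs_a %||% extrapolation_factors()
  devs <- vapply(c("k_inc", "k_rrr", "k_alpha", "k_cost", "k_surv",
                   "periods"),
                 function(nm) rel_spread(c(fd[[nm]], fb[[nm]])), numeric(1))
  max(devs)
}

proposition_cancels <- list(
  "1" = c("savings", "survival_costs"),
  "2" = "survival_costs", "3" = "survival_costs", "4" = "survival_costs",
  "5" = "savings", "6" = "savings", "7" = "savings",
  "subcase" = "survival_costs"
)

#' Check one cancellation proposition
#'
#' Evaluates, for a scenario, the sufficient conditions under which a
#' downstream component (savings from avoided events and/or survival costs)
#' cancels from the value-based pricing condition:
#'
#' * **1** — single endpoint, equal case fatality across comparisons: both
#'   savings and survival costs are neutralized.
#' * **2** — equal case fatality across endpoints (and comparisons) and a
#'   common-scalar RRR within each comparison: survival costs cancel.
#' * **3** — post-trial change entering through common scaling factors, with
#'   a common survival-cost ratio (weighted survival cost per unit weighted
#'   effect) across comparisons: changing survival costs leave the price
#'   unchanged.
#' * **4** — equal case fatality, equal severity weights and equal survival
#'   cost across endpoints: survival costs cancel.
#' * **5** — equal case fatality and common-scalar RRR: savings cancel.
#' * **6** — common post-trial scaling factors with common event-cost ratios
#'   across comparisons: changing savings leave the price unchanged.
#' * **7** — equal case fatality, equal weights and equal event unit costs:
#'   savings cancel.
#' * **subcase** — case-fatality reductions with their own survival cost:
#'   survival costs cancel when the survival cost per avoided death is
#'   common across comparisons and disease-specific and disease-unrelated
#'   survival expenditures grow proportionally.
#'
#' "Equal" and "constant ratio" are tested with a relative tolerance:
#' tight by default for constructed scenarios; pass a looser value for
#' noisy empirical inputs.
#'
#' @inheritParams weighted_effect
#' @param id Proposition id: 1 through 7, or `"subcase"`.
#' @param tolerance Relative tolerance for equality/proportionality
#'   conditions (default 1e-9).
#' @return An object of class `vbp_condition_report`: the evaluated
#'   condition table, the overall `applicable` verdict, the `cancelled`
#'   component set, and whether the proposition also implies an unchanged
#'   price given the RRR-stability condition (`price_invariant`).
#' @export
check_proposition <- function(scenario, id, tolerance = 1e-9) {
  id <- as.character(id)
  if (!id %in% c(as.character(1:7), "subcase")) {
    abort(paste0("Unknown proposition id: ", id),
          class = "vbp_proposition_error")
  }
  m <- nrow(scenario$endpoints)
  if (id == "1" && m > 1L) {
    abort("Proposition 1 applies to single-endpoint scenarios only.",
          class = "vbp_proposition_error")
  }
  if (id == "subcase") {
    has_sub <- !is.null(scenario$d_vs_b$delta_fatality) &&
      any(!is.na(scenario$endpoints$survival_cost_fatality))
    if (!has_sub) {
      abort("Subcase fields (delta_fatality, survival_cost_fatality) absent.",
            class = "vbp_proposition_error")
    }
  }
  rd <- comparison_ratios(scenario, "d_vs_b")
  # an unspecified B-vs-A comparison contributes no data of its own;
  # across-comparison equality conditions then bind on D-vs-B alone
  rb <- tryCatch(comparison_ratios(scenario, "b_vs_a"),
                 vbp_scenario_error = function(e) NULL)
  cmb <- function(field) c(rd[[field]], if (!is.null(rb)) rb[[field]])

  eq_fatality <- cond_row(
    "case fatality equal across endpoints and comparisons",
    rel_spread(cmb("fatality")), tolerance
  )
  common_rrr <- cond_row(
    "common-scalar RRR within each comparison",
    if (is.null(rd$rrr_ratio)) NA_real_ else
      max(rel_spread(rd$rrr_ratio),
          if (!is.null(rb) && !is.null(rb$rrr_ratio))
            rel_spread(rb$rrr_ratio) else 0),
    tolerance
  )
  eq_weights <- cond_row("severity weights equal across endpoints",
                         rel_spread(rd$weight), tolerance)

  conditions <- switch(
    id,
    "1" = bind_rows(
      cond_row("single endpoint", 0, tolerance, holds = m == 1L),
      cond_row("case fatality equal across comparisons",
               rel_spread(cmb("fatality")), tolerance)
    ),
    "2" = bind_rows(eq_fatality, common_rrr),
    "3" = bind_rows(
      cond_row("post-trial scaling factors supplied", 0, tolerance,
               holds = !is.null(scenario$factors)),
      cond_row("scaling factors common to both comparisons",
               factors_common_dev(scenario), tolerance),
      cond_row("survival-cost ratio common across comparisons",
               rel_spread(cmb("survival_rate")), tolerance)
    ),
    "4" = bind_rows(
      eq_fatality, eq_weights,
      cond_row("survival cost equal across endpoints",
               rel_spread(rd$survival_cost), tolerance)
    ),
    "5" = bind_rows(eq_fatality, common_rrr),
    "6" = bind_rows(
      cond_row("post-trial scaling factors supplied", 0, tolerance,
               holds = !is.null(scenario$factors)),
      cond_row("scaling factors common to both comparisons",
               factors_common_dev(scenario), tolerance),
      cond_row("event-cost ratio common across comparisons",
               rel_spread(cmb("gross_cost_rate")),
               tolerance),
      cond_row("fatal event-cost ratio common across comparisons",
               rel_spread(cmb("fatal_cost_rate")),
               tolerance)
    ),
    "7" = bind_rows(
      eq_fatality, eq_weights,
      cond_row("event unit cost equal across endpoints",
               rel_spread(rd$event_cost), tolerance)
    ),
    "subcase" = bind_rows(
      cond_row("case-fatality reduction and its survival cost supplied", 0,
               tolerance, holds = TRUE),
      cond_row("survival cost per avoided death common across comparisons",
               rel_spread(cmb("death_cost_rate")),
               tolerance),
      cond_row("proportional survival-expenditure growth",
               subcase_growth_dev(scenario), tolerance)
    )
  )

  applicable <- all(conditions$holds)
  stable <- rrr_path_common(scenario, tolerance)
  price_invariant <- applicable &&
    (if (id %in% c("3", "6")) TRUE else stable)
  structure(
    list(
      proposition = id,
      conditions = conditions,
      applicable = applicable,
      cancelled = if (applicable) proposition_cancels[[id]] else character(0),
      price_invariant = price_invariant,
      tolerance = tolerance
    ),
    class = "vbp_condition_report"
  )
}

# Deviation from proportional growth of the two survival-expenditure
# streams: the case-fatality survival cost must scale by the same factor as
# the event survival cost, in both comparisons. No factors: no growth is
# modeled, deviation 0.
subcase_growth_dev <- function(scenario) {
  f <- scenario$factors
  if (is.null(f)) return(0)
  fl <- if (inherits(f, "vbp_factors")) list(d_vs_b = f, b_vs_a = f) else f
  devs <- vapply(fl, function(fi) {
    rel_spread(c(fi$k_surv, fi$k_surv_fatality %||% fi$k_surv))
  }, numeric(1))
  max(devs)
}

#' @export
print.vbp_condition_report <- function(x, ...) {
  cat("<vbp_condition_report> proposition ", x$proposition, "\n", sep = "")
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("  [%s] %s (deviation %.3g)\n",
                if (isTRUE(x$conditions$holds[i])) "ok" else "FAIL",
                x$conditions$condition[i], x$conditions$deviation[i]))
  }
  cat("  applicable:      ", x$applicable, "\n")
  cat("  cancelled:       ",
      if (length(x$cancelled)) paste(x$cancelled, collapse = ", ") else
        "(none)", "\n")
  cat("  price invariant: ", x$price_invariant, "\n")
  invisible(x)
}

# Chain-consistent price solve used by the cancellation verifier: the
# operative threshold is the B-vs-A ICER at its stored price, recomputed
# for the same (possibly component-stripped) model, so that removing a
# component from BOTH comparisons is coherent. `denominator = "deaths"`
# switches to the case-fatality subcase structure, whose effect measure is
# avoided deaths.
chain_price <- function(scenario, horizon = "trial", strip = NULL,
                        denominator = c("weighted", "deaths")) {
  denominator <- match.arg(denominator)
  if (is.na(scenario$b_vs_a$drug_price_delta)) {
    abort("B-vs-A must carry a price for chain-based verification.",
          class = "vbp_pricing_error")
  }
  hd <- horizon_summary(scenario, "d_vs_b", horizon, strip = strip)
  hb <- horizon_summary(scenario, "b_vs_a", horizon, strip = strip)
  den_d <- if (denominator == "weighted") hd$effect else hd$deaths
  den_b <- if (denominator == "weighted") hb$effect else hb$deaths
  if (!is.finite(den_d) || den_d <= 0 || !is.finite(den_b) || den_b <= 0) {
    abort("Effect denominator must be > 0 on both sides of the chain.",
          class = "vbp_undefined_icer")
  }
  lambda <- (scenario$b_vs_a$drug_price_delta +
               scenario$b_vs_a$nonprice_cost_delta + hb$downstream) / den_b
  lambda * den_d - scenario$d_vs_b$nonprice_cost_delta - hd$downstream
}

#' Verify a cancellation numerically
#'
#' Brute-force check of a proposition's claim: solve the chain-consistent
#' value-based price of D with the full model and again with the component
#' removed from BOTH comparisons, and return the signed difference. The
#' residual is ~0 (to float precision) exactly when the relevant
#' proposition's conditions hold, and nonzero otherwise (whenever the
#' component actually contributes).
#'
#' @inheritParams weighted_effect
#' @param component `"savings"` or `"survival_costs"`.
#' @param horizon `"trial"` (default) or `"extended"`.
#' @param denominator `"auto"` (deaths-based when case-fatality subcase
#'   fields are present, weighted effect otherwise), `"weighted"`, or
#'   `"deaths"`.
#' @return Signed residual in money units.
#' @export
verify_cancellation <- function(scenario, component = c("savings",
                                                        "survival_costs"),
                                horizon = "trial",
                                denominator = c("auto", "weighted",
                                                "deaths")) {
  component <- match.arg(component)
  denominator <- match.arg(denominator)
  if (denominator == "auto") {
    denominator <- if (any((scenario$d_vs_b$delta_fatality %||% 0) != 0))
      "deaths" else "weighted"
  }
  full <- chain_price(scenario, horizon, strip = NULL,
                      denominator = denominator)
  stripped <- chain_price(scenario, horizon, strip = component,
                          denominator = denominator)
  full - stripped
}

#' Run all proposition checks
#'
#' Evaluates every proposition (1-7 and the case-fatality subcase) against
#' a scenario. Propositions whose preconditions are not met (more than one
#' endpoint for proposition 1; missing subcase fields) are reported as not
#' applicable rather than raising. Reports are ordered with applicable
#' price-invariant propositions first (lowest number first), then
#' applicable partial shortcuts, then the rest.
#'
#' @inheritParams check_proposition
#' @return A list of `vbp_condition_report`s (class
#'   `vbp_condition_reports`); `tidy()` flattens it to a tibble.
#' @export
applicable_propositions <- function(scenario, tolerance = 1e-9) {
  ids <- c(as.character(1:7), "subcase")
  reports <- purrr::map(ids, function(id) {
    tryCatch(
      check_proposition(scenario, id, tolerance),
      vbp_proposition_error = function(e) {
        structure(
          list(
            proposition = id,
            conditions = cond_row("preconditions met", NA_real_, tolerance,
                                  holds = FALSE),
            applicable = FALSE, cancelled = character(0),
            price_invariant = FALSE, tolerance = tolerance
          ),
          class = "vbp_condition_report"
        )
      }
    )
  })
  rank <- vapply(reports, function(r) {
    if (r$applicable && r$price_invariant) 0 else if (r$applicable) 1 else 2
  }, numeric(1))
  out <- reports[order(rank, seq_along(reports))]
  class(out) <- "vbp_condition_reports"
  out
}

#' @export
print.vbp_condition_reports <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Check the case-fatality subcase
#'
#' Convenience wrapper for `check_proposition(scenario, "subcase")`: the
#' setting where treatment reduces the probability of dying once an event
#' has occurred (a `delta_fatality` per endpoint with its own survival cost
#' per averted death). Errors when the subcase fields are absent.
#'
#' @inheritParams check_proposition
#' @return A `vbp_condition_report`.
#' @export
check_subcase <- function(scenario, tolerance = 1e-9) {
  check_proposition(scenario, "subcase", tolerance)
}
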