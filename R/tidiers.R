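#' Tidy an ICER decomposition
#'
#' @param x A `vbp_icer` from [compute_icer()].
#' @param ... Unused.
#' @return One row per additive term (`drug`, `savings`, `survival`) with
#'   its value per weighted-effect unit.
#' @export
tidy.vbp_icer <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    horizon = x$horizon,
    term = c("drug", "savings", "survival"),
    value = c(x$term_drug, x$term_savings, x$term_survival)
  )
}

#' @rdname tidy.vbp_icer
#' @return `glance()`: a one-row summary (total ICER, weighted effect,
#'   downstream cost, price evaluated at).
#' @export
glance.vbp_icer <- function(x, ...) {
  tibble(
    comparison = x$comparison, horizon = x$horizon, price = x$price,
    weighted_effect = x$weighted_effect,
    downstream_cost = x$downstream_cost, icer = x$total
  )
}

#' Tidy a price-invariance result
#'
#' @param x A `vbp_price_result` from [price_invariance_check()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.vbp_price_result <- function(x, ...) {
  tibble(
    price_trial = x$price_trial, price_extended = x$price_extended,
    delta_price = x$delta_price, invariant = x$invariant,
    tolerance = x$tolerance
  )
}

#' @rdname tidy.vbp_price_result
#' @export
glance.vbp_price_result <- tidy.vbp_price_result

#' Tidy proposition condition reports
#'
#' @param x A `vbp_condition_report` ([check_proposition()]) or a
#'   `vbp_condition_reports` list ([applicable_propositions()]).
#' @param ... Unused.
#' @return For a single report, one row per condition; for a report list,
#'   one summary row per proposition.
#' @export
tidy.vbp_condition_report <- function(x, ...) {
  mutate(x$conditions, proposition = x$proposition, .before = 1)
}

#' @rdname tidy.vbp_condition_report
#' @export
glance.vbp_condition_report <- function(x, ...) {
  tibble(
    proposition = x$proposition,
    applicable = x$applicable,
    cancelled = paste(x$cancelled, collapse = "+"),
    price_invariant = x$price_invariant,
    n_conditions = nrow(x$conditions),
    n_failed = sum(!x$conditions$holds)
  )
}

#' @rdname tidy.vbp_condition_report
#' @export
tidy.vbp_condition_reports <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x, glance))
}

#' Tidy a shortcut decision
#'
#' @param x A `vbp_shortcut` from [run_shortcut()].
#' @param ... Unused.
#' @return `tidy()`: the per-proposition summary table; `glance()`: a
#'   one-row decision summary.
#' @export
tidy.vbp_shortcut <- function(x, ...) {
  tidy(x$reports)
}

#' @rdname tidy.vbp_shortcut
#' @export
glance.vbp_shortcut <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    price = x$price %||% NA_real_,
    price_trial = x$price_trial,
    omitted = paste(x$omitted_components, collapse = "+"),
    delta_price = if (!is.null(x$invariance))
      x$invariance$delta_price else NA_real_
  )
}
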