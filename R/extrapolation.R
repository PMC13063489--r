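#' Post-trial scaling factors
#'
#' Multiplicative constants scaling the aggregate post-trial block relative
#' to the trial block: `k_inc` on incidence, `k_rrr` on the relative risk
#' reduction, `k_alpha` on case fatality, `k_cost` on event unit costs, and
#' `k_surv` on survival costs (with an optional separate multiplier for the
#' case-fatality survival cost, used to probe non-proportional expenditure
#' growth). `periods` is the number of post-trial periods the block covers.
#' The factors multiply block sums, not period-by-period recursions.
#'
#' @param k_inc,k_rrr,k_alpha,k_cost,k_surv Positive multipliers (default 1).
#' @param periods Number of post-trial periods (> 0 for a non-empty block).
#' @param k_surv_fatality Optional separate multiplier for
#'   `survival_cost_fatality`; defaults to `k_surv`.
#' @return An object of class `vbp_factors`.
#' @export
extrapolation_factors <- function(k_inc = 1, k_rrr = 1, k_alpha = 1,
                                  k_cost = 1, k_surv = 1, periods = 1,
                                  k_surv_fatality = NULL) {
  ks <- c(k_inc = k_inc, k_rrr = k_rrr, k_alpha = k_alpha,
          k_cost = k_cost, k_surv = k_surv)
  if (any(ks <= 0)) {
    abort("All scaling factors must be > 0.",
          class = "vbp_extrapolation_error")
  }
  if (periods < 0) {
    abort("`periods` must be >= 0.", class = "vbp_extrapolation_error")
  }
  structure(
    list(k_inc = k_inc, k_rrr = k_rrr, k_alpha = k_alpha, k_cost = k_cost,
         k_surv = k_surv, k_surv_fatality = k_surv_fatality,
         periods = periods),
    class = "vbp_factors"
  )
}

#' Extend a scenario beyond the trial period
#'
#' Attaches an event-based post-trial block built from scaling factors: the
#' post-trial avoided events of endpoint i are
#' `k_inc * k_rrr * Inc_i * RRR_i * periods`, post-trial fatality is
#' `k_alpha * alpha_i` (an error if that exceeds 1), post-trial event costs
#' are `k_cost * C_CE_i`, and survival costs scale by `k_surv`. Both
#' comparisons receive the same factors unless `factors_b_vs_a` is supplied
#' (the asymmetric override used in violation experiments such as
#' differential effect waning).
#'
#' @inheritParams weighted_effect
#' @param factors An [extrapolation_factors()] object.
#' @param factors_b_vs_a Optional distinct factors for the B-vs-A arm.
#' @return The scenario with factors attached; extended-horizon summaries
#'   then combine the trial and post-trial blocks.
#' @export
extend_scenario <- function(scenario, factors, factors_b_vs_a = NULL) {
  stopifnot(inherits(factors, "vbp_factors"))
  scenario$post_trial <- NULL
  if (is.null(factors_b_vs_a)) {
    scenario$factors <- factors
  } else {
    stopifnot(inherits(factors_b_vs_a, "vbp_factors"))
    scenario$factors <- list(d_vs_b = factors, b_vs_a = factors_b_vs_a)
  }
  # fail fast if k_alpha breaches the fatality bound
  for (cmp in c("d_vs_b", "b_vs_a")) post_block(scenario, cmp)
  scenario
}

#' Price invariance under extrapolation
#'
#' Solves the value-based price at the trial and extended horizons and
#' reports whether the change stays within a tolerance expressed as a
#' fraction of the trial price.
#'
#' @inheritParams weighted_effect
#' @param factors Optional [extrapolation_factors()]; when omitted the
#'   scenario must already carry factors or a stipulated post-trial block.
#' @param tolerance Fraction of the trial price (default 0.05, i.e. 5%).
#' @return An object of class `vbp_price_result` with fields `price_trial`,
#'   `price_extended`, `delta_price`, `invariant`, `tolerance`.
#' @examples
#' price_invariance_check(worked_example_scenario())   # delta 0, invariant
#' @export
price_invariance_check <- function(scenario, factors = NULL,
                                   tolerance = 0.05) {
  if (!is.null(factors)) scenario <- extend_scenario(scenario, factors)
  if (is.null(scenario$factors) && is.null(scenario$post_trial)) {
    abort("No post-trial block: supply `factors` or a stipulated block.",
          class = "vbp_extrapolation_error")
  }
  p_trial <- solve_vbp_price(scenario, "trial")
  p_ext <- solve_vbp_price(scenario, "extended")
  delta <- p_ext - p_trial
  structure(
    list(
      price_trial = p_trial,
      price_extended = p_ext,
      delta_price = delta,
      invariant = abs(delta) <= tolerance * abs(p_trial),
      tolerance = tolerance
    ),
    class = "vbp_price_result"
  )
}

#' @export
print.vbp_price_result <- function(x, ...) {
  cat("<vbp_price_result>\n")
  cat(sprintf("  trial price:     %12.4f\n", x$price_trial))
  cat(sprintf("  extended price:  %12.4f\n", x$price_extended))
  cat(sprintf("  delta:           %12.4g  (tolerance %.3g x trial price)\n",
              x$delta_price, x$tolerance))
  cat("  invariant:       ", x$invariant, "\n")
  invisible(x)
}

# Extended-horizon price as a function of one factor's value, all other
# factors held at 1. periods taken from the scenario's factors (or 1).
price_at_k <- function(scenario, factor_name, k, periods = NULL,
                       per_comparison = FALSE) {
  f0 <- scenario$factors
  if (inherits(f0, "vbp_factors")) periods <- periods %||% f0$periods
  periods <- periods %||% 1
  vapply(k, function(ki) {
    args <- list(periods = periods)
    args[[factor_name]] <- ki
    tryCatch({
      fk <- do.call(extrapolation_factors, args)
      sck <- if (per_comparison) {
        extend_scenario(scenario, fk,
                        factors_b_vs_a = extrapolation_factors(periods = periods))
      } else {
        extend_scenario(scenario, fk)
      }
      solve_vbp_price(sck, "extended")
    }, vbp_extrapolation_error = function(e) NA_real_)
  }, numeric(1))
}

#' Admissible deviation range for a scaling factor
#'
#' The maximal interval of `k` around 1 over which the extended-horizon
#' price stays within a tolerance of its value at `k = 1`:
#' `|delta_p(k) - delta_p(1)| <= tolerance * |delta_p(1)|`. The swept
#' factor varies while all other factors are held at 1. Each side is found
#' by bracket expansion (doubling/halving, limited to `k` in \[1e-3, 1e3\])
#' followed by bracketed root finding to 1e-6; a side where the bound is
#' never exceeded is reported as open (unbounded).
#'
#' @inheritParams weighted_effect
#' @param factor_name One of `"k_inc"`, `"k_rrr"`, `"k_alpha"`, `"k_cost"`,
#'   `"k_surv"`.
#' @param tolerance Fraction of the baseline price (default 0.05).
#' @param periods Post-trial periods; defaults to the scenario's factors.
#' @param per_comparison If `TRUE` the swept factor applies to the D-vs-B
#'   arm only (B-vs-A held at 1), probing differential deviations.
#' @return A tibble with columns `factor`, `lower`, `upper`, `lower_open`,
#'   `upper_open`, `tolerance`, `price_at_1`.
#' @export
admissible_k_range <- function(scenario, factor_name, tolerance = 0.05,
                               periods = NULL, per_comparison = FALSE) {
  factor_name <- match.arg(factor_name,
                           c("k_inc", "k_rrr", "k_alpha", "k_cost", "k_surv"))
  p1 <- price_at_k(scenario, factor_name, 1, periods, per_comparison)
  if (!is.finite(p1) || p1 == 0) {
    abort("Baseline price delta_p(1) is zero; relative tolerance undefined.",
          class = "vbp_extrapolation_error")
  }
  bound <- tolerance * abs(p1)
  excess <- function(k) {
    p <- price_at_k(scenario, factor_name, k, periods, per_comparison)
    if (!is.finite(p)) return(Inf)  # infeasible factor value (e.g. fatality > 1)
    abs(p - p1) - bound
  }
  # bisection between a k inside the band (excess <= 0) and one outside
  # (excess > 0, or infeasible, treated as outside); 1e-6 resolution in k
  bisect <- function(inside, outside, tol = 1e-6) {
    while (abs(outside - inside) > tol) {
      mid <- (inside + outside) / 2
      if (excess(mid) <= 0) inside <- mid else outside <- mid
    }
    (inside + outside) / 2
  }
  side <- function(direction) {
    k <- 1
    repeat {
      k_next <- if (direction > 0) k * 2 else k / 2
      if (k_next > 1e3 || k_next < 1e-3) {
        return(list(k = if (direction > 0) Inf else 0, open = TRUE))
      }
      if (excess(k_next) > 0) {
        return(list(k = bisect(k, k_next), open = FALSE))
      }
      k <- k_next
    }
  }
  lo <- side(-1)
  hi <- side(+1)
  tibble(
    factor = factor_name,
    lower = lo$k, upper = hi$k,
    lower_open = lo$open, upper_open = hi$open,
    tolerance = tolerance, price_at_1 = p1
  )
}

#' Local price sensitivity to a scaling factor
#'
#' Central finite-difference derivative of the extended-horizon price with
#' respect to one factor at `k = 1` (step 1e-6), all other factors at 1.
#'
#' @inheritParams admissible_k_range
#' @param step Finite-difference half-step (default 1e-6).
#' @return `d(delta_p)/dk` at `k = 1`, money per unit k.
#' @export
linearized_sensitivity <- function(scenario, factor_name, periods = NULL,
                                   per_comparison = FALSE, step = 1e-6) {
  factor_name <- match.arg(factor_name,
                           c("k_inc", "k_rrr", "k_alpha", "k_cost", "k_surv"))
  p <- price_at_k(scenario, factor_name, c(1 - step, 1 + step), periods,
                  per_comparison)
  (p[2] - p[1]) / (2 * step)
}

#' Sensitivity table across all scaling factors
#'
#' Derivatives and admissible ranges for every factor, suitable for a
#' tornado-style display via [autoplot()].
#'
#' @inheritParams admissible_k_range
#' @param factors Character vector of factor names to sweep.
#' @return A tibble of class `vbp_sensitivity` with one row per factor.
#' @export
sensitivity_table <- function(scenario, tolerance = 0.05, periods = NULL,
                              per_comparison = FALSE,
                              factors = c("k_inc", "k_rrr", "k_alpha",
                                          "k_cost")) {
  rows <- purrr::map(factors, function(f) {
    rng <- admissible_k_range(scenario, f, tolerance, periods,
                              per_comparison)
    rng$derivative <- linearized_sensitivity(scenario, f, periods,
                                             per_comparison)
    rng
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vbp_sensitivity", class(out))
  out
}
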