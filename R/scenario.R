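#' Define a clinical endpoint
#'
#' An endpoint is one clinical event (CE) type affected by treatment: a
#' hospitalization, fracture, myocardial infarction, and so on. Each endpoint
#' carries a severity weight used to aggregate heterogeneous events into a
#' composite effect measure, a baseline incidence, a case-fatality
#' probability, and the two downstream unit costs: the (signed) cost per
#' non-fatal event and the survival (life-extension) cost per avoided death.
#'
#' @param id Short label identifying the endpoint.
#' @param weight Severity weight `w_i` (> 0, dimensionless). Weighted avoided
#'   events `sum(delta_ce * weight)` form the effect denominator of the ICER.
#' @param incidence Baseline incidence `Inc_i`, events per person per period
#'   (>= 0). May be `NA` when avoided events are supplied directly on the
#'   comparison.
#' @param fatality Case-fatality probability `alpha_i` in \[0, 1\]: the
#'   probability that an event of this type is fatal.
#' @param event_cost Unit cost `C_CE,i` per non-fatal event, SIGNED: negative
#'   when avoiding the event saves money (the usual case for cost offsets).
#' @param survival_cost Survival cost `C_s,i` per avoided death: health-care
#'   cost incurred during the life-years gained by averting a fatal event
#'   (>= 0 by convention).
#' @param survival_cost_fatality Optional cost `C_s(alpha),i` per death
#'   averted through reduced case-fatality (used only by the case-fatality
#'   subcase; `NA` otherwise).
#'
#' @return A one-row tibble; bind rows of these to build an endpoint table.
#' @examples
#' vbp_endpoint("hosp", weight = 0.2, fatality = 0, event_cost = -5000)
#' @export
vbp_endpoint <- function(id, weight, incidence = NA_real_, fatality = 0,
                         event_cost = 0, survival_cost = 0,
                         survival_cost_fatality = NA_real_) {
  out <- tibble(
    id = as.character(id),
    weight = as.numeric(weight),
    incidence = as.numeric(incidence),
    fatality = as.numeric(fatality),
    event_cost = as_money(event_cost, "event_cost"),
    survival_cost = as_money(survival_cost, "survival_cost"),
    survival_cost_fatality = as_money(survival_cost_fatality,
                                      "survival_cost_fatality")
  )
  validate_endpoints(out)
  out
}

validate_endpoints <- function(ep) {
  if (!is.data.frame(ep) || nrow(ep) < 1L) {
    abort("At least one endpoint is required.", class = "vbp_scenario_error")
  }
  required <- c("id", "weight", "fatality", "event_cost", "survival_cost")
  missing <- setdiff(required, names(ep))
  if (length(missing)) {
    abort(paste0("Endpoint table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vbp_scenario_error")
  }
  if (!"incidence" %in% names(ep)) ep$incidence <- NA_real_
  if (!"survival_cost_fatality" %in% names(ep)) {
    ep$survival_cost_fatality <- NA_real_
  }
  if (anyDuplicated(ep$id)) {
    abort("Endpoint ids must be unique.", class = "vbp_scenario_error")
  }
  if (any(ep$weight <= 0)) {
    abort("Endpoint weights must be > 0.", class = "vbp_scenario_error")
  }
  if (any(ep$fatality < 0 | ep$fatality > 1)) {
    abort("Case-fatality probabilities must lie in [0, 1].",
          class = "vbp_scenario_error")
  }
  if (any(!is.na(ep$incidence) & ep$incidence < 0)) {
    abort("Incidence must be >= 0.", class = "vbp_scenario_error")
  }
  invisible(as_tibble(ep))
}

#' Define a treatment comparison
#'
#' One treatment contrast: the new drug D versus its comparator B
#' (`"d_vs_b"`), or B versus the reference intervention A (`"b_vs_a"`).
#' Effects enter either as per-endpoint relative risk reductions (RRR), from
#' which avoided events are `incidence * rrr * trial_duration`, or directly
#' as per-endpoint avoided events `delta_ce` (which take precedence).
#'
#' @param label `"d_vs_b"` or `"b_vs_a"`.
#' @param rrr Relative risk reduction, a scalar (common across endpoints) or
#'   one value per endpoint.
#' @param delta_ce Optional avoided events per endpoint over the trial
#'   period; overrides `incidence * rrr * duration` when supplied.
#' @param drug_price_delta Incremental acquisition price of the contrast
#'   (money). For `b_vs_a` a non-`NA` value marks B as already priced, which
#'   activates chain-consistent thresholding (see
#'   [effective_threshold()]).
#' @param nonprice_cost_delta Incremental non-price drug-related costs
#'   (monitoring, administration, adverse-event management).
#' @param fatality Optional per-endpoint case-fatality override for this
#'   comparison, used when the underlying trials exhibit different fatality
#'   proportions (e.g. differing concomitant therapy).
#' @param delta_fatality Optional per-endpoint reduction in case-fatality
#'   probability achieved by the more effective arm (case-fatality subcase
#'   only).
#'
#' @return An object of class `vbp_comparison`.
#' @export
vbp_comparison <- function(label = c("d_vs_b", "b_vs_a"), rrr = NULL,
                           delta_ce = NULL, drug_price_delta = NA_real_,
                           nonprice_cost_delta = 0, fatality = NULL,
                           delta_fatality = NULL) {
  label <- match.arg(label)
  structure(
    list(
      label = label,
      rrr = if (!is.null(rrr)) as.numeric(rrr),
      delta_ce = if (!is.null(delta_ce)) as.numeric(delta_ce),
      drug_price_delta = as_money(drug_price_delta, "drug_price_delta"),
      nonprice_cost_delta = as_money(nonprice_cost_delta,
                                     "nonprice_cost_delta"),
      fatality = if (!is.null(fatality)) as.numeric(fatality),
      delta_fatality = if (!is.null(delta_fatality)) as.numeric(delta_fatality)
    ),
    class = "vbp_comparison"
  )
}

#' Assemble a pricing scenario
#'
#' Bundles the endpoint table, the two treatment comparisons
#' (D vs B and B vs A), the willingness-to-pay threshold and the horizon
#' settings into the object every other function in the package consumes.
#'
#' @param endpoints Tibble of endpoints (rows from [vbp_endpoint()]).
#' @param d_vs_b,b_vs_a [vbp_comparison()] objects. `b_vs_a` may be omitted
#'   when only the direct comparison is priced against a fixed threshold.
#' @param threshold Willingness-to-pay threshold `lambda`, money per
#'   weighted-effect unit (> 0).
#' @param comparator_price Absolute acquisition price of B (`p_B`); only
#'   needed to report the absolute price `p_D = p_B + delta_p`.
#' @param trial_duration Trial observation window `T` in periods (> 0).
#' @param discount_rate Per-period discount rate (>= 0); the aggregate-block
#'   worked examples use 0.
#' @param effect_unit Free label for the effect unit (e.g. `"weighted
#'   events"`, `"QALYs"`). Labels only; no conversion is performed.
#' @param post_trial Optional named list of stipulated post-trial blocks, one
#'   per comparison label, each `list(effect = , downstream = )` giving the
#'   post-trial weighted effect and downstream cost directly (the
#'   stipulated-block style of the worked example). Event-based post-trial
#'   blocks are attached with [extend_scenario()] instead.
#' @param factors Optional [extrapolation_factors()] applied to both
#'   comparisons (or a named list with elements `d_vs_b` and `b_vs_a` for
#'   deliberately asymmetric scaling experiments).
#'
#' @return An object of class `vbp_scenario`.
#' @examples
#' sc <- vbp_scenario(
#'   endpoints = rbind(
#'     vbp_endpoint("nonfatal", weight = 0.2, event_cost = -5000),
#'     vbp_endpoint("fatal", weight = 1, fatality = 1, survival_cost = 30000)
#'   ),
#'   d_vs_b = vbp_comparison("d_vs_b", delta_ce = c(0.10, 0.02),
#'                           nonprice_cost_delta = 1000),
#'   threshold = 50000
#' )
#' solve_vbp_price(sc)
#' @export
vbp_scenario <- function(endpoints, d_vs_b, b_vs_a = NULL, threshold,
                         comparator_price = NA_real_, trial_duration = 1,
                         discount_rate = 0, effect_unit = "weighted events",
                         post_trial = NULL, factors = NULL) {
  endpoints <- validate_endpoints(as_tibble(endpoints))
  threshold <- as_money(threshold, "threshold")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.",
          class = "vbp_scenario_error")
  }
  if (trial_duration <= 0) {
    abort("`trial_duration` must be > 0.", class = "vbp_scenario_error")
  }
  if (discount_rate < 0) {
    abort("`discount_rate` must be >= 0.", class = "vbp_scenario_error")
  }
  if (is.null(b_vs_a)) b_vs_a <- vbp_comparison("b_vs_a")
  sc <- structure(
    list(
      endpoints = endpoints,
      d_vs_b = d_vs_b,
      b_vs_a = b_vs_a,
      threshold = threshold,
      comparator_price = as_money(comparator_price, "comparator_price"),
      trial_duration = as.numeric(trial_duration),
      discount_rate = as.numeric(discount_rate),
      effect_unit = as.character(effect_unit),
      post_trial = post_trial,
      factors = factors
    ),
    class = "vbp_scenario"
  )
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  m <- nrow(sc$endpoints)
  for (which in c("d_vs_b", "b_vs_a")) {
    cmp <- sc[[which]]
    if (!inherits(cmp, "vbp_comparison") || cmp$label != which) {
      abort(paste0("`", which, "` must be a vbp_comparison labelled '",
                   which, "'."), class = "vbp_scenario_error")
    }
    for (fld in c("rrr", "delta_ce", "fatality", "delta_fatality")) {
      v <- cmp[[fld]]
      if (!is.null(v) && !length(v) %in% c(1L, m)) {
        abort(paste0("`", which, "$", fld, "` must have length 1 or ", m,
                     " (one per endpoint)."), class = "vbp_scenario_error")
      }
    }
    if (!is.null(cmp$fatality) &&
        any(cmp$fatality < 0 | cmp$fatality > 1)) {
      abort("Comparison fatality override must lie in [0, 1].",
            class = "vbp_scenario_error")
    }
    if (!is.null(cmp$delta_fatality)) {
      base <- cmp$fatality %||% sc$endpoints$fatality
      post <- rep_len(base, m) - rep_len(cmp$delta_fatality, m)
      if (any(post < 0 | post > 1)) {
        abort("`delta_fatality` pushes a post-treatment fatality outside [0, 1].",
              class = "vbp_scenario_error")
      }
    }
    if (!is.null(cmp$delta_ce) && !is.null(cmp$rrr) &&
        any(!is.na(sc$endpoints$incidence))) {
      warn(paste0("Both `delta_ce` and (incidence, rrr) supplied for ",
                  which, "; `delta_ce` takes precedence."),
           class = "vbp_consistency_warning")
    }
    if (is.null(cmp$delta_ce) && is.null(cmp$rrr) && which == "d_vs_b") {
      abort("d_vs_b needs either `delta_ce` or `rrr`.",
            class = "vbp_scenario_error")
    }
  }
  if (!is.null(sc$post_trial)) {
    bad <- setdiff(names(sc$post_trial), c("d_vs_b", "b_vs_a"))
    if (length(bad)) {
      abort("`post_trial` entries must be named d_vs_b / b_vs_a.",
            class = "vbp_scenario_error")
    }
  }
  sc
}

#' @export
print.vbp_scenario <- function(x, ...) {
  cat("<vbp_scenario>\n")
  cat("  endpoints:        ", nrow(x$endpoints), " (",
      paste(x$endpoints$id, collapse = ", "), ")\n", sep = "")
  cat("  threshold:        ", format(x$threshold, big.mark = ""),
      " per ", x$effect_unit, "\n", sep = "")
  cat("  trial duration:   ", x$trial_duration, " period(s)\n", sep = "")
  cat("  B-vs-A priced:    ",
      !is.na(x$b_vs_a$drug_price_delta), "\n", sep = "")
  if (!is.null(x$post_trial)) cat("  stipulated post-trial block present\n")
  if (!is.null(x$factors))    cat("  extrapolation factors attached\n")
  invisible(x)
}

# ---- internal accessors -----------------------------------------------------

get_comparison <- function(scenario, comparison) {
  if (inherits(comparison, "vbp_comparison")) return(comparison)
  comparison <- match.arg(comparison, c("d_vs_b", "b_vs_a"))
  scenario[[comparison]]
}

# Per-endpoint event block for one comparison over the trial period.
# Columns: id, delta_ce, fatality, weight, event_cost, survival_cost,
# delta_fatality, survival_cost_fatality.
trial_block <- function(scenario, comparison) {
  cmp <- get_comparison(scenario, comparison)
  ep <- scenario$endpoints
  m <- nrow(ep)
  if (!is.null(cmp$delta_ce)) {
    dce <- rep_len(cmp$delta_ce, m)
  } else {
    if (is.null(cmp$rrr)) {
      abort(paste0("Comparison '", cmp$label,
                   "' has neither `delta_ce` nor `rrr`."),
            class = "vbp_scenario_error")
    }
    if (any(is.na(ep$incidence))) {
      abort("RRR-based avoided events need non-missing incidence.",
            class = "vbp_scenario_error")
    }
    dce <- ep$incidence * rep_len(cmp$rrr, m) * scenario$trial_duration
  }
  tibble(
    id = ep$id,
    delta_ce = dce,
    fatality = rep_len(cmp$fatality %||% ep$fatality, m),
    weight = ep$weight,
    event_cost = ep$event_cost,
    survival_cost = ep$survival_cost,
    delta_fatality = rep_len(cmp$delta_fatality %||% 0, m),
    survival_cost_fatality = ifelse(is.na(ep$survival_cost_fatality), 0,
                                    ep$survival_cost_fatality)
  )
}

factors_for <- function(scenario, label) {
  f <- scenario$factors
  if (is.null(f)) return(NULL)
  if (inherits(f, "vbp_factors")) return(f)
  f[[label]]
}

# Event-based or stipulated post-trial block. Returns a list with elements
# effect, savings, survival, downstream, and (when event-based) the scaled
# per-endpoint table.
post_block <- function(scenario, comparison) {
  cmp <- get_comparison(scenario, comparison)
  stip <- scenario$post_trial[[cmp$label]]
  if (!is.null(stip)) {
    eff <- as.numeric(stip$effect %||% 0)
    down <- as.numeric(stip$downstream %||% 0)
    return(list(effect = eff, savings = NA_real_, survival = NA_real_,
                downstream = down, events = NULL, stipulated = TRUE))
  }
  f <- factors_for(scenario, cmp$label)
  if (is.null(f)) return(NULL)
  tb <- trial_block(scenario, cmp)
  # The k-factors scale the aggregate post-trial block: avoided events pick
  # up k_inc * k_rrr (per period, times the number of post-trial periods),
  # fatality picks up k_alpha, event costs k_cost, survival costs k_surv.
  scale_ev <- f$k_inc * f$k_rrr * f$periods / scenario$trial_duration
  fat <- f$k_alpha * tb$fatality
  if (any(fat > 1 + 1e-12)) {
    abort("`k_alpha` pushes a post-trial case fatality above 1.",
          class = "vbp_extrapolation_error")
  }
  post <- tb
  post$delta_ce <- tb$delta_ce * scale_ev
  post$fatality <- pmin(fat, 1)
  post$event_cost <- f$k_cost * tb$event_cost
  post$survival_cost <- f$k_surv * tb$survival_cost
  post$delta_fatality <- tb$delta_fatality * scale_ev
  post$survival_cost_fatality <-
    (f$k_surv_fatality %||% f$k_surv) * tb$survival_cost_fatality
  c(block_summary(post), list(events = post, stipulated = FALSE))
}

block_summary <- function(tb) {
  out <- list(
    effect = sum(tb$delta_ce * tb$weight),
    savings = sum(tb$delta_ce * (1 - tb$fatality) * tb$event_cost),
    survival = sum(tb$delta_ce * tb$fatality * tb$survival_cost) +
      sum(tb$delta_fatality * tb$survival_cost_fatality),
    deaths = sum(tb$delta_ce * tb$fatality) + sum(tb$delta_fatality)
  )
  out$downstream <- out$savings + out$survival
  out
}

# Aggregate a comparison over a horizon. strip: optionally zero out a
# downstream component ("savings" or "survival_costs") before summing --
# the primitive behind verify_cancellation().
horizon_summary <- function(scenario, comparison,
                            horizon = c("trial", "extended"),
                            strip = NULL) {
  horizon <- match.arg(horizon)
  tb <- trial_block(scenario, comparison)
  if (!is.null(strip)) tb <- strip_component(tb, strip)
  out <- block_summary(tb)
  if (horizon == "extended") {
    pb <- post_block(scenario, comparison)
    if (is.null(pb)) {
      abort("Extended horizon requested but the scenario has no post-trial block or factors.",
            class = "vbp_extrapolation_error")
    }
    if (!is.null(pb$events)) {
      ev <- pb$events
      if (!is.null(strip)) ev <- strip_component(ev, strip)
      pb <- c(block_summary(ev), list(events = ev))
    } else if (!is.null(strip)) {
      abort("Cannot strip a component from a stipulated (aggregate) post-trial block.",
            class = "vbp_extrapolation_error")
    }
    out$effect <- out$effect + pb$effect
    out$savings <- out$savings + pb$savings
    out$survival <- out$survival + pb$survival
    out$deaths <- out$deaths + (pb$deaths %||% NA_real_)
    out$downstream <- out$downstream + pb$downstream
  }
  out
}

strip_component <- function(tb, component) {
  component <- match.arg(component, c("savings", "survival_costs"))
  if (component == "savings") {
    tb$event_cost <- 0
  } else {
    tb$survival_cost <- 0
    tb$survival_cost_fatality <- 0
  }
  tb
}
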