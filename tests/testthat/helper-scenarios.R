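# Scenario builders shared across test files. All randomness is drawn under
# an explicit seed so every test is reproducible.

# Unconstrained random scenario (no proposition structure enforced).
random_scenario <- function(seed, m = NULL, priced_b = FALSE) {
  set.seed(seed)
  if (is.null(m)) m <- sample(1:4, 1)
  endpoints <- tibble::tibble(
    id = paste0("ce", seq_len(m)),
    weight = runif(m, 0.1, 1),
    incidence = runif(m, 0.01, 0.5),
    fatality = runif(m, 0.05, 0.9),
    event_cost = runif(m, -20000, 0),
    survival_cost = runif(m, 0, 50000),
    survival_cost_fatality = NA_real_
  )
  sc <- vbp_scenario(
    endpoints = endpoints,
    d_vs_b = vbp_comparison("d_vs_b", rrr = runif(m, 0.05, 0.5),
                            nonprice_cost_delta = runif(1, 0, 2000)),
    b_vs_a = vbp_comparison("b_vs_a", rrr = runif(m, 0.05, 0.5),
                            nonprice_cost_delta = runif(1, 0, 2000)),
    threshold = runif(1, 20000, 100000),
    trial_duration = 1
  )
  if (priced_b) {
    sc$b_vs_a$drug_price_delta <-
      sc$threshold * weighted_effect(sc, "b_vs_a") -
      sc$b_vs_a$nonprice_cost_delta - downstream_cost(sc, "b_vs_a")
  }
  sc
}

# Break exactly one of a proposition's required conditions by a relative
# 10%, asymmetrically (on one comparison / one component), since the
# cancellations are between-comparison equalities.
perturb_condition <- function(sc, id) {
  id <- as.character(id)
  if (id %in% c("1", "4", "7")) {
    sc$d_vs_b$fatality <- pmin(sc$endpoints$fatality * 1.1, 1)
  } else if (id %in% c("2", "5")) {
    r <- rep_len(sc$d_vs_b$rrr, nrow(sc$endpoints))
    r[1] <- r[1] * 1.1
    sc$d_vs_b$rrr <- r
  } else if (id == "3") {
    f <- sc$factors
    fd <- f
    fd$k_alpha <- f$k_alpha * 0.9
    sc$factors <- list(d_vs_b = fd, b_vs_a = f)
  } else if (id == "6") {
    f <- sc$factors
    fd <- f
    fd$k_cost <- f$k_cost * 1.1
    sc$factors <- list(d_vs_b = fd, b_vs_a = f)
  } else if (id == "subcase") {
    sc$endpoints$survival_cost_fatality <-
      sc$endpoints$survival_cost_fatality * 1.1
  }
  sc
}

cancelled_component <- function(id) {
  if (as.character(id) %in% c("5", "6", "7")) "savings" else "survival_costs"
}

# Relative price residual of the cancellation claim for one generated
# scenario; for the extrapolation propositions (3, 6) it is the relative
# two-horizon price change instead.
relative_residual <- function(sc, id) {
  id <- as.character(id)
  if (id %in% c("3", "6")) {
    pic <- price_invariance_check(sc)
    pic$delta_price / abs(pic$price_trial)
  } else {
    verify_cancellation(sc, cancelled_component(id)) /
      abs(solve_vbp_price(sc))
  }
}
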