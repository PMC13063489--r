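#' Generate a scenario satisfying a proposition's conditions
#'
#' Seeded synthetic-scenario generator: draws endpoint parameters from
#' documented ranges and then enforces the requested proposition's equality
#' or constant-ratio constraints exactly, so the generated scenario is a
#' positive instance for [check_proposition()] and a zero-residual instance
#' for [verify_cancellation()]. The B-vs-A comparison is priced at value
#' (its ICER equals the threshold), activating the D -> B -> A chain.
#'
#' Draw ranges: incidence 0.01-0.5 per period, weights 0.1-1, case fatality
#' 0-0.9, event cost -20,000-0, survival cost 0-50,000, RRR 0.05-0.5; all
#' overridable via `ranges`.
#'
#' @param proposition Proposition id: 1-7 or `"subcase"`.
#' @param seed Integer seed; the same seed yields an identical scenario.
#'   The caller's RNG state is preserved.
#' @param m Number of endpoints (forced to 1 for proposition 1).
#' @param threshold Willingness-to-pay threshold (default 50,000).
#' @param ranges Optional named list overriding individual draw ranges,
#'   each a length-2 numeric `c(min, max)`; names among `incidence`,
#'   `weight`, `fatality`, `event_cost`, `survival_cost`, `rrr`, `nonprice`,
#'   `k`.
#' @return A [vbp_scenario()] whose `d_vs_b` price is left unset (to be
#'   solved) and whose `b_vs_a` comparison is value-priced.
#' @examples
#' sc <- generate_scenario(2, seed = 1)
#' check_proposition(sc, 2)$applicable
#' verify_cancellation(sc, "survival_costs")
#' @export
generate_scenario <- function(proposition, seed, m = 3L, threshold = 50000,
                              ranges = list()) {
  id <- as.character(proposition)
  if (!id %in% c(as.character(1:7), "subcase")) {
    abort(paste0("Unknown proposition id: ", id),
          class = "vbp_proposition_error")
  }
  if (id == "1") m <- 1L
  if (m < 1L) abort("`m` must be >= 1.", class = "vbp_scenario_error")

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(as.integer(seed))

  rg <- utils::modifyList(list(
    incidence = c(0.01, 0.5), weight = c(0.1, 1), fatality = c(0, 0.9),
    event_cost = c(-20000, 0), survival_cost = c(0, 50000),
    rrr = c(0.05, 0.5), nonprice = c(0, 2000), k = c(0.5, 2)
  ), ranges)
  draw <- function(n, r) runif(n, r[1], r[2])

  inc <- draw(m, rg$incidence)
  w <- draw(m, rg$weight)
  alpha <- draw(m, c(max(rg$fatality[1], 0.05), rg$fatality[2]))
  ec <- draw(m, rg$event_cost)
  sc_ <- draw(m, c(max(rg$survival_cost[1], 1000), rg$survival_cost[2]))
  sca <- rep(NA_real_, m)
  rrr_d <- draw(m, rg$rrr)
  rrr_b <- draw(m, rg$rrr)
  dfat_d <- dfat_b <- NULL
  factors <- NULL

  scalar_rrr <- function() {
    rrr_d <<- rep(runif(1, rg$rrr[1], rg$rrr[2]), m)
    rrr_b <<- rep(runif(1, rg$rrr[1], rg$rrr[2]), m)
  }
  common_alpha <- function() alpha <<- rep(runif(1, 0.05, rg$fatality[2]), m)
  common_factors <- function(with_cost = FALSE, with_surv = FALSE) {
    k_alpha_max <- min(rg$k[2], 0.99 / max(alpha))
    extrapolation_factors(
      k_inc = runif(1, rg$k[1], rg$k[2]),
      k_rrr = runif(1, rg$k[1], rg$k[2]),
      k_alpha = if (with_surv) 1 else runif(1, rg$k[1], k_alpha_max),
      k_cost = if (with_cost) runif(1, rg$k[1], rg$k[2]) else 1,
      k_surv = if (with_surv) runif(1, 0.8, 1.5) else 1,
      periods = sample(1:5, 1)
    )
  }

  switch(id,
    "1" = scalar_rrr(),
    "2" = { common_alpha(); ec[] <- 0; scalar_rrr() },
    "3" = { ec[] <- 0; scalar_rrr(); factors <- common_factors() },
    "4" = {
      common_alpha(); w[] <- runif(1, rg$weight[1], rg$weight[2])
      sc_[] <- runif(1, 5000, rg$survival_cost[2]); ec[] <- 0
    },
    "5" = { common_alpha(); sc_[] <- 0; scalar_rrr() },
    "6" = { sc_[] <- 0; scalar_rrr()
            factors <- common_factors(with_cost = TRUE) },
    "7" = {
      common_alpha(); w[] <- runif(1, rg$weight[1], rg$weight[2])
      ec[] <- runif(1, rg$event_cost[1], -1000); sc_[] <- 0
    },
    "subcase" = {
      ec[] <- 0
      c0 <- runif(1, 5000, 40000)
      sc_[] <- c0; sca[] <- c0
      dfat_d <- runif(m, 0.05, 0.4) * alpha
      dfat_b <- runif(m, 0.05, 0.4) * alpha
      factors <- common_factors(with_surv = TRUE)
    }
  )

  endpoints <- tibble(
    id = paste0("ce", seq_len(m)), weight = w, incidence = inc,
    fatality = alpha, event_cost = ec, survival_cost = sc_,
    survival_cost_fatality = sca
  )
  b_vs_a <- vbp_comparison("b_vs_a", rrr = rrr_b,
                           nonprice_cost_delta = draw(1, rg$nonprice),
                           delta_fatality = dfat_b)
  d_vs_b <- vbp_comparison("d_vs_b", rrr = rrr_d,
                           nonprice_cost_delta = draw(1, rg$nonprice),
                           delta_fatality = dfat_d)
  sc <- vbp_scenario(endpoints = endpoints, d_vs_b = d_vs_b,
                     b_vs_a = b_vs_a, threshold = threshold,
                     trial_duration = 1, factors = factors)

  # price B at value: ICER_BvsA over the trial period equals the threshold
  hb <- horizon_summary(sc, "b_vs_a", "trial")
  sc$b_vs_a$drug_price_delta <- threshold * hb$effect -
    sc$b_vs_a$nonprice_cost_delta - hb$downstream
  sc
}
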