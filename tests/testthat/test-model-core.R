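test_that("avoided events combine incidence, risk reduction and duration", {
  sc <- vbp_scenario(
    endpoints = vbp_endpoint("hosp", weight = 1, incidence = 0.15),
    d_vs_b = vbp_comparison("d_vs_b", rrr = 0.15),
    threshold = 50000, trial_duration = 3
  )
  expect_equal(avoided_events(sc)$events_avoided, 0.0675)
  expect_equal(avoided_events(sc, duration = 1)$events_avoided, 0.0225)

  sc0 <- vbp_scenario(
    endpoints = vbp_endpoint("hosp", weight = 1, incidence = 0.2),
    d_vs_b = vbp_comparison("d_vs_b", rrr = 0),
    threshold = 50000
  )
  expect_equal(avoided_events(sc0)$events_avoided, 0)

  sc1 <- vbp_scenario(
    endpoints = vbp_endpoint("hosp", weight = 1, incidence = 0.2),
    d_vs_b = vbp_comparison("d_vs_b", rrr = 0.5),
    threshold = 50000, trial_duration = 1
  )
  expect_equal(avoided_events(sc1)$events_avoided, 0.1)
  expect_error(avoided_events(sc1, endpoint = "nope"),
               class = "vbp_scenario_error")
})

test_that("direct avoided events override the incidence pathway, with a warning", {
  expect_warning(
    sc <- vbp_scenario(
      endpoints = vbp_endpoint("hosp", weight = 1, incidence = 0.2),
      d_vs_b = vbp_comparison("d_vs_b", rrr = 0.5, delta_ce = 0.03),
      threshold = 50000
    ),
    class = "vbp_consistency_warning"
  )
  expect_equal(avoided_events(sc)$events_avoided, 0.03)
})

test_that("weighted effect sums severity-weighted avoided events", {
  sc <- worked_example_scenario()
  expect_equal(weighted_effect(sc), 0.04)
  expect_equal(weighted_effect(sc, horizon = "extended"), 0.06)

  # unit weights reduce to the plain event sum; zero effects give zero
  scu <- vbp_scenario(
    endpoints = rbind(vbp_endpoint("a", weight = 1),
                      vbp_endpoint("b", weight = 1)),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = c(0.07, 0.03)),
    threshold = 50000
  )
  expect_equal(weighted_effect(scu), 0.1)
  scz <- vbp_scenario(
    endpoints = vbp_endpoint("a", weight = 0.5),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = 0),
    threshold = 50000
  )
  expect_equal(weighted_effect(scz), 0)
})

test_that("downstream cost splits non-fatal savings and survival costs", {
  sc <- worked_example_scenario()
  # 0.10 * (1-0) * (-5000) + 0.02 * 1 * 30000 = 100
  expect_equal(downstream_cost(sc), 100)
  expect_equal(downstream_cost(sc, horizon = "extended"), 1100)

  # all-zero costs give zero; the sum is linear in avoided events
  scz <- vbp_scenario(
    endpoints = rbind(vbp_endpoint("a", weight = 1),
                      vbp_endpoint("b", weight = 1)),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = c(0.1, 0.2)),
    threshold = 50000
  )
  expect_equal(downstream_cost(scz), 0)
  sc2 <- worked_example_scenario()
  sc2$d_vs_b$delta_ce <- sc2$d_vs_b$delta_ce * 2
  expect_equal(downstream_cost(sc2), 2 * downstream_cost(sc))
})

test_that("the ICER decomposition reproduces the worked example at both horizons", {
  sc <- worked_example_scenario()
  trial <- compute_icer(sc, price = 900)
  expect_equal(trial$total, 50000)
  expect_equal(trial$weighted_effect, 0.04)
  ext <- compute_icer(sc, price = 900, horizon = "extended")
  expect_equal(ext$total, 50000)

  # with no downstream or non-price costs, price = lambda * effect gives lambda
  scp <- vbp_scenario(
    endpoints = vbp_endpoint("a", weight = 1),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = 0.05),
    threshold = 42000
  )
  expect_equal(compute_icer(scp, price = 42000 * 0.05)$total, 42000)

  scz <- vbp_scenario(
    endpoints = vbp_endpoint("a", weight = 1),
    d_vs_b = vbp_comparison("d_vs_b", delta_ce = 0),
    threshold = 50000
  )
  expect_error(compute_icer(scz, price = 100), class = "vbp_undefined_icer")
})

test_that("ICER breakdown is additive and downstream terms are incidence-scale invariant", {
  for (seed in 1:200) {
    sc <- random_scenario(seed)
    ic <- compute_icer(sc, price = runif(1, 0, 5000))
    expect_equal(ic$total, ic$term_drug + ic$term_savings + ic$term_survival,
                 tolerance = 1e-9)
    # one-expression evaluation of the same ratio
    direct <- (ic$price + sc$d_vs_b$nonprice_cost_delta +
                 downstream_cost(sc)) / weighted_effect(sc)
    expect_equal(ic$total, direct, tolerance = 1e-9)

    # multiplying all incidences by c scales effect and downstream together:
    # savings/survival terms unchanged, drug term divided by c
    c_ <- runif(1, 0.5, 3)
    sc2 <- sc
    sc2$endpoints$incidence <- sc$endpoints$incidence * c_
    ic2 <- compute_icer(sc2, price = ic$price)
    expect_equal(ic2$term_savings, ic$term_savings, tolerance = 1e-9)
    expect_equal(ic2$term_survival, ic$term_survival, tolerance = 1e-9)
    expect_equal(ic2$term_drug, ic$term_drug / c_, tolerance = 1e-9)
  }
})

test_that("discounting follows the end-of-period convention", {
  expect_equal(discount_stream(c(3, 4, 5), rate = 0), 12)
  expect_equal(discount_stream(100, rate = 0.05), 100 / 1.05)
  # 10-period constant stream vs the geometric-series closed form
  r <- 0.035
  expect_equal(discount_stream(rep(200, 10), rate = r),
               200 * (1 - (1 + r)^-10) / r, tolerance = 1e-12)
  expect_error(discount_stream(1:3, rate = -0.01),
               class = "vbp_scenario_error")
})

test_that("survival weighting cancels from the lifetime ICER under constant increments", {
  # constant per-period increments: the ratio equals the per-period ratio
  # for any non-increasing survival curve
  per_period <- (2225 - 225) / 0.04
  expect_equal(per_period, 50000)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    surv <- cumprod(runif(n, 0.7, 1))
    pr <- survival_profile(
      data.frame(period = 1:n, survival = surv, effect = 0.04,
                 savings = 225),
      price = 2225
    )
    expect_equal(lifetime_icer(pr), 50000, tolerance = 1e-12)
  }
  # n = 1 reduces to the plain per-period ratio
  pr1 <- survival_profile(
    data.frame(period = 1, survival = 0.9, effect = 0.04, savings = 225),
    price = 2225, nonprice = 100
  )
  expect_equal(lifetime_icer(pr1), (2225 + 100 - 225) / 0.04)
})

test_that("survival profiles are validated", {
  expect_error(
    survival_profile(data.frame(period = 1:2, survival = c(0.8, 0.9),
                                effect = 1, savings = 0), price = 1),
    class = "vbp_scenario_error"
  )
  pr <- survival_profile(data.frame(period = 1:3, survival = c(1, 1, 0),
                                    effect = 0, savings = 0), price = 1)
  expect_error(lifetime_icer(pr), class = "vbp_undefined_icer")
})
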