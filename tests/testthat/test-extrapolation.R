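test_that("scaling factors are validated and neutral factors duplicate the trial block", {
  expect_error(extrapolation_factors(k_inc = -1),
               class = "vbp_extrapolation_error")
  sc <- generate_scenario(3, seed = 5)
  # k_alpha breaching the fatality bound fails fast
  expect_error(
    extend_scenario(sc, extrapolation_factors(
      k_alpha = 1.5 / max(sc$endpoints$fatality), periods = 1)),
    class = "vbp_extrapolation_error"
  )

  # identity factors over one trial-length block: post-trial == trial
  neutral <- extrapolation_factors(periods = sc$trial_duration)
  scn <- extend_scenario(sc, neutral)
  expect_equal(weighted_effect(scn, horizon = "extended"),
               2 * weighted_effect(scn))
  expect_equal(downstream_cost(scn, horizon = "extended"),
               2 * downstream_cost(scn))
})

test_that("post-trial downstream-to-effect ratios are invariant to k_inc * k_rrr", {
  for (seed in 1:25) {
    sc <- random_scenario(seed, priced_b = TRUE)
    base <- extend_scenario(sc, extrapolation_factors(periods = 2))
    scaled <- extend_scenario(sc, extrapolation_factors(
      k_inc = runif(1, 0.5, 2), k_rrr = runif(1, 0.5, 2), periods = 2))
    for (cmp in c("d_vs_b", "b_vs_a")) {
      pb0 <- vbpricer:::post_block(base, cmp)
      pb1 <- vbpricer:::post_block(scaled, cmp)
      expect_equal(pb1$savings / pb1$effect, pb0$savings / pb0$effect,
                   tolerance = 1e-12)
      expect_equal(pb1$survival / pb1$effect, pb0$survival / pb0$effect,
                   tolerance = 1e-12)
    }
  }
})

test_that("k_cost scales the post-trial savings block exactly", {
  sc <- random_scenario(31, priced_b = TRUE)
  pb1 <- vbpricer:::post_block(
    extend_scenario(sc, extrapolation_factors(periods = 2)), "d_vs_b")
  pb2 <- vbpricer:::post_block(
    extend_scenario(sc, extrapolation_factors(k_cost = 2, periods = 2)),
    "d_vs_b")
  expect_equal(pb2$savings, 2 * pb1$savings, tolerance = 1e-12)
  expect_equal(pb2$survival, pb1$survival, tolerance = 1e-12)
})

test_that("price invariance holds under common factors and fails under asymmetric scaling", {
  sc <- worked_example_scenario()
  pic <- price_invariance_check(sc)
  expect_equal(pic$delta_price, 0, tolerance = 1e-9)
  expect_true(pic$invariant)

  sc3 <- generate_scenario(3, seed = 17)
  pic3 <- price_invariance_check(sc3)
  expect_lt(abs(pic3$delta_price), 1e-9 * abs(pic3$price_trial))

  # raising k_alpha on one comparison only: a higher post-trial survival
  # cost burden for D reduces its implied price
  f <- sc3$factors
  fd <- f; fd$k_alpha <- min(f$k_alpha * 1.2, 0.99 / max(sc3$endpoints$fatality))
  sc3a <- sc3; sc3a$factors <- list(d_vs_b = fd, b_vs_a = f)
  pic3a <- price_invariance_check(sc3a)
  expect_lt(pic3a$delta_price, -1e-6)
})

test_that("the admissible k interval brackets 1, matches a grid oracle, and grows with tolerance", {
  sc <- generate_scenario(3, seed = 23)
  rng <- admissible_k_range(sc, "k_alpha", tolerance = 0.02,
                            per_comparison = TRUE)
  expect_true(rng$lower < 1 && rng$upper > 1)
  expect_false(rng$lower_open || rng$upper_open)

  # brute-force grid scan at step 1e-4
  p1 <- rng$price_at_1
  bound <- rng$tolerance * abs(p1)
  ks <- seq(rng$lower - 0.05, rng$upper + 0.05, by = 1e-4)
  dev <- abs(vbpricer:::price_at_k(sc, "k_alpha", ks,
                                   per_comparison = TRUE) - p1)
  inside <- ks[dev <= bound]
  expect_lt(abs(min(inside) - rng$lower), 2e-4)
  expect_lt(abs(max(inside) - rng$upper), 2e-4)

  wider <- admissible_k_range(sc, "k_alpha", tolerance = 0.05,
                              per_comparison = TRUE)
  expect_lte(wider$lower, rng$lower)
  expect_gte(wider$upper, rng$upper)

  # symmetric factors cancel: no k dependence, interval unbounded
  rng_sym <- admissible_k_range(sc, "k_inc", tolerance = 0.02)
  expect_true(rng_sym$lower_open && rng_sym$upper_open)
})

test_that("local sensitivity matches a first-order prediction and carries the right sign", {
  sc <- generate_scenario(3, seed = 29)
  d <- linearized_sensitivity(sc, "k_alpha", per_comparison = TRUE)
  p1 <- vbpricer:::price_at_k(sc, "k_alpha", 1, per_comparison = TRUE)
  p101 <- vbpricer:::price_at_k(sc, "k_alpha", 1.01, per_comparison = TRUE)
  expect_equal(p101 - p1, 0.01 * d, tolerance = 1e-3)
  # higher post-trial fatality burden on D lowers its price
  expect_lt(d, 0)

  # positive post-trial event-cost burden: k_cost raises costs, price falls
  scb <- vbp_scenario(
    endpoints = vbp_endpoint("a", weight = 1, incidence = 0.2,
                             event_cost = 4000),
    d_vs_b = vbp_comparison("d_vs_b", rrr = 0.3),
    b_vs_a = vbp_comparison("b_vs_a", rrr = 0.2),
    threshold = 50000
  )
  scb$b_vs_a$drug_price_delta <- scb$threshold *
    weighted_effect(scb, "b_vs_a") - downstream_cost(scb, "b_vs_a")
  expect_lt(linearized_sensitivity(scb, "k_cost", periods = 2,
                                   per_comparison = TRUE), 0)

  # no post-trial block: zero derivative
  expect_equal(linearized_sensitivity(sc, "k_cost", periods = 0), 0)
})

test_that("the sensitivity table aggregates derivatives and ranges for plotting", {
  sc <- generate_scenario(3, seed = 37)
  tab <- sensitivity_table(sc, tolerance = 0.05, per_comparison = TRUE,
                           factors = c("k_alpha", "k_cost"))
  expect_s3_class(tab, "vbp_sensitivity")
  expect_equal(nrow(tab), 2)
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(compute_icer(generate_scenario(2, seed = 2), price = 1000))
  expect_s3_class(p2, "ggplot")
})
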