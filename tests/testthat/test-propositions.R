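test_that("single-endpoint scenarios neutralize both downstream components", {
  sc <- generate_scenario(1, seed = 7)
  rep1 <- check_proposition(sc, 1)
  expect_true(rep1$applicable)
  expect_setequal(rep1$cancelled, c("savings", "survival_costs"))
  expect_lt(abs(verify_cancellation(sc, "savings")),
            1e-9 * abs(solve_vbp_price(sc)))
  expect_lt(abs(verify_cancellation(sc, "survival_costs")),
            1e-9 * abs(solve_vbp_price(sc)))

  # differing case fatality between the comparisons breaks it, and the
  # failing condition is named
  sc2 <- sc
  sc2$d_vs_b$fatality <- pmin(sc$endpoints$fatality * 1.1, 1)
  rep2 <- check_proposition(sc2, 1)
  expect_false(rep2$applicable)
  failing <- rep2$conditions$condition[!rep2$conditions$holds]
  expect_match(failing, "fatality", all = TRUE)
  expect_gt(abs(verify_cancellation(sc2, "survival_costs")), 1e-6)

  expect_error(check_proposition(generate_scenario(2, seed = 1), 1),
               class = "vbp_proposition_error")
  expect_error(check_proposition(sc, "9"), class = "vbp_proposition_error")
})

test_that("each generated proposition scenario passes its own checker", {
  for (id in c("1", "2", "3", "4", "5", "6", "7", "subcase")) {
    for (seed in 1:10) {
      sc <- generate_scenario(id, seed = seed)
      rep <- check_proposition(sc, id)
      expect_true(rep$applicable,
                  label = paste0("P", id, " seed ", seed, " applicable"))
      expect_identical(rep$cancelled,
                       if (id == "1") c("savings", "survival_costs")
                       else if (id %in% c("5", "6", "7")) "savings"
                       else "survival_costs")
    }
  }
})

test_that("cancellation verification is sound on generated scenarios and detects violations", {
  for (id in c("2", "4", "5", "7")) {
    sc <- generate_scenario(id, seed = 21)
    comp <- cancelled_component(id)
    expect_lt(abs(verify_cancellation(sc, comp)),
              1e-9 * abs(solve_vbp_price(sc)),
              label = paste0("P", id, " residual"))
    scp <- perturb_condition(sc, id)
    expect_gt(abs(verify_cancellation(scp, comp)), 1e-6,
              label = paste0("P", id, " perturbed residual"))
    expect_false(check_proposition(scp, id)$applicable)
  }
})

test_that("a morbidity-only single-endpoint scenario is the archetypal full shortcut", {
  # one endpoint, no mortality effect: reduced hospitalizations, fatality 0
  inp <- as.list(hf_example_inputs())
  sc <- vbp_scenario(
    endpoints = vbp_endpoint("hosp", weight = 1, incidence = inp$incidence,
                             event_cost = -inp$event_cost),
    d_vs_b = vbp_comparison("d_vs_b", rrr = inp$rrr),
    b_vs_a = vbp_comparison("b_vs_a", rrr = 0.1),
    threshold = inp$threshold, trial_duration = inp$duration
  )
  rep1 <- check_proposition(sc, 1)
  expect_true(rep1$applicable)
  expect_true(rep1$price_invariant)
})

test_that("the applicability scan orders reports and handles preconditions", {
  sc4 <- generate_scenario(4, seed = 3)
  reps <- applicable_propositions(sc4)
  smry <- tidy(reps)
  expect_true(smry$applicable[smry$proposition == "4"])
  expect_false(smry$applicable[smry$proposition == "2"])  # per-endpoint RRR
  expect_false(smry$applicable[smry$proposition == "1"])  # m > 1
  # applicable price-invariant propositions come first
  first_block <- smry$applicable[1]
  expect_true(first_block)

  # a scenario violating every condition yields an empty applicable set
  set.seed(99)
  scv <- random_scenario(99, m = 3, priced_b = TRUE)
  scv$d_vs_b$fatality <- pmin(scv$endpoints$fatality * 1.3, 0.95)
  expect_equal(sum(tidy(applicable_propositions(scv))$applicable), 0)
})

test_that("the case-fatality subcase cancels survival costs when expenditures grow proportionally", {
  sc <- generate_scenario("subcase", seed = 13)
  rep <- check_subcase(sc)
  expect_true(rep$applicable)
  # residual of the death-denominator price at the trial horizon
  expect_lt(abs(verify_cancellation(sc, "survival_costs")),
            1e-9 * abs(solve_vbp_price(sc)))
  # price oracle at two horizons (proportional growth of both survival
  # expenditure streams)
  p_t <- vbpricer:::chain_price(sc, "trial", denominator = "deaths")
  p_e <- vbpricer:::chain_price(sc, "extended", denominator = "deaths")
  expect_lt(abs(p_e - p_t), 1e-9 * abs(p_t))

  # non-proportional growth of the two survival expenditures breaks the
  # extended-horizon invariance
  scn <- sc
  f <- sc$factors
  f$k_surv_fatality <- f$k_surv * 1.2
  scn$factors <- f
  rep_n <- check_subcase(scn)
  expect_false(rep_n$applicable)
  p_en <- vbpricer:::chain_price(scn, "extended", denominator = "deaths")
  expect_gt(abs(p_en - p_t), 1e-6)

  # trial-structure violation: the two survival costs diverge
  scp <- perturb_condition(sc, "subcase")
  expect_gt(abs(verify_cancellation(scp, "survival_costs")), 1e-6)

  expect_error(check_subcase(generate_scenario(2, seed = 1)),
               class = "vbp_proposition_error")
})
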