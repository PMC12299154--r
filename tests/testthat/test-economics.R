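test_that("monthly milk follows the curve, the reductions, and the drying rules", {
  sc <- dp$scenario
  eff <- dp$effects
  expect_equal(monthly_milk(cow_state(par = 2, mil = 1), sc, eff), 1252)
  expect_equal(monthly_milk(cow_state(par = 1, mil = 1), sc, eff), 1252)
  expect_equal(monthly_milk(cow_state(par = 3, mil = 2), sc, eff), 1333)
  # abortion-history reductions
  expect_equal(monthly_milk(cow_state(ab = 2, par = 3, mil = 1), sc, eff),
               1025 * (1 - 0.194))  # 826.15
  expect_equal(monthly_milk(cow_state(ab = 1, par = 2, mil = 1), sc, eff),
               1252 * (1 - 0.073))
  # months 11-12 carry the month-10 yield; beyond the milking window: dry
  expect_equal(monthly_milk(cow_state(par = 2, mil = 11), sc, eff), 703)
  expect_equal(monthly_milk(cow_state(par = 2, mil = 13), sc, eff), 0)
  # a conventional gestation-based dry-off can be imposed via the scenario
  sc8 <- sc; sc8$dry_off_preg <- 8
  expect_equal(monthly_milk(cow_state(par = 2, preg = 8, mil = 12), sc8, eff), 0)
  expect_equal(monthly_milk(cow_state(par = 2, preg = 7, mil = 12), sc8, eff), 703)
})

test_that("single-state cash flow matches hand arithmetic", {
  pol <- validation_policy()
  td <- transition_distribution(cow_state(par = 2, preg = 0, mil = 1),
                                dp$rates, dp$effects, pol, "base")
  cf <- state_cashflow(cow_state(par = 2, preg = 0, mil = 1),
                       attr(td, "events"), dp$scenario, dp$rates,
                       dp$effects, pol)
  # income over feed cost: 1252 kg x 0.36 - 25 kg/d x 30 d x 0.17
  expect_equal(unname(cf["iofc"]), 1252 * 0.36 - 25 * 30 * 0.17)  # 323.22
  # no calving possible from an open state
  expect_equal(unname(cf[c("calf_income", "vet_cost", "twin_loss")]),
               c(0, 0, 0))
  # exits: death 0.012 (no salvage) + involuntary culling 0.018 (salvage)
  expect_equal(unname(cf["salvage_income"]), 1.16 * 563 * 0.018)
  expect_equal(unname(cf["replacement_cost"]), 1300 * 0.030)
  # MIL 1 is below the insemination window: no AI charge
  expect_equal(unname(cf["ai_cost"]), 0)
  td2 <- transition_distribution(cow_state(par = 2, preg = 0, mil = 3),
                                 dp$rates, dp$effects, pol, "base")
  cf2 <- state_cashflow(cow_state(par = 2, preg = 0, mil = 3),
                        attr(td2, "events"), dp$scenario, dp$rates,
                        dp$effects, pol)
  expect_equal(unname(cf2["ai_cost"]), dp$scenario$ai_cost)
  expect_equal(unname(cf2["net"]),
               unname(cf2["iofc"] + cf2["calf_income"] + cf2["salvage_income"] -
                        cf2["replacement_cost"] - cf2["ai_cost"] -
                        cf2["vet_cost"] - cf2["twin_loss"]))
})

test_that("component linearity in prices and in the stationary weights", {
  fit <- herd_model("base", policy = herd_policy(8, 8))
  sc2 <- dp$scenario
  sc2$milk_price <- 2 * sc2$milk_price
  fit2 <- herd_model("base", scenario = sc2, policy = herd_policy(8, 8))
  # doubling the milk price doubles exactly the milk term of IOFC
  milk_term <- sum(fit$steady$pi *
                     monthly_milk(fit$states, dp$scenario, dp$effects)) *
    dp$scenario$milk_price
  expect_equal(fit2$net$iofc - fit$net$iofc, milk_term)
  expect_equal(fit2$net$calf_income, fit$net$calf_income)

  sc3 <- dp$scenario
  sc3$calf_value <- 3 * sc3$calf_value
  fit3 <- herd_model("base", scenario = sc3, policy = herd_policy(8, 8))
  expect_equal(fit3$net$calf_income, 3 * fit$net$calf_income)
  expect_equal(fit3$net$iofc, fit$net$iofc)

  # probability-weighting: a uniform distribution over two states averages
  # their contributions
  cf <- fit$cashflows[1:2, , drop = FALSE]
  nb <- herd_net_benefit(c(0.5, 0.5), cf)
  expect_equal(nb$net, mean(cf[, "net"]))
  expect_equal(nb$annual_net, 12 * nb$net)
  expect_error(herd_net_benefit(c(1, 0, 0), cf), "differ")
})

test_that("annualization and the breakdown identity hold on a full fit", {
  fit <- herd_model("extended", policy = herd_policy(6, 6))
  nb <- fit$net
  expect_equal(nb$annual_net, 12 * nb$net)
  expect_equal(nb$net,
               nb$iofc + nb$calf_income + nb$salvage_income -
                 nb$replacement_cost - nb$ai_cost - nb$vet_cost - nb$twin_loss)
  expect_equal(nb$net, sum(fit$steady$pi * fit$cashflows[, "net"]))
})

test_that("model methods expose the fit consistently", {
  fit <- herd_model("base", policy = validation_policy())
  co <- coef(fit)
  expect_equal(unname(co["net"]), fit$net$net)
  expect_equal(unname(co["annual_net"]), 12 * unname(co["net"]))
  expect_equal(predict(fit), unname(fit$cashflows[, "net"]))
  nd <- cow_state(par = 2, preg = 0, mil = 1)
  expect_equal(predict(fit, nd, type = "milk"), 1252)
  expect_error(predict(fit, cow_state(ab = 1, par = 2)), "state space")
  expect_output(print(fit), "net benefit")
  expect_output(print(summary(fit)), "Parity distribution")
  sim <- simulate(fit, nsim = 500, seed = 3, n_months = 60)
  expect_s3_class(sim, "herd_cohort")
})
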