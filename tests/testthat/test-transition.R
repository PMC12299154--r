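test_that("kernel reproduces hand-computed one-step distributions", {
  pol <- validation_policy()

  # fresh heifer: only death (0.004) + involuntary culling (0.006) move her
  # (both to the replacement state, which is the state itself), no conception
  # at MIL 1
  td <- transition_distribution(cow_state(par = 1, preg = 0, mil = 1),
                                dp$rates, dp$effects, pol, "base")
  expect_equal(td$prob[td$mil == 1], 0.010)
  expect_equal(td$prob[td$mil == 2], 0.990)

  # first insemination month: survivors conceive at the published 0.2368
  td <- transition_distribution(cow_state(par = 1, preg = 0, mil = 2),
                                dp$rates, dp$effects, pol, "base")
  expect_equal(td$prob[td$preg == 1], 0.99 * 0.2368)  # 0.234432
  expect_equal(td$prob[td$preg == 0 & td$mil == 3], 0.99 * (1 - 0.2368))
  ev <- attr(td, "events")
  expect_equal(unname(ev["conception"]), 0.234432)
  expect_equal(sum(ev), 1)

  # third-gestation-month multiparous cow, extended model: 2.5% hazard
  # splits 84.8% rebreeding (same parity, MIL + 1) / 15.2% new lactation
  # (parity + 1, MIL = 1); mortality 0.009 + culling 0.011 exit first
  td <- transition_distribution(cow_state(par = 2, preg = 3, mil = 7),
                                dp$rates, dp$effects, pol, "extended")
  surv <- 1 - 0.009 - 0.011
  expect_equal(td$prob[td$ab == 1], surv * 0.025 * (1 - 1.9 / 12.5))
  row_nla <- td[td$ab == 2, ]
  expect_equal(row_nla$prob, surv * 0.025 * (1.9 / 12.5))
  expect_equal(row_nla[, c("par", "preg", "mil")],
               data.frame(par = 3L, preg = 0L, mil = 1L),
               ignore_attr = TRUE)
  expect_equal(td$prob[td$preg == 4], surv * 0.975)
  expect_equal(sum(td$prob), 1)

  # the culling-risk multiplier scales involuntary culling of aborted cows
  td <- transition_distribution(cow_state(ab = 1, par = 3, preg = 0, mil = 4),
                                dp$rates, dp$effects, pol, "extended")
  ev <- attr(td, "events")
  expect_equal(unname(ev["involuntary_cull"]), 0.015 * 1.9)
  expect_equal(unname(ev["death"]), 0.010)

  # calving moves to the next parity at MIL 1; final parity is replaced
  td <- transition_distribution(cow_state(par = 3, preg = 9, mil = 12),
                                dp$rates, dp$effects, pol, "base")
  expect_equal(td[td$par == 4, c("preg", "mil")],
               data.frame(preg = 0L, mil = 1L), ignore_attr = TRUE)
  td <- transition_distribution(cow_state(par = 15, preg = 9, mil = 12),
                                dp$rates, dp$effects, pol, "base")
  expect_equal(td$par, 1L)  # everything lands on the replacement state
  expect_equal(sum(td$prob), 1)

  # voluntary culling strikes exactly at the threshold month
  td <- transition_distribution(cow_state(par = 2, preg = 0, mil = 10),
                                dp$rates, dp$effects, pol, "base")
  expect_equal(td, data.frame(ab = 0L, par = 1L, preg = 0L, mil = 1L,
                              prob = 1), ignore_attr = TRUE)

  expect_error(transition_distribution(cow_state(par = 1, preg = 1, mil = 1),
                                       dp$rates, dp$effects, pol, "base"),
               "infeasible")
  expect_error(transition_distribution(cow_state(ab = 1, par = 2, preg = 0,
                                                 mil = 3),
                                       dp$rates, dp$effects, pol, "base"),
               "ab = 0")
})

test_that("transition matrices are row-stochastic with mass on feasible states only", {
  for (kind in c("base", "extended")) {
    st <- herd_states(kind)
    tm <- build_transition_matrix(st, dp$rates, dp$effects, validation_policy())
    expect_equal(dim(tm$P), rep(nrow(st), 2))
    expect_rows_stochastic(tm$P)
    expect_true(all(tm$P@x >= 0))
    expect_equal(rowSums(tm$events), rep(1, nrow(st)), tolerance = 1e-12)
  }
})

test_that("matrix rows equal the single-state kernel exactly", {
  st <- herd_states("extended")
  tm <- build_transition_matrix(st, dp$rates, dp$effects, validation_policy())
  set.seed(42)
  for (i in sample.int(nrow(st), 40)) {
    td <- transition_distribution(st[i, ], dp$rates, dp$effects,
                                  validation_policy(), "extended")
    row <- tm$P[i, ]
    j <- which(row != 0)
    idx <- herdabort:::state_lookup(herdabort:::state_index_array(st),
                                    td$ab, td$par, td$preg, td$mil)
    expect_setequal(j, idx)
    expect_equal(unname(row[idx]), td$prob)
    expect_equal(tm$events[i, ], attr(td, "events"))
  }
})

test_that("with neutral effects and no new-lactation branch the extended chain
           marginalizes onto the base chain", {
  rates <- ra_only_rates()
  pol <- herd_policy(6, 6)
  ext <- herd_model("extended", rates, neutral_effects(), dp$scenario, pol)
  base <- herd_model("base", rates, neutral_effects(), dp$scenario, pol)
  marg <- rowsum(ext$steady$pi,
                 paste(ext$states$par, ext$states$preg, ext$states$mil))
  key <- paste(base$states$par, base$states$preg, base$states$mil)
  expect_equal(unname(marg[match(key, rownames(marg)), 1]),
               base$steady$pi, tolerance = 1e-10)
})

test_that("empirical one-step frequencies match the kernel within 3 binomial SE", {
  td <- transition_distribution(cow_state(par = 2, preg = 3, mil = 7),
                                dp$rates, dp$effects, validation_policy(),
                                "extended")
  n <- 1e5
  set.seed(11)
  draws <- sample.int(nrow(td), n, replace = TRUE, prob = td$prob)
  freq <- tabulate(draws, nbins = nrow(td)) / n
  se <- sqrt(td$prob * (1 - td$prob) / n)
  expect_true(all(abs(freq - td$prob) <= 3 * se + 1e-12))
})

test_that("row-stochasticity holds across randomized rate tables and policies", {
  st <- herd_states("base")
  for (s in 1:10) {
    r <- random_rate_tables(s)
    m <- sample(2:15, 1)
    tm <- build_transition_matrix(st, r, dp$effects, herd_policy(m, m))
    expect_rows_stochastic(tm$P)
  }
})

test_that("zero abortion hazard leaves the aborted blocks unreachable", {
  r <- dp$rates
  r$abort_hazard[] <- 0
  fit <- herd_model("extended", r, dp$effects, dp$scenario, herd_policy(6, 6))
  expect_equal(unname(abortion_prevalence(fit)), c(0, 0, 0))
  expect_true(all(!fit$steady$reachable[fit$states$ab >= 1]))
})
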