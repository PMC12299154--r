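test_that("packaged defaults reproduce the published parameter tables", {
  r <- dp$rates

  # spot cells of the monthly rate table
  expect_identical(unname(r$preg_rate[2, "primiparous"]), 0.2368)
  expect_identical(unname(r$preg_rate[2, "multiparous"]), 0.2103)
  expect_identical(unname(r$preg_rate[15, "multiparous"]), 0.0549)
  expect_identical(unname(r$mortality[1, "primiparous"]), 0.004)
  expect_identical(unname(r$inv_cull[1, "multiparous"]), 0.018)
  expect_identical(unname(r$mortality[24, "primiparous"]), 0.0025)
  expect_true(all(r$preg_rate[c(1, 16:24), ] == 0))

  # abortion hazards: months 2-8, totalling 8.45%
  expect_identical(r$abort_hazard[2], 0.035)
  expect_identical(r$abort_hazard[3], 0.025)
  expect_identical(unname(r$abort_hazard[c(1, 9)]), c(0, 0))
  expect_equal(sum(r$abort_hazard), 0.0845)

  # RA/NLA split from the 1.9/12.5 odds
  expect_equal(r$nla_share, 1.9 / 12.5)
  expect_equal(r$ra_share, 1 - 1.9 / 12.5)
  expect_equal(round(100 * r$ra_share, 1), 84.8)

  e <- dp$effects
  expect_identical(e$milk_reduction_ra, 0.073)
  expect_identical(e$milk_reduction_nla, 0.194)
  expect_identical(e$cull_risk_multiplier, 1.9)

  sc <- dp$scenario
  expect_identical(sc$milk_price, 0.36)
  expect_identical(sc$calf_value, 100)
  expect_identical(sc$carcass_price, 1.16)
  expect_identical(sc$replacement_cost, 1300)
  expect_identical(sc$feed_cost_lact, 0.17)
  expect_identical(sc$feed_cost_dry, 0.13)
  expect_identical(sc$dmi, 25)
  expect_identical(unname(sc$milk_curve[1, "second_parity"]), 1252)
  expect_identical(unname(sc$milk_curve[1, "later_parity"]), 1025)
  expect_identical(unname(sc$milk_curve[10, "second_parity"]), 703)
})

test_that("validation accepts the defaults and rejects single mutations", {
  expect_true(validate_params(dp$rates, dp$effects, dp$scenario))

  bad <- dp$rates; bad$preg_rate[3, 1] <- 1.2
  expect_error(validate_params(bad), "preg_rate")
  bad <- dp$rates; bad$mortality[5, 2] <- -0.01
  expect_error(validate_params(bad), "mortality")
  bad <- dp$rates; bad$preg_rate[2, 1] <- 0.999  # breaks the risk budget
  expect_error(validate_params(bad), "exceeds 1")
  bad <- dp$rates; bad$abort_hazard[1] <- 0.01
  expect_error(validate_params(bad), "abort_hazard")
  bad <- dp$rates; bad$nla_share <- 0.5
  expect_error(validate_params(bad), "ra_share")
  bad_e <- dp$effects; bad_e$cull_risk_multiplier <- 0.5
  expect_error(validate_params(dp$rates, bad_e), "multiplier")
  bad_s <- dp$scenario; bad_s$milk_price <- -1
  expect_error(validate_params(dp$rates, dp$effects, bad_s), "milk_price")
})

test_that("parameter files override defaults field-wise and are validated", {
  f <- withr::local_tempfile(fileext = ".yaml")

  writeLines("economics:\n  milk_price: 0.40\n", f)
  p <- load_params(f)
  expect_equal(p$scenario$milk_price, 0.40)
  expect_equal(p$scenario$calf_value, dp$scenario$calf_value)
  expect_equal(p$rates$preg_rate, dp$rates$preg_rate)

  writeLines(paste0("rates:\n  preg_rate:\n    primiparous: [",
                    paste(c(0, rep(1.2, 14), rep(0, 9)), collapse = ", "),
                    "]\n"), f)
  expect_error(load_params(f), "preg_rate")

  writeLines("", f)  # empty file falls back to the packaged defaults
  p <- load_params(f)
  expect_equal(p$rates, dp$rates)
  expect_equal(p$scenario, dp$scenario)
  expect_equal(p$effects, dp$effects)
  expect_equal(p$policy, dp$policy)

  writeLines("policy:\n  cull_mil_primiparous: 6\n", f)
  expect_equal(load_params(f)$policy$cull_mil_primiparous, 6L)

  expect_error(load_params("no/such/file.yaml"), "not found")
})

test_that("randomized rate tables are deterministic per seed and always valid", {
  a <- random_rate_tables(7)
  b <- random_rate_tables(7)
  expect_identical(a, b)
  expect_false(identical(random_rate_tables(0), random_rate_tables(1)))
  for (s in 1:25) {
    r <- random_rate_tables(s)
    expect_true(validate_params(r))
    expect_true(all(r$mortality + r$inv_cull + r$preg_rate <= 1))
  }
})
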