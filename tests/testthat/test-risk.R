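# Hand oracle for the dose model, written out term by term.
add_oracle <- function(c, ingr, ef, ed, bw, at_days) {
  (c * ingr * ef * ed) / (bw * at_days)
}

test_that("average daily dose matches the hand oracle in both AT modes", {
  s <- default_scenario()
  expect_equal(average_daily_dose(117.01, s),
               add_oracle(117.01, 0.001, 90, 40, 75, 365 * 40))
  expect_equal(average_daily_dose(117.01, s), 3.8469e-4, tolerance = 1e-4)
  expect_equal(average_daily_dose(0, s), 0)

  sl <- default_scenario("lifetime")
  expect_equal(average_daily_dose(117.01, sl),
               add_oracle(117.01, 0.001, 90, 40, 75, 365 * 75.5))
  # lifetime dose is the match_ed dose rescaled by ED / life expectancy
  expect_equal(average_daily_dose(117.01, sl),
               average_daily_dose(117.01, s) * 40 / 75.5)

  expect_error(average_daily_dose(NaN, s), "finite")
  expect_error(average_daily_dose(-1, s), ">= 0")
})

test_that("ADD is linear in C and invariant to ED under match_ed", {
  set.seed(21)
  for (i in 1:25) {
    ingr <- runif(1, 1e-4, 0.01); ef <- runif(1, 1, 365)
    bw <- runif(1, 40, 100); c <- runif(1, 0, 200)
    ed1 <- runif(1, 1, 70); ed2 <- runif(1, 1, 70)
    s1 <- exposure_scenario(ingr, ef, ed1, bw, "match_ed")
    s2 <- exposure_scenario(ingr, ef, ed2, bw, "match_ed")
    expect_equal(average_daily_dose(c, s1), average_daily_dose(c, s2))
    expect_equal(average_daily_dose(2 * c, s1), 2 * average_daily_dose(c, s1))
    expect_equal(average_daily_dose(c, s1), c * ingr * ef / (bw * 365))
  }
})

test_that("hazard quotient divides by RfD and uses a strict threshold", {
  hq <- hazard_quotient(3.8469e-4, "Pb")
  expect_equal(hq$hq, 3.8469e-4 / 0.004)
  expect_equal(hq$label, "no_concern")
  expect_equal(hazard_quotient(0, "As")$hq, 0)
  # HQ exactly 1 is still no_concern
  expect_equal(classify_hq(1), "no_concern")
  expect_equal(classify_hq(1 + 1e-12), "potential_risk")
})

test_that("carcinogenic risk supports both characterizations, rejects Mn", {
  add <- 2.0381e-4
  expect_equal(carcinogenic_risk(add, "Pb"), add * 0.0085)
  expect_equal(carcinogenic_risk(add, "Pb", formula = "divide"), add / 0.0085)
  expect_equal(carcinogenic_risk(0, "Cd"), 0)
  expect_error(carcinogenic_risk(add, "Mn"), "slope factor")

  # end-to-end Cd at the maximum printed concentration: negligible risk
  cr_cd <- carcinogenic_risk(
    average_daily_dose(0.123, default_scenario("lifetime")), "Cd")
  expect_equal(cr_cd, 1.31e-9, tolerance = 5e-3)
  expect_equal(classify_cr(cr_cd), "very_low")
})

test_that("classify_cr partitions the nonnegative line", {
  expect_equal(classify_cr(5e-4), "moderate")
  expect_equal(classify_cr(1.732e-6), "above_screening")
  expect_equal(classify_cr(0), "very_low")
  expect_error(classify_cr(-1e-9), ">= 0")

  # every band boundary gets exactly one label, lower bounds inclusive
  bounds <- c(1e-6, 1e-5, 1e-4, 1e-3)
  eps <- 1e-12
  vals <- sort(c(0, bounds, bounds - eps, bounds + eps, 1))
  labs <- classify_cr(vals)
  expect_true(all(labs %in% c("very_low", "above_screening", "low",
                              "moderate", "substantial")))
  expect_equal(classify_cr(1e-6), "above_screening")
  expect_equal(classify_cr(1e-6 - eps), "very_low")
  expect_equal(classify_cr(1e-5), "low")
  expect_equal(classify_cr(1e-4), "moderate")
  expect_equal(classify_cr(1e-3), "substantial")
  # labels are non-decreasing in cr (partition with ordered bands)
  sev <- match(labs, c("very_low", "above_screening", "low", "moderate",
                       "substantial"))
  expect_true(all(diff(sev) >= 0))
})

test_that("assess_dataset reproduces the fixture-level conclusions", {
  fx <- build_paper_fixture(1)
  res <- assess_dataset(fx)
  expect_equal(nrow(res), 48L)

  # no element approaches HQ = 1 anywhere
  expect_true(all(res$hq < 1))
  expect_true(all(res$hq_label == "no_concern"))

  # Pb risk crosses the 1e-6 screening level exactly at the two
  # grossly contaminated sites
  pb <- res[res$element == "Pb", ]
  above <- pb$sample_id[pb$cr > 1e-6]
  expect_setequal(above, c("P06", "P10"))
  expect_equal(pb$cr_label[pb$sample_id == "P06"], "above_screening")

  # Mn carries HQ only
  mn <- res[res$element == "Mn", ]
  expect_true(all(is.na(mn$cr)) && all(is.na(mn$add_car)))
  expect_true(all(!is.na(mn$hq)))

  # lifetime/chronic dose ratio is ED / life expectancy for carcinogens
  car <- res[res$element != "Mn" & res$concentration > 0, ]
  expect_equal(car$add_car / car$add_nc, rep(40 / 75.5, nrow(car)))

  # with the zero policy censored cells contribute no dose
  cens <- res[res$sample_id == "P11" & res$element == "Cd", ]
  expect_equal(cens$hq, 0)

  # empty dataset passes through
  expect_equal(nrow(assess_dataset(propolistox:::empty_samples())), 0L)
})

test_that("assessment is deterministic and monotone in concentration", {
  fx <- build_paper_fixture(5)
  expect_identical(assess_dataset(fx), assess_dataset(fx))

  m <- random_toy_matrix(4, 13)
  r1 <- assess_dataset(samples_from_matrix(m))
  r2 <- assess_dataset(samples_from_matrix(m * 3))
  expect_true(all(r2$hq >= r1$hq))
  expect_true(all(r2$cr >= r1$cr, na.rm = TRUE))
})
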