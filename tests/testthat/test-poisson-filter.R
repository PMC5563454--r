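test_that("max_tolerated_ac reproduces the worked Poisson bounds", {
  expect_identical(max_tolerated_ac(1e-4, 100000), 15L)
  expect_identical(max_tolerated_ac(4e-5, 121412), 9L)
  expect_identical(max_tolerated_ac(2e-5, 121412), 5L)
  expect_identical(max_tolerated_ac(0, 123456), 0L)
  expect_identical(max_tolerated_ac(0.3, 0), 0L)
})

test_that("max_tolerated_ac agrees with direct PMF summation", {
  for (lambda in c(0.01, 0.3553, 1, 4.856, 10, 42.7, 150)) {
    an <- 10000
    expect_identical(max_tolerated_ac(lambda / an, an),
                     oracle_max_tolerated_ac(lambda / an, an))
    expect_identical(max_tolerated_ac(lambda / an, an, confidence = 0.99),
                     oracle_max_tolerated_ac(lambda / an, an,
                                             confidence = 0.99))
  }
})

test_that("filtering_af matches the exhaustive grid-scan definition", {
  expect_equal(filtering_af(2, 10000), 3.5e-5)
  expect_equal(filtering_af(1, 121412), 0)  # singletons never filtered
  expect_equal(filtering_af(0, 50000), 0)
  for (an in c(1000, 121412)) {
    for (ac in c(0, 1, 2, 3, 5, 9, 17)) {
      expect_equal(filtering_af(ac, an), oracle_filtering_af(ac, an),
                   info = sprintf("ac=%d an=%d", ac, an))
    }
  }
  # non-default confidence and granularity still match the scan
  expect_equal(filtering_af(4, 10000, confidence = 0.99),
               oracle_filtering_af(4, 10000, confidence = 0.99))
  expect_equal(filtering_af(4, 10000, granularity = 1e-5),
               oracle_filtering_af(4, 10000, granularity = 1e-5))
})

test_that("filtering_af brackets the Poisson bound on both sides", {
  g <- 1e-6
  for (an in c(1000, 10000, 121412)) {
    for (ac in 2:25) {
      f <- filtering_af(ac, an)
      expect_lte(max_tolerated_ac(f, an), ac - 1L)
      expect_gte(max_tolerated_ac(f + g, an), ac)
    }
  }
})

test_that("bounds are monotone in allele count, frequency and sample size", {
  an <- 10000
  faf <- filtering_af(0:30, an)
  expect_true(all(diff(faf) >= 0))
  afs <- seq(0, 5e-3, length.out = 40)
  expect_true(all(diff(max_tolerated_ac(afs, an)) >= 0))
  expect_true(all(diff(max_tolerated_ac(2e-4, c(1e3, 1e4, 1e5, 1e6))) >= 0))
})

test_that("smaller reference samples give larger (more conservative) filtering AFs", {
  expect_gt(filtering_af(5, 1000), filtering_af(5, 100000))
  # same allele count carries less frequency evidence in a small sample
  for (ac in c(2, 5, 20)) {
    f <- filtering_af(ac, c(500, 5000, 50000))
    expect_true(all(diff(f) < 0))
  }
})

test_that("true-frequency variants are filtered at most 5% of the time", {
  set.seed(7)
  af <- 4e-5; an <- 121412
  k <- max_tolerated_ac(af, an)
  draws <- rpois(20000, af * an)
  rate <- mean(draws > k)
  se <- sqrt(0.05 * 0.95 / length(draws))
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("popmax takes the highest filtering AF across eligible populations", {
  single <- popmax_filtering_af(
    data.frame(population = "NFE", ac = 2, an = 10000))
  expect_equal(single$popmax_af, 3.5e-5)
  expect_identical(single$popmax_population, "NFE")

  two <- popmax_filtering_af(
    data.frame(population = c("AFR", "NFE"), ac = c(0, 2),
               an = c(8000, 10000)))
  expect_equal(two$per_population, c(AFR = 0, NFE = 3.5e-5))
  expect_identical(two$popmax_population, "NFE")

  none <- popmax_filtering_af(
    data.frame(population = c("AFR", "NFE"), ac = c(0, 0),
               an = c(8000, 10000)))
  expect_equal(none$popmax_af, 0)
  expect_identical(none$popmax_population, "AFR")  # tie: canonical order
})

test_that("popmax skips zero-AN populations and honours the whitelist", {
  zero_an <- popmax_filtering_af(
    data.frame(population = c("AFR", "NFE"), ac = c(0, 0), an = c(0, 0)))
  expect_equal(zero_an$popmax_af, 0)
  expect_true(is.na(zero_an$popmax_population))
  expect_length(zero_an$per_population, 0)

  # FIN and OTH are outside the canonical set: ignored unless whitelisted
  mixed <- data.frame(population = c("FIN", "NFE"), ac = c(50, 2),
                      an = c(5000, 10000))
  expect_equal(popmax_filtering_af(mixed)$popmax_af, 3.5e-5)
  with_fin <- popmax_filtering_af(
    mixed, populations = c("AFR", "AMR", "EAS", "NFE", "SAS", "FIN"))
  expect_identical(with_fin$popmax_population, "FIN")
  expect_gt(with_fin$popmax_af, 3.5e-5)

  # min_an excludes poorly genotyped populations
  small <- data.frame(population = c("AFR", "NFE"), ac = c(3, 2),
                      an = c(50, 10000))
  expect_identical(
    popmax_filtering_af(small, min_an = 100)$popmax_population, "NFE")
})

test_that("count and parameter validation is enforced", {
  expect_error(max_tolerated_ac(1.5, 1000), "af")
  expect_error(max_tolerated_ac(1e-4, -1), "an")
  expect_error(max_tolerated_ac(1e-4, 1000, confidence = 1), "confidence")
  expect_error(filtering_af(5, 3), "exceeds")
  expect_error(filtering_af(-1, 100), "non-negative")
  expect_error(filtering_af(2, 1000, granularity = 0), "granularity")
  expect_error(popmax_filtering_af(data.frame()), "columns")
  expect_error(popmax_filtering_af(
    data.frame(population = character(), ac = integer(), an = integer())),
    "empty")
})
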