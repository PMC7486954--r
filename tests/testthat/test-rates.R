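# Poisson rate estimation with exact confidence intervals

test_that("Garwood intervals match the independent exact Poisson test", {
  for (count in c(0L, 3L, 30L, 455L)) {
    for (E in c(1, 8.19e11)) {
      r <- rate_estimate(count, E)
      oracle <- poisson.test(count)$conf.int / E
      expect_equal(r$ci, as.numeric(oracle), tolerance = 1e-12,
                   info = sprintf("count %d exposure %g", count, E))
      expect_equal(r$mu, count / E)
    }
  }
})

test_that("a zero count gives mu = 0 and upper bound 3.689/exposure", {
  r <- rate_estimate(0L, 100)
  expect_equal(r$mu, 0)
  expect_equal(r$ci[1], 0)
  expect_equal(r$ci[2] * 100, 3.68887945, tolerance = 1e-8)
})

test_that("rate estimation is exactly scale-equivariant in exposure", {
  r1 <- rate_estimate(37L, 1e6)
  r2 <- rate_estimate(37L, 2e6)
  expect_equal(r2$mu, r1$mu / 2)
  expect_equal(r2$ci, r1$ci / 2)
})

test_that("normal-approximation intervals are available and centred on mu", {
  r <- rate_estimate(100L, 1e4, method = "normal")
  expect_equal(mean(r$ci), r$mu, tolerance = 1e-12)
  expect_equal(r$ci[2] - r$mu, 1.959964 * 10 / 1e4, tolerance = 1e-5)
})

test_that("per-line rates and count moments are exact arithmetic", {
  tab <- ehux_ma_lines()
  pl <- per_line_rates(tab)
  # direct arithmetic on one line
  s <- pl$rates[pl$rates$line == "Eh_mut_S", ]
  expect_equal(s$mu, 52 / (2 * 116500955 * 214), tolerance = 1e-12)
  # exact rational mean and sample SD of the counts
  expect_equal(pl$mean_count, sum(tab$n_mut) / 15)
  expect_equal(pl$sd_count,
               sqrt(sum((tab$n_mut - mean(tab$n_mut))^2) / 14))
})

test_that("heterogeneity chi-square is zero for identical lines", {
  tab <- experiment_table(data.frame(line = letters[1:4], generations = 100,
                                     callable_sites = 1e6, n_mut = 7L))
  for (mode in c("exposure", "equal")) {
    pl <- per_line_rates(tab, expectation = mode)
    expect_equal(pl$chisq, 0)
    expect_equal(pl$df, 3L)
  }
  # with equal exposures the two expectation modes coincide
  tab2 <- experiment_table(data.frame(line = letters[1:4], generations = 100,
                                      callable_sites = 1e6,
                                      n_mut = c(3L, 9L, 5L, 7L)))
  expect_equal(per_line_rates(tab2, expectation = "exposure")$chisq,
               per_line_rates(tab2, expectation = "equal")$chisq)
  expect_error(per_line_rates(tab2[1, , drop = FALSE]), "2 lines")
})

test_that("the fitted model reports U and U_cds as size x mu", {
  fit <- ma_fit(ehux_ma_lines(), genome_size = 167e6, cds_size = 39635709)
  expect_equal(fit$U, 167e6 * fit$rate$mu)
  expect_equal(fit$U_cds, 39635709 * fit$rate$mu)
  expect_equal(unname(coef(fit)), fit$rate$mu)
  expect_equal(confint(fit), fit$rate$ci)
  s <- summary(fit)
  expect_equal(unname(s["count"]), 455)
  # zero rate propagates
  tab0 <- experiment_table(data.frame(line = "a", generations = 10,
                                      callable_sites = 100, n_mut = 0L))
  fit0 <- ma_fit(tab0, genome_size = 1e6, cds_size = 1e5)
  expect_equal(c(fit0$U, fit0$U_cds), c(0, 0))
})

test_that("organelle exposure uses copy number x length x generations", {
  gens <- ehux_ma_lines()$generations
  r <- organelle_rate(7L, organelle_length = 29013, copy_number = 50,
                      generations = gens)
  expect_equal(r$mu, 7 / (50 * 29013 * sum(gens)), tolerance = 1e-12)
  expect_error(organelle_rate(7L, 29013, generations = gens),
               "copy number")
  # consistency reduction: organelle machinery reproduces the nuclear fit
  tab <- experiment_table(data.frame(line = "a", generations = 100,
                                     callable_sites = 5e5, n_mut = 12L))
  nuc <- ma_fit(tab)$rate
  org <- organelle_rate(12L, organelle_length = 5e5, copy_number = 2,
                        generations = 100)
  expect_equal(org$mu, nuc$mu)
  expect_equal(org$ci, nuc$ci)
})

test_that("copy number estimation is coverage proportionality", {
  expect_equal(estimate_copy_number(1000, 50, 2), 40)
  expect_equal(estimate_copy_number(50, 50, 2), 2)
  set.seed(9)
  # planted coverage ratio r recovers 2r
  nuc <- rnbinom(200, mu = 60, size = 20)
  org <- rnbinom(200, mu = 60 * 7.5, size = 20)
  est <- estimate_copy_number(mean(org), mean(nuc), 2)
  expect_lt(abs(est - 15), 1.5)
})

test_that("rate comparison is a symmetric df-1 contingency chi-square", {
  a <- rate_estimate(30L, 1e6)
  b <- rate_estimate(30L, 1e6)
  same <- compare_rates(a, b)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$df, 1)
  c1 <- rate_estimate(90L, 1e6)
  expect_equal(compare_rates(a, c1)$chisq, compare_rates(c1, a)$chisq)
  # a 3x rate ratio at this exposure is confidently detected
  set.seed(10)
  hits <- replicate(20, {
    x <- rate_estimate(rpois(1, 100), 1e6)
    y <- rate_estimate(rpois(1, 300), 1e6)
    compare_rates(x, y)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("Garwood coverage holds near the nominal level", {
  set.seed(11)
  lam <- 30
  draws <- rpois(400, lam)
  covered <- vapply(draws, function(x) {
    ci <- rate_estimate(x, 1)$ci
    ci[1] <= lam && lam <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})
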