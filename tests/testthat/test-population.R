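test_that("log-normal moment identities hold", {
  # hand arithmetic: mu_x = 2, CV = 0.3
  lp <- lognormal_parameters(2, 0.3)
  expect_equal(lp$sigma_w^2, log(1.09), tolerance = 1e-12)
  expect_equal(lp$sigma_w^2, 0.08618, tolerance = 1e-4)
  expect_equal(lp$mu_w, 0.6501, tolerance = 1e-4)
  # degenerate case
  lp0 <- lognormal_parameters(5, 0)
  expect_equal(lp0$sigma_w, 0)
  expect_equal(lp0$mu_w, log(5))
  # moment closure exp(mu_w + sigma_w^2/2) = mu_x over a grid
  for (mu in c(0.3, 1, 7)) for (cv in c(0, 0.2, 0.9)) {
    lp <- lognormal_parameters(mu, cv)
    expect_equal(exp(lp$mu_w + lp$sigma_w^2 / 2), mu, tolerance = 1e-12)
    # and the implied CV
    if (cv > 0)
      expect_equal(sqrt(exp(lp$sigma_w^2) - 1), cv, tolerance = 1e-12)
  }
  expect_error(lognormal_parameters(-1, 0.3), "domain error")
})

test_that("abundance sampling matches a quadrature oracle under truncation", {
  spec <- population_spec(mu_x = 1, cv_x = 0.5, n = 1e5, seed = 42)
  ab <- sample_abundances(spec)
  # oracle: mean of the +/-3 SD truncated log-normal by numeric integration
  lp <- lognormal_parameters(1, 0.5)
  lo <- exp(lp$mu_w - 3 * lp$sigma_w); hi <- exp(lp$mu_w + 3 * lp$sigma_w)
  mass <- integrate(function(x) dlnorm(x, lp$mu_w, lp$sigma_w), lo, hi)$value
  mean_trunc <- integrate(function(x) x * dlnorm(x, lp$mu_w, lp$sigma_w),
                          lo, hi)$value / mass
  expect_equal(mean(ab$retained), mean_trunc, tolerance = 0.02)
  # expected exclusion fraction ~ 2*pnorm(-3) = 0.27%
  expect_equal(ab$excluded_count / spec$n, 2 * pnorm(-3), tolerance = 0.3)
  # untruncated draws converge to the target moments
  expect_equal(mean(ab$draws), 1, tolerance = 0.02)
  expect_equal(sd(ab$draws) / mean(ab$draws), 0.5, tolerance = 0.02)
})

test_that("sampling is seed-stable and extending n keeps early draws", {
  spec <- population_spec(n = 500, seed = 7)
  a <- sample_abundances(spec)
  b <- sample_abundances(spec)
  expect_identical(a, b)
  big <- sample_abundances(population_spec(n = 1000, seed = 7))
  expect_identical(big$draws[1:500], a$draws)
  # CV 0: every draw equals the mean, nothing excluded
  d0 <- sample_abundances(population_spec(mu_x = 1.3, cv_x = 0, n = 50, seed = 1))
  expect_true(all(d0$draws == 1.3))
  expect_identical(d0$excluded_count, 0L)
})

test_that("a degenerate population reproduces the reference individual", {
  spec <- population_spec(cv_x = 0, n = 1, seed = 1)
  pop <- run_population(spec, ref_ps(), days = 1)
  ref <- extract_cmax(simulate_ba(ref_ps(), days = 1, dt_out = 0.02,
                                  rtol = 1e-6, atol = 1e-8), "plasma")$cmax
  expect_equal(pop$cmax_plasma, ref, tolerance = 1e-12)
})

test_that("population runs are reproducible and monotone in abundance", {
  spec <- population_spec(n = 24, seed = 11)
  p1 <- run_population(spec, ref_ps(), days = 2)
  p2 <- run_population(spec, ref_ps(), days = 2)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  ord <- order(p1$abundance)
  expect_true(all(diff(p1$cmax_plasma[ord]) < 1e-9))
  expect_true(all(diff(p1$vmax[ord]) > 0))
})

test_that("fraction above threshold is non-increasing in mean abundance", {
  fr <- vapply(c(0.85, 1, 1.2), function(mu) {
    pop <- run_population(population_spec(mu_x = mu, n = 60, seed = 3),
                          ref_ps(), days = 2, threshold = 8)
    attr(pop, "summary")$fraction_above
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("Wilcoxon pre/post comparison behaves at its boundaries", {
  pre <- c(2, 3, 4, 5, 6, 7, 8)
  expect_error(compare_pre_post(pre, pre), "degenerate-test")
  res <- compare_pre_post(pre = rnorm(20, 5), post = rnorm(20, 5) + 2)
  expect_lt(res$p_value, 0.05)
  # a pure positive shift over 20 pairs is maximally significant
  pre20 <- seq(1, 20)
  res2 <- compare_pre_post(pre20, pre20 + 0.5)
  expect_lt(res2$p_value, 0.05)
  expect_error(compare_pre_post(1:3, 2:4), "at least 6")
  expect_error(compare_pre_post(1:6, 1:7), "equal length")
})
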