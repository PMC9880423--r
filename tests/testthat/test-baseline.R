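# The two-stage linear baseline: packaged coefficient sets, affine
# evaluation, and OLS refitting against a normal-equations oracle.

test_that("packaged coefficients evaluate to the published intercepts", {
  pub <- baseline_coefficients("published")
  ref <- baseline_coefficients("refit")
  expect_equal(estimate_fresh_weight(0, pub), -0.2704)
  expect_equal(estimate_fresh_weight(0, ref), -0.3372)
  expect_equal(estimate_tiller_count(0, 0, pub), 5.26)
  expect_equal(estimate_tiller_count(0, 0, ref), 3.885)
})

test_that("affine evaluations match hand arithmetic", {
  pub <- baseline_coefficients("published")
  expect_equal(estimate_fresh_weight(10000, pub), 0.3755 - 0.2704)
  expect_equal(estimate_tiller_count(10, 1, pub), 2.2 - 2.19 + 5.26)
  expect_error(estimate_fresh_weight(-5, pub), ">= 0")
  expect_error(estimate_tiller_count(NaN, 1, pub), "finite")
})

test_that("the chained estimate is affine in area and aspect ratio", {
  co <- baseline_coefficients("published")
  A <- withr::with_seed(1, runif(20, 0, 5e4))
  H <- withr::with_seed(2, runif(20, 0.2, 4))
  chained <- estimate_tiller_count(estimate_fresh_weight(A, co), H, co)
  expanded <- co$tc_fw_coef * co$fw_slope * A +
    co$tc_fw_coef * co$fw_intercept + co$tc_hw_coef * H + co$tc_intercept
  expect_equal(chained, expanded)
})

test_that("noiseless planted data is recovered exactly", {
  A <- seq(100, 5000, length.out = 30)
  fw <- 0.002 * A - 0.1
  rr <- refit_fresh_weight(A, fw)
  expect_equal(rr$coefficients$fw_slope, 0.002, tolerance = 1e-9)
  expect_equal(rr$coefficients$fw_intercept, -0.1, tolerance = 1e-9)
  expect_equal(rr$r_squared, 1.0, tolerance = 1e-9)

  M <- withr::with_seed(3, runif(30, 0, 10))
  H <- withr::with_seed(4, runif(30, 0.5, 3))
  tc <- 0.2 * M - 1.0 * H + 4.0
  rt <- refit_tiller_model(M, H, tc)
  expect_equal(rt$coefficients$tc_fw_coef, 0.2, tolerance = 1e-9)
  expect_equal(rt$coefficients$tc_hw_coef, -1.0, tolerance = 1e-9)
  expect_equal(rt$coefficients$tc_intercept, 4.0, tolerance = 1e-9)
  expect_equal(rt$r_squared, 1.0, tolerance = 1e-9)
})

test_that("noisy recovery at n = 158 lands within three standard errors", {
  withr::with_seed(5, {
    A <- runif(158, 200, 4000)
    fw <- 0.002 * A - 0.1 + rnorm(158, 0, 0.01)
  })
  rr <- refit_fresh_weight(A, fw)
  se <- summary(lm(fw ~ A))$coefficients["A", "Std. Error"]
  expect_lte(abs(rr$coefficients$fw_slope - 0.002), 3 * se)
})

test_that("refits equal the normal-equations oracle", {
  withr::with_seed(6, {
    A <- runif(20, 0, 100)
    fw <- runif(20, -1, 5)
  })
  rr <- refit_fresh_weight(A, fw)
  X <- cbind(1, A)
  beta <- solve(t(X) %*% X, t(X) %*% fw)
  expect_equal(rr$coefficients$fw_intercept, beta[1], tolerance = 1e-8)
  expect_equal(rr$coefficients$fw_slope, beta[2], tolerance = 1e-8)

  withr::with_seed(7, {
    M <- runif(30, 0, 10); H <- runif(30, 0.2, 3); tc <- runif(30, 1, 12)
  })
  rt <- refit_tiller_model(M, H, tc)
  X2 <- cbind(1, M, H)
  b2 <- solve(t(X2) %*% X2, t(X2) %*% tc)
  expect_equal(rt$coefficients$tc_intercept, b2[1], tolerance = 1e-8)
  expect_equal(rt$coefficients$tc_fw_coef, b2[2], tolerance = 1e-8)
  expect_equal(rt$coefficients$tc_hw_coef, b2[3], tolerance = 1e-8)

  perm <- withr::with_seed(8, sample.int(30))
  rp <- refit_tiller_model(M[perm], H[perm], tc[perm])
  expect_equal(rp$coefficients, rt$coefficients)
})

test_that("degenerate designs raise singular-fit errors", {
  expect_error(refit_fresh_weight(rep(10, 5), 1:5), "zero area variance")
  expect_error(refit_fresh_weight(1:2, 1:2), "at least 3")
  M <- 1:10
  expect_error(refit_tiller_model(M, 2 * M, runif(10)), "collinear")
})
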