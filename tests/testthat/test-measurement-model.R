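# The error-model parameterization, its implied moment structure, and the
# closed-form validity metrics.

test_that("degenerate perfect instruments give the all-ones covariance", {
  p <- model_parameters(mu_T = 2, sigma2_T = 1)
  mo <- implied_moments(p, design_spec())
  expect_equal(unname(mo$cov), matrix(1, 9, 9))
  expect_equal(unname(mo$mean), rep(2, 9))
})

test_that("biomarker cross-occasion covariance is exactly sigma2_T", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    S <- implied_moments(p)$cov
    off <- S[7:9, 7:9][upper.tri(matrix(0, 3, 3))]
    expect_equal(off, rep(p$sigma2_T, 3))
  }
})

test_that("implied covariance is symmetric PSD for random valid parameters", {
  set.seed(12)
  for (i in 1:30) {
    S <- implied_moments(random_params())$cov
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("implied moments match a large simulated cohort (MC oracle)", {
  n <- 2e5
  sc <- simulation_scenario(n = n, seed = 301,
                            params = list(protein = p0_params()),
                            missing = no_missing)
  y <- cohort_wide(generate_cohort(sc), "protein")$y
  mo <- implied_moments(p0_params())
  emp_mean <- colMeans(y)
  emp_cov <- stats::cov(y)
  se_mean <- sqrt(diag(mo$cov) / n)
  expect_true(all(abs(emp_mean - mo$mean) < 3 * se_mean))
  se_cov <- sqrt((outer(diag(mo$cov), diag(mo$cov)) + mo$cov^2) / n)
  expect_true(all(abs(emp_cov - mo$cov) < 3 * se_cov))
})

test_that("parameter validation names the violated invariant", {
  expect_error(model_parameters(sigma2_r = -1), "sigma2_r")
  expect_error(model_parameters(rho_rs = 1.2), "rho_rs")
  expect_error(model_parameters(beta_Q1 = Inf), "beta_Q1")
  expect_error(model_parameters(mu_Q = c(0.5, 0, 0)), "identification")
  expect_error(model_parameters(mu_Q = c(0, 0)), "equal length")
  expect_warning(model_parameters(beta_Q1 = -0.2), "slope")
  expect_error(design_spec(n_occasions = 1), "identifiability")
})

test_that("attenuation factor matches its closed form and a regression oracle", {
  p <- model_parameters(sigma2_T = 1, beta_Q1 = 1, sigma2_r = 1,
                        sigma2_eps = 2)
  expect_equal(attenuation_factor(p, "webq", 1L), 0.25)
  expect_equal(attenuation_factor(p, "webq", 2L), 1 / 3)

  # oracle: slope of regressing true intake on the k-administration mean
  n <- 5e5
  sc <- simulation_scenario(n = n, seed = 302, params = list(x = p),
                            missing = no_missing)
  co <- generate_cohort(sc)
  y <- cohort_wide(co, "x")$y
  Tt <- attr(co, "truth")$T
  for (k in 1:2) {
    qbar <- rowMeans(y[, seq_len(k), drop = FALSE])
    sl <- stats::coef(stats::lm(Tt ~ qbar))[2]
    se <- sqrt(diag(stats::vcov(stats::lm(Tt ~ qbar)))[2])
    expect_lt(abs(sl - attenuation_factor(p, "webq", k)), 3 * se)
  }
})

test_that("correlation with truth matches closed form and empirical oracle", {
  p <- model_parameters(sigma2_T = 1, beta_Q1 = 1, sigma2_r = 1,
                        sigma2_eps = 2)
  expect_equal(correlation_with_truth(p, "webq", 1L), 0.5)
  expect_equal(correlation_with_truth(p, "webq", 2L), 1 / sqrt(3))

  n <- 5e5
  sc <- simulation_scenario(n = n, seed = 303, params = list(x = p),
                            missing = no_missing)
  co <- generate_cohort(sc)
  y <- cohort_wide(co, "x")$y
  Tt <- attr(co, "truth")$T
  for (k in 1:2) {
    r_emp <- stats::cor(Tt, rowMeans(y[, seq_len(k), drop = FALSE]))
    # Fisher-z standard error
    expect_lt(abs(atanh(r_emp) - atanh(correlation_with_truth(p, "webq", k))),
              3 / sqrt(n - 3))
  }
})

test_that("error-free instrument has lambda_k = rho_k = 1 for all k", {
  p <- model_parameters(sigma2_T = 0.5, beta_Q1 = 1, sigma2_v = 0.1)
  expect_equal(attenuation_factor(p, "webq", c(1L, 3L, 10L)), rep(1, 3))
  expect_equal(correlation_with_truth(p, "webq", c(1L, 3L, 10L)), rep(1, 3))
})

test_that("metric argument errors are raised", {
  p <- tiny_params()
  expect_error(attenuation_factor(p, "webq", 0L), "k must be")
  expect_error(attenuation_factor(p, "webq", 1.5), "k must be")
  expect_error(attenuation_factor(p, "biomarker", 1L))
})

test_that("closed-form extrapolation reproduces published repeat-administration cells", {
  # protein rows
  tab <- extrapolate_from_pair(extrapolation_input(0.27, 0.37, 0.40), 1:5)
  expect_equal(round_half_up(tab$lambda, 2), c(0.27, 0.37, 0.42, 0.45, 0.48))
  expect_equal(round_half_up(tab$rho, 2), c(0.40, 0.47, 0.50, 0.52, 0.53))
  # potassium k = 3
  tab <- extrapolate_from_pair(extrapolation_input(0.31, 0.42, 0.34), 3L)
  expect_equal(round_half_up(tab$lambda, 2), 0.48)
  expect_equal(round_half_up(tab$rho, 2), 0.42)
})

test_that("extrapolation with lambda2 = lambda1 is the identity (x = 0)", {
  tab <- extrapolate_from_pair(extrapolation_input(0.5, 0.5, 0.5),
                               c(1L, 7L, 99L))
  expect_equal(tab$lambda, rep(0.5, 3))
  expect_equal(tab$rho, rep(0.5, 3))
})

test_that("infeasible attenuation ratios are rejected", {
  expect_error(extrapolation_input(0.2, 0.15, 0.3), "lambda2 < lambda1")
  expect_error(extrapolation_input(0.2, 0.4, 0.3), "infeasible ratio")
  expect_error(extrapolation_input(0.2, 0.45, 0.3), "infeasible ratio")
  expect_error(extrapolation_input(0, 0.1, 0.3), "lambda1")
  expect_error(extrapolation_input(0.2, 0.25, 1.2), "rho1")
})

test_that("metric identities hold to machine precision for random parameters", {
  set.seed(13)
  ks <- 1:8
  for (i in 1:20) {
    p <- random_params()
    lam <- attenuation_factor(p, "webq", ks)
    rho <- correlation_with_truth(p, "webq", ks)
    # (rho_k / rho_1)^2 = lambda_k / lambda_1
    expect_equal((rho / rho[1])^2, lam / lam[1], tolerance = 1e-12)
    # strictly increasing whenever within-person variance is positive
    expect_true(all(diff(lam) > 0) && all(diff(rho) > 0))
    # finite limits
    x <- p$sigma2_eps / (p$beta_Q1^2 * p$sigma2_T + p$sigma2_r)
    expect_lt(max(lam), lam[1] * (1 + x) + 1e-12)
    expect_lt(max(rho), rho[1] * sqrt(1 + x) + 1e-12)
    # closed-form extrapolation agrees with the direct formulas (round trip)
    tab <- extrapolate_from_pair(
      extrapolation_input(lam[1], lam[2], rho[1]), ks)
    expect_equal(tab$lambda, lam, tolerance = 1e-12)
    expect_equal(tab$rho, rho, tolerance = 1e-12)
  }
})

test_that("parameter serialization round-trips losslessly", {
  set.seed(14)
  p <- random_params()
  q <- read_parameters(text = write_parameters(p))
  expect_equal(unclass(p), unclass(q), tolerance = 0)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_parameters(p, tmp)
  expect_equal(unclass(read_parameters(tmp)), unclass(p), tolerance = 0)
})
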