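# FIML likelihood, maximum likelihood fitting, uncertainty, subgroups.

# Independent multivariate-normal log-density (solve/determinant route,
# written without reference to the package internals).
mvn_logdens <- function(y, mu, S) {
  d <- y - mu
  -0.5 * (length(y) * log(2 * pi) + determinant(S)$modulus[1] +
            drop(t(d) %*% solve(S) %*% d))
}

test_that("FIML equals the complete-data multivariate normal likelihood", {
  sc <- protein_scenario(seed = 401, n = 60, missing = no_missing)
  co <- generate_cohort(sc)
  p <- p0_params()
  mo <- implied_moments(p)
  y <- cohort_wide(co, "protein")$y
  direct <- sum(apply(y, 1L, mvn_logdens, mu = mo$mean, S = mo$cov))
  expect_equal(log_likelihood(p, co), direct, tolerance = 1e-10)
})

test_that("FIML equals brute-force marginalization on a toy with one missing cell", {
  p <- tiny_params()
  mo <- implied_moments(p)
  set.seed(402)
  y <- MASS_free_rmvnorm(2L, mo$mean, mo$cov)
  y[2L, 5L] <- NA   # participant 2 misses the occasion-2 recall
  # oracle for participant 2: numerically integrate the full 9-dim density
  # over the missing coordinate
  dens2 <- stats::integrate(function(m) {
    vapply(m, function(mi) {
      yy <- y[2L, ]; yy[5L] <- mi
      exp(mvn_logdens(yy, mo$mean, mo$cov))
    }, numeric(1L))
  }, lower = -30, upper = 30, rel.tol = 1e-12)$value
  oracle <- mvn_logdens(y[1L, ], mo$mean, mo$cov) + log(dens2)
  expect_equal(log_likelihood(p, y), oracle, tolerance = 1e-8)
})

test_that("the truth outscores perturbed parameters on a large cohort", {
  sc <- protein_scenario(seed = 403, n = 2000)
  co <- generate_cohort(sc)
  p <- p0_params()
  ll_true <- log_likelihood(p, co)
  pert <- p
  pert$beta_Q1 <- p$beta_Q1 * 1.3
  pert$sigma2_T <- p$sigma2_T * 0.7
  expect_gt(ll_true, log_likelihood(pert, co))
})

test_that("likelihood input contracts are enforced", {
  sc <- protein_scenario(seed = 404, n = 20)
  co <- generate_cohort(sc)
  raw <- co
  attr(raw, "log_transformed") <- FALSE
  expect_error(log_likelihood(p0_params(), raw), "log-transformed")
  y <- cohort_wide(co, "protein")$y
  y[3L, ] <- NA
  expect_warning(log_likelihood(p0_params(), y), "no observed values")
})

test_that("compiled and reference likelihood/gradient implementations agree", {
  sc <- protein_scenario(seed = 405, n = 80)
  co <- generate_cohort(sc)
  design <- design_spec()
  y <- cohort_wide(co, "protein")$y
  pats <- dietvalid:::pattern_stats(y)
  fp <- dietvalid:::flatten_patterns(pats)
  set.seed(406)
  for (i in 1:5) {
    p <- random_params()
    th <- params_to_theta(p, design)
    ref <- dietvalid:::fiml_core(p, pats, design, gradient = TRUE)
    gref <- dietvalid:::fiml_grad_theta(p, ref, design, "free")
    cpp <- dietvalid:::fiml_eval_flat(
      dietvalid:::theta_to_natural(th, 3L, "free"), 3L, TRUE, fp, TRUE)
    expect_equal(cpp$loglik, ref$loglik, tolerance = 1e-10)
    expect_equal(cpp$grad, unname(gref), tolerance = 1e-8)
  }
})

test_that("near-noiseless cohorts are fitted with lambda_1 = rho_1 = 1", {
  p <- model_parameters(mu_T = 4, sigma2_T = 0.25, beta_Q1 = 1, beta_F1 = 1,
                        sigma2_r = 1e-6, sigma2_s = 1e-6,
                        sigma2_eps = 1e-6, sigma2_u = 1e-6, sigma2_v = 1e-6)
  sc <- simulation_scenario(n = 200, seed = 407, params = list(x = p),
                            missing = no_missing)
  f <- fit_model(generate_cohort(sc), nutrient = "x")
  expect_equal(attenuation_factor(f$params, "webq", 1L), 1, tolerance = 1e-3)
  expect_equal(correlation_with_truth(f$params, "webq", 1L), 1,
               tolerance = 1e-3)
  expect_true(length(f$boundary) > 0)  # variances flagged at the boundary
})

test_that("parameters are recovered within 3 SE on a seeded n = 2000 cohort", {
  sc <- protein_scenario(seed = 408, n = 2000)
  f <- fit_model(generate_cohort(sc), nutrient = "protein")
  expect_true(f$converged)
  expect_false(is.null(f$vcov))
  p <- p0_params()
  th_true <- params_to_theta(p, design_spec())
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(f$theta - th_true) < 3 * se))
  # and the derived attenuation factor is close to its generating value
  expect_lt(abs(attenuation_factor(f$params, "webq", 1L) -
                  attenuation_factor(p, "webq", 1L)), 0.05)
})

test_that("ML attenuation agrees with the method-of-moments estimate", {
  sc <- protein_scenario(seed = 409, n = 20000, missing = no_missing)
  co <- generate_cohort(sc)
  f <- fit_model(co, nutrient = "protein", compute_vcov = FALSE)
  y <- cohort_wide(co, "protein")$y
  mom <- stats::cov(y[, 1], y[, 7]) / stats::var(y[, 1])
  expect_lt(abs(attenuation_factor(f$params, "webq", 1L) - mom), 0.005)
})

test_that("log-likelihood is invariant to participant and occasion order", {
  sc <- protein_scenario(seed = 410, n = 120)
  co <- generate_cohort(sc)
  p <- p0_params()
  y <- cohort_wide(co, "protein")$y
  ll <- log_likelihood(p, y)
  set.seed(411)
  for (i in 1:5)
    expect_equal(log_likelihood(p, y[sample(nrow(y)), ]), ll,
                 tolerance = 1e-10)
  # occasions are exchangeable when the model carries no drift
  p0 <- p
  p0$mu_Q <- p0$mu_F <- p0$mu_M <- numeric(3)
  perm <- c(3, 1, 2)
  yperm <- y[, c(perm, 3 + perm, 6 + perm)]
  colnames(yperm) <- colnames(y)
  expect_equal(log_likelihood(p0, yperm), log_likelihood(p0, y),
               tolerance = 1e-10)
})

test_that("fitting is deterministic and improves on its initialization", {
  sc <- protein_scenario(seed = 412)
  co <- generate_cohort(sc)
  f1 <- fit_model(co, nutrient = "protein")
  f2 <- fit_model(co, nutrient = "protein")
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
  expect_gte(f1$loglik, log_likelihood(f1$init, co))
})

test_that("listwise deletion and multi-start options run and agree broadly", {
  sc <- protein_scenario(seed = 413)
  co <- generate_cohort(sc)
  f <- fit_model(co, nutrient = "protein")
  fl <- fit_model(co, nutrient = "protein", listwise = TRUE)
  expect_lt(fl$n, f$n)  # complete cases only
  expect_lt(abs(attenuation_factor(f$params, "webq", 1) -
                  attenuation_factor(fl$params, "webq", 1)), 0.15)
  fm <- fit_model(co, nutrient = "protein", n_starts = 3L, start_seed = 9L)
  expect_equal(fm$loglik, f$loglik, tolerance = 1e-6)
})

test_that("fit results export to structured JSON with derived metrics", {
  sc <- protein_scenario(seed = 419, n = 100)
  f <- fit_model(generate_cohort(sc), nutrient = "protein")
  js <- jsonlite::fromJSON(write_fit_result(f, K = 3L))
  expect_equal(js$parameters$beta_Q1, f$params$beta_Q1)
  expect_equal(js$n, f$n)
  expect_true(js$converged)
  expect_equal(js$derived_metrics$lambda[js$derived_metrics$instrument ==
                                           "webq"],
               unname(attenuation_factor(f$params, "webq", 1:3)))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_fit_result(f, tmp)
  expect_true(file.exists(tmp))
})

test_that("identifiability guard rejects cohorts without biomarker replicates", {
  sc <- protein_scenario(seed = 414, n = 40, missing = no_missing)
  co <- generate_cohort(sc)
  d <- co[!(co$instrument == "biomarker" & co$occasion > 1L), ]
  co2 <- cohort_measurements(d, log_transformed = TRUE)
  expect_error(fit_model(co2, nutrient = "protein"), "biomarker")
})

test_that("bootstrap and delta intervals bracket the estimate and overlap", {
  sc <- protein_scenario(seed = 415)
  co <- generate_cohort(sc)
  f <- fit_model(co, nutrient = "protein")
  mu <- metric_uncertainty(f, "lambda", "webq", k = 1L, n_boot = 120L,
                           seed = 5L)
  expect_lt(mu$ci[1], mu$estimate)
  expect_gt(mu$ci[2], mu$estimate)
  expect_lt(max(mu$ci[1], mu$ci_delta[1]), min(mu$ci[2], mu$ci_delta[2]))
  expect_lte(mu$n_boot_failed, 0.2 * 120)
  # duplicating every participant shrinks resampling variability
  big <- do.call(rbind, lapply(1:8, function(r) {
    d <- as.data.frame(co)
    d$participant_id <- paste0(d$participant_id, "_", r)
    d
  }))
  fbig <- fit_model(cohort_measurements(big, TRUE), nutrient = "protein",
                    compute_vcov = FALSE)
  mubig <- metric_uncertainty(fbig, "lambda", "webq", k = 1L, n_boot = 120L,
                              seed = 5L)
  expect_lt(diff(mubig$ci), 0.6 * diff(mu$ci))
})

test_that("subgroup fits partition the cohort and respect the size floor", {
  sc <- simulation_scenario(n = 200, seed = 416,
                            params = default_parameters()["protein"])
  co <- generate_cohort(sc)
  sg <- fit_subgroups(co, "sex", nutrient = "protein", compute_vcov = FALSE)
  expect_setequal(names(sg), c("men", "women"))
  expect_equal(sum(vapply(sg, function(f) f$n, 0L)),
               length(unique(co$participant_id)))
  # homogeneous generator: strata agree within sampling error
  lam <- vapply(sg, function(f) attenuation_factor(f$params, "webq", 1L), 0)
  expect_lt(abs(diff(lam)), 0.25)
  # an understrength stratum is skipped with a warning
  d <- as.data.frame(co)
  d$sex <- ifelse(d$participant_id %in% unique(d$participant_id)[1:5], 1, 0)
  co2 <- cohort_measurements(d, TRUE)
  expect_warning(sg2 <- fit_subgroups(co2, "sex", nutrient = "protein",
                                      compute_vcov = FALSE), "skipped")
  expect_named(sg2, "men")
})

test_that("a stratum with more person-specific bias shows lower attenuation", {
  pars <- default_parameters()["protein"]
  noisy <- pars
  noisy$protein$sigma2_r <- noisy$protein$sigma2_r * 6
  co_lo <- generate_cohort(simulation_scenario(n = 300, seed = 417,
                                               params = pars))
  co_hi <- generate_cohort(simulation_scenario(n = 300, seed = 418,
                                               params = noisy))
  d_lo <- as.data.frame(co_lo); d_lo$sex <- 0
  d_hi <- as.data.frame(co_hi); d_hi$sex <- 1
  d_hi$participant_id <- paste0("H", d_hi$participant_id)
  co <- cohort_measurements(rbind(d_lo, d_hi), TRUE)
  sg <- fit_subgroups(co, "sex", nutrient = "protein", compute_vcov = FALSE)
  expect_lt(attenuation_factor(sg$women$params, "webq", 1L),
            attenuation_factor(sg$men$params, "webq", 1L))
})
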