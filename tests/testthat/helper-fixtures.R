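# Shared fixtures: small parameter sets and scenario builders used across
# the test files.  Everything is generated in code; no stored data.

# Simple instructional parameter set: unit latent variance, unit slope,
# person-specific bias variance 1, within-person variance 2 for the webq.
tiny_params <- function(...) {
  model_parameters(mu_T = 0, sigma2_T = 1, beta_Q1 = 1, beta_F1 = 1,
                   sigma2_r = 1, sigma2_s = 0.5, rho_rs = 0.2,
                   sigma2_eps = 2, sigma2_u = 1, sigma2_v = 0.5, ...)
}

# The fixed numeric set used for Monte-Carlo oracles: the protein member of
# the default generating parameters.
p0_params <- function() default_parameters()$protein

# A scenario small enough for fast fitting tests.
quick_scenario <- function(seed, n = 160L, ...) {
  simulation_scenario(n = n, seed = seed, ...)
}

# Draw a random valid parameter set (for property-style loops).
random_params <- function() {
  model_parameters(
    mu_T = stats::runif(1, -1, 5),
    sigma2_T = stats::runif(1, 0.02, 1),
    beta_Q0 = stats::runif(1, -1, 1), beta_F0 = stats::runif(1, -1, 1),
    beta_Q1 = stats::runif(1, 0.2, 1.5), beta_F1 = stats::runif(1, 0.2, 1.5),
    sigma2_r = stats::runif(1, 0.001, 0.5),
    sigma2_s = stats::runif(1, 0.001, 0.5),
    rho_rs = stats::runif(1, -0.9, 0.9),
    sigma2_eps = stats::runif(1, 0.001, 0.8),
    sigma2_u = stats::runif(1, 0.001, 0.8),
    sigma2_v = stats::runif(1, 0.001, 0.5),
    mu_Q = c(0, stats::runif(2, -0.1, 0.1)),
    mu_F = c(0, stats::runif(2, -0.1, 0.1)),
    mu_M = c(0, stats::runif(2, -0.1, 0.1)))
}

# Scenario with a single nutrient (protein) to keep fitting tests fast.
protein_scenario <- function(seed, n = 160L, missing = NULL) {
  args <- list(n = n, seed = seed,
               params = default_parameters()["protein"])
  if (!is.null(missing)) args$missing <- missing
  do.call(simulation_scenario, args)
}

no_missing <- list(webq = rep(0, 3), recall = rep(0, 3),
                   biomarker = rep(0, 3))

# small multivariate normal sampler independent of the package's generator
MASS_free_rmvnorm <- function(n, mu, S) {
  L <- chol(S)
  matrix(stats::rnorm(n * length(mu)), n) %*% L +
    matrix(mu, n, length(mu), byrow = TRUE)
}
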