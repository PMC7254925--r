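# Maximum likelihood fitting, bootstrap/delta uncertainty, subgroup fits.

# Deterministic method-of-moments initialization from pairwise-complete
# sample moments.  Cheap and close enough to the optimum that BFGS converges
# in a few dozen iterations; variance components are floored at 1e-4.
moments_init <- function(y, design) {
  J <- design$n_occasions
  Qi <- seq_len(J); Fi <- J + Qi; Mi <- 2L * J + Qi
  mns <- colMeans(y, na.rm = TRUE)
  mns[!is.finite(mns)] <- 0
  C <- suppressWarnings(stats::cov(y, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  offmean <- function(M) mean(M[upper.tri(M)])
  flo <- function(v, lo = 1e-4) max(v, lo)

  s2T <- flo(offmean(C[Mi, Mi]))
  a <- mean(C[Qi, Mi]) / s2T
  b <- mean(C[Fi, Mi]) / s2T
  if (!is.finite(a) || abs(a) < 1e-3) a <- 1
  if (!is.finite(b) || abs(b) < 1e-3) b <- 1
  s2r <- flo(offmean(C[Qi, Qi]) - a^2 * s2T)
  s2s <- flo(offmean(C[Fi, Fi]) - b^2 * s2T)
  s2e <- flo(mean(diag(C)[Qi]) - a^2 * s2T - s2r)
  s2u <- flo(mean(diag(C)[Fi]) - b^2 * s2T - s2s)
  s2v <- flo(mean(diag(C)[Mi]) - s2T)
  rho <- (mean(C[Qi, Fi]) - a * b * s2T) / sqrt(s2r * s2s)
  rho <- min(max(ifelse(is.finite(rho), rho, 0), -0.95), 0.95)

  mu_T <- mns[Mi[1L]]
  mu_M <- mns[Mi] - mu_T
  beta_Q0 <- mns[Qi[1L]] - a * mu_T
  beta_F0 <- mns[Fi[1L]] - b * mu_T
  mu_Q <- mns[Qi] - beta_Q0 - a * mu_T
  mu_F <- mns[Fi] - beta_F0 - b * mu_T
  mu_Q[1L] <- mu_F[1L] <- mu_M[1L] <- 0
  suppressWarnings(model_parameters(
    mu_T = mu_T, sigma2_T = s2T, beta_Q0 = beta_Q0, beta_F0 = beta_F0,
    beta_Q1 = a, beta_F1 = b, sigma2_r = s2r, sigma2_s = s2s, rho_rs = rho,
    sigma2_eps = s2e, sigma2_u = s2u, sigma2_v = s2v,
    mu_Q = mu_Q, mu_F = mu_F, mu_M = mu_M))
}

# theta (unconstrained scale) -> natural-scale parameter vector in the same
# order, as consumed by the compiled likelihood kernel.
theta_to_natural <- function(theta, J, drift) {
  nfix <- 3L + if (drift == "free") 3L * (J - 1L) else 0L
  nat <- theta
  v <- nfix + 2L + c(1L, 2L, 3L, 5L, 6L, 7L)   # the six log-variances
  nat[v] <- exp(theta[v])
  nat[nfix + 6L] <- tanh(theta[nfix + 6L])     # rho_rs
  nat
}

# Optimize the FIML likelihood over pattern statistics, starting from theta0.
# BFGS with the compiled joint likelihood/gradient evaluation (cached so the
# fn and gr callbacks at the same point cost one kernel call).
# Returns optim-style list plus the fitted natural-scale parameters.
fit_patterns <- function(patterns, design, theta0, drift = "free",
                         maxit = 500L, reltol = 1e-12) {
  J <- design$n_occasions
  drift_free <- drift == "free"
  fp <- flatten_patterns(patterns)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    res <- fiml_eval_flat(theta_to_natural(theta, J, drift), J, drift_free,
                          fp, TRUE)
    val <- if (!is.finite(res$loglik)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else {
      list(value = -res$loglik, grad = -res$grad)
    }
    cache$key <- key; cache$val <- val
    val
  }
  opt <- stats::optim(theta0,
                      fn = function(th) eval_at(th)$value,
                      gr = function(th) eval_at(th)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  theta <- opt$par
  names(theta) <- theta_names(J, drift)
  grad <- eval_at(theta)$grad
  list(theta = theta, loglik = -opt$value, convergence = opt$convergence,
       counts = opt$counts, grad_norm = sqrt(sum(grad^2)),
       params = suppressWarnings(theta_to_params(theta, design, drift)))
}

#' Fit the three-instrument measurement error model by maximum likelihood
#'
#' Full-information maximum likelihood over the observed measurement
#' patterns (missing-at-random), started from a deterministic
#' method-of-moments initialization and optimized by BFGS on the
#' unconstrained parameter scale.  Identical inputs always produce
#' identical fits.
#'
#' @param cohort A log-transformed [cohort_measurements()] object.
#' @param design A [design_spec()].
#' @param nutrient Nutrient to fit when the cohort holds several.
#' @param drift `"free"` (default): occasion intercepts estimated with
#'   occasion 1 anchored at 0; `"none"`: no drift terms.
#' @param listwise If `TRUE`, participants with any missing cell are dropped
#'   (complete-case comparison mode) instead of the FIML default.
#' @param n_starts Number of optimizer starts.  The first start is always
#'   the method-of-moments initialization; additional starts jitter it with
#'   seeded Gaussian noise (robustness mode), and the best optimum is kept.
#' @param start_seed Seed for the jittered extra starts.
#' @param maxit,reltol Optimizer control: iteration cap and relative
#'   convergence tolerance on the objective.
#' @param compute_vcov If `TRUE` (default), the observed-information
#'   covariance of the transformed parameters is computed from a
#'   finite-difference Jacobian of the analytic gradient.
#' @return An object of class `fit_result` with elements `params`
#'   (fitted [model_parameters()]), `theta` (transformed estimates), `vcov`
#'   (their observed-information covariance), `loglik`, `converged`,
#'   `boundary` (variance components at the lower boundary), `n`,
#'   `missingness` (pattern summary), and the data needed for bootstrap
#'   resampling.  Derived metrics come from [attenuation_factor()] /
#'   [correlation_with_truth()] applied to `$params`, or see
#'   [metric_uncertainty()].
#' @export
fit_model <- function(cohort, design = design_spec(), nutrient = NULL,
                      drift = c("free", "none"), listwise = FALSE,
                      n_starts = 1L, start_seed = 1L,
                      maxit = 500L, reltol = 1e-12, compute_vcov = TRUE) {
  drift <- match.arg(drift)
  y <- cohort_matrix(cohort, nutrient, design)
  if (listwise) y <- y[stats::complete.cases(y), , drop = FALSE]
  patterns <- pattern_stats(y)
  if (!any(vapply(patterns, function(p)
        sum(p$obs > 2L * design$n_occasions) >= 2L, logical(1L))))
    stop("no participant has two or more biomarker measurements: ",
         "within- vs between-person biomarker variance is unidentified",
         call. = FALSE)

  init <- moments_init(y, design)
  theta0 <- params_to_theta(init, design, drift)
  best <- fit_patterns(patterns, design, theta0, drift, maxit, reltol)
  if (n_starts > 1L) {
    set.seed(as.integer(start_seed))
    for (s in seq_len(n_starts - 1L)) {
      th <- theta0 + stats::rnorm(length(theta0), sd = 0.2)
      cand <- fit_patterns(patterns, design, th, drift, maxit, reltol)
      if (cand$convergence == 0L && cand$loglik > best$loglik) best <- cand
    }
  }
  ll_init <- fiml_core(init, patterns, design)$loglik
  if (is.finite(ll_init) && best$loglik < ll_init - 1e-8)
    warning("optimizer ended below its initialization; fit is suspect",
            call. = FALSE)

  vc <- NULL
  if (compute_vcov) {
    fp <- flatten_patterns(patterns)
    H <- grad_jacobian(function(th) {
      res <- fiml_eval_flat(theta_to_natural(th, design$n_occasions, drift),
                            design$n_occasions, drift == "free", fp, TRUE)
      -res$grad
    }, best$theta)
    H <- (H + t(H)) / 2
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      dimnames(vc) <- list(names(best$theta), names(best$theta))
      ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev))) vc <- NULL
    }
  }
  vars <- unlist(best$params[c("sigma2_T", "sigma2_r", "sigma2_s",
                               "sigma2_eps", "sigma2_u", "sigma2_v")])
  pat_tab <- vapply(patterns, function(p) p$n, integer(1L))
  structure(list(
    params = best$params, theta = best$theta, vcov = vc,
    loglik = best$loglik, converged = best$convergence == 0L,
    grad_norm = best$grad_norm,
    boundary = names(vars)[vars <= 2e-4],
    n = attr(patterns, "n_total"),
    missingness = data.frame(pattern = names(pat_tab), n = unname(pat_tab)),
    init = init, y = y, design = design, drift = drift,
    nutrient = if (is.null(nutrient) && !is.matrix(cohort))
      unique(cohort$nutrient) else nutrient
  ), class = "fit_result")
}

# Finite-difference Jacobian of a gradient function (central differences);
# used for the observed information so no extra dependency is needed.
grad_jacobian <- function(gr, theta, eps = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- eps * max(1, abs(theta[i]))
    H[i, ] <- (gr(theta + e) - gr(theta - e)) / (2 * e[i])
  }
  H
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Measurement-model ML fit: n = %d, logLik = %.4f, %s\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (length(x$boundary))
    cat("  boundary variance component(s):",
        paste(x$boundary, collapse = ", "), "\n")
  print(x$params)
  lam <- attenuation_factor(x$params, "webq", 1L)
  rho <- correlation_with_truth(x$params, "webq", 1L)
  cat(sprintf("  webq: lambda_1 = %.3f, rho_1 = %.3f\n", lam, rho))
  invisible(x)
}

#' Export a fit result as structured JSON
#'
#' Writes the fitted parameters, the observed-information covariance of the
#' transformed parameters, convergence diagnostics, and the derived
#' attenuation factors and correlations with true intake for `k = 1..K`
#' administrations of both self-report instruments.
#'
#' @param fit A [fit_model()] result.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @param K Largest repeat count for the derived metrics.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_fit_result <- function(fit, path = NULL, K = 5L) {
  stopifnot(inherits(fit, "fit_result"))
  ks <- seq_len(K)
  metrics <- do.call(rbind, lapply(c("webq", "recall"), function(ins)
    data.frame(instrument = ins, k = ks,
               lambda = attenuation_factor(fit$params, ins, ks),
               rho = correlation_with_truth(fit$params, ins, ks))))
  obj <- list(
    nutrient = fit$nutrient,
    parameters = unclass(fit$params),
    theta = as.list(fit$theta),
    vcov = fit$vcov,
    loglik = fit$loglik,
    converged = fit$converged,
    boundary = fit$boundary,
    n = fit$n,
    missingness = fit$missingness,
    derived_metrics = metrics)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", matrix = "rowmajor",
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Bootstrap and delta-method intervals for derived validity metrics
#'
#' Primary method: nonparametric bootstrap over participants — resample
#' participants with replacement, refit the model (warm-started at the
#' original optimum), recompute the metric, and take percentile limits.
#' A delta-method interval from the observed-information covariance is
#' reported alongside.  Replicates whose refit does not converge are
#' dropped and counted; more than 20% dropped triggers a warning.
#'
#' @param fit A converged [fit_model()] result.
#' @param metric `"lambda"` (attenuation factor) or `"rho"` (correlation
#'   with true intake).
#' @param instrument `"webq"` or `"recall"`.
#' @param k Repeat count the metric is evaluated at.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for resampling (mandatory for reproducibility).
#' @param level Confidence level.
#' @return A list with `estimate`, `ci` (bootstrap percentile), `ci_delta`,
#'   `se_delta`, `n_boot_used`, `n_boot_failed`, and the bootstrap draws.
#' @export
metric_uncertainty <- function(fit, metric = c("lambda", "rho"),
                               instrument = c("webq", "recall"), k = 1L,
                               n_boot = 500L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged)
    stop("uncertainty is only reported for converged fits", call. = FALSE)
  metric <- match.arg(metric)
  instrument <- match.arg(instrument)
  k <- check_k(k)
  fmetric <- function(par) {
    if (metric == "lambda") attenuation_factor(par, instrument, k)
    else correlation_with_truth(par, instrument, k)
  }
  est <- fmetric(fit$params)
  alpha <- (1 - level) / 2

  # delta method on the transformed scale
  se_delta <- ci_delta <- NULL
  if (!is.null(fit$vcov)) {
    g <- num_grad(function(th) fmetric(
      suppressWarnings(theta_to_params(th, fit$design, fit$drift))), fit$theta)
    se_delta <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
    ci_delta <- est + stats::qnorm(c(alpha, 1 - alpha)) * se_delta
  }

  set.seed(as.integer(seed))
  n <- nrow(fit$y)
  draws <- rep(NA_real_, n_boot)
  failed <- 0L
  for (bidx in seq_len(n_boot)) {
    yb <- fit$y[sample.int(n, n, replace = TRUE), , drop = FALSE]
    pats <- suppressWarnings(pattern_stats(yb, warn_empty = FALSE))
    fb <- tryCatch(
      fit_patterns(pats, fit$design, fit$theta, fit$drift, maxit = 200L),
      error = function(e) NULL)
    if (is.null(fb) || fb$convergence != 0L) { failed <- failed + 1L; next }
    draws[bidx] <- fmetric(fb$params)
  }
  ok <- draws[!is.na(draws)]
  if (failed > 0.2 * n_boot)
    warning(failed, " of ", n_boot, " bootstrap replicates failed to ",
            "converge; percentile interval may be unreliable", call. = FALSE)
  ci <- if (length(ok)) unname(stats::quantile(ok, c(alpha, 1 - alpha),
                                               type = 7))
        else c(NA_real_, NA_real_)
  list(metric = metric, instrument = instrument, k = k,
       estimate = unname(est), ci = ci, ci_delta = unname(ci_delta),
       se_delta = se_delta, n_boot_used = length(ok), n_boot_failed = failed,
       draws = ok)
}

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1L))
}

#' Fit the measurement model separately within participant strata
#'
#' Strata follow the usual validation-study subgroup analyses: sex
#' (man/woman), age dichotomized at 40 years, or BMI dichotomized at 25.
#' Each stratum is fitted independently; strata with fewer participants
#' than `min_n` are skipped with a warning.
#'
#' @param cohort A log-transformed [cohort_measurements()] object.
#' @param stratifier `"sex"`, `"age"` or `"bmi"`.
#' @param age_cut,bmi_cut Cut points for the age and BMI strata.
#' @param min_n Minimum participants required to fit a stratum.
#' @param ... Passed to [fit_model()].
#' @return Named list of `fit_result` objects (skipped strata are absent).
#' @export
fit_subgroups <- function(cohort, stratifier = c("sex", "age", "bmi"),
                          age_cut = 40, bmi_cut = 25, min_n = 20L, ...) {
  stopifnot(inherits(cohort, "cohort_measurements"))
  stratifier <- match.arg(stratifier)
  first <- cohort[!duplicated(cohort$participant_id), ]
  grp <- switch(stratifier,
    sex = ifelse(first$sex == 1, "women", "men"),
    age = ifelse(first$age >= age_cut,
                 paste0("age>=", age_cut), paste0("age<", age_cut)),
    bmi = ifelse(first$bmi >= bmi_cut,
                 paste0("bmi>=", bmi_cut), paste0("bmi<", bmi_cut)))
  out <- list()
  for (g in sort(unique(stats::na.omit(grp)))) {
    ids <- first$participant_id[!is.na(grp) & grp == g]
    if (length(ids) < min_n) {
      warning("stratum '", g, "' has ", length(ids), " participants ",
              "(< ", min_n, "); skipped", call. = FALSE)
      next
    }
    sub <- cohort_measurements(
      cohort[cohort$participant_id %in% ids, , drop = FALSE],
      log_transformed = attr(cohort, "log_transformed"))
    out[[g]] <- fit_model(sub, ...)
  }
  if (!length(out)) warning("no stratum met the minimum size", call. = FALSE)
  out
}
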