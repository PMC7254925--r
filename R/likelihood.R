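# Full-information maximum likelihood machinery.
#
# Participants are grouped by missingness pattern; each pattern contributes
# through its sufficient statistics (n, mean, scatter), so one likelihood or
# gradient evaluation costs O(#patterns * (3J)^3) regardless of n.  The
# gradient is analytic (chain rule through the structured mean/covariance),
# which is what keeps the bootstrap-heavy analyses tractable in pure R.

# --- unconstrained parameterization -----------------------------------------
# theta = (mu_T, beta_Q0, beta_F0, mu_Q[2..J], mu_F[2..J], mu_M[2..J],
#          beta_Q1, beta_F1, log sigma2_T, log sigma2_r, log sigma2_s,
#          atanh rho_rs, log sigma2_eps, log sigma2_u, log sigma2_v)
# Variances live on the log scale and rho_rs on the arctanh scale so the
# optimizer is unconstrained.  drift = "none" drops the occasion intercepts
# (fixes them at 0) instead of estimating them.

theta_names <- function(J, drift = "free") {
  nm <- c("mu_T", "beta_Q0", "beta_F0")
  if (drift == "free" && J >= 2L)
    nm <- c(nm, paste0("mu_Q", 2:J), paste0("mu_F", 2:J), paste0("mu_M", 2:J))
  c(nm, "beta_Q1", "beta_F1", "log_sigma2_T", "log_sigma2_r", "log_sigma2_s",
    "atanh_rho_rs", "log_sigma2_eps", "log_sigma2_u", "log_sigma2_v")
}

#' Map model parameters to the unconstrained optimizer scale and back
#'
#' Variances are log-transformed and the bias correlation arctanh-
#' transformed so that maximum likelihood optimization is unconstrained;
#' occasion intercepts beyond the anchored first occasion are included only
#' when `drift = "free"`.
#'
#' @param params A [model_parameters()] object.
#' @param design A [design_spec()].
#' @param drift `"free"` (estimate occasion intercepts, anchored at
#'   occasion 1) or `"none"` (all occasion intercepts fixed at 0).
#' @return `params_to_theta()`: a named numeric vector;
#'   `theta_to_params()`: a `model_parameters` object.
#' @keywords internal
#' @export
params_to_theta <- function(params, design = design_spec(), drift = "free") {
  J <- design$n_occasions
  floorv <- function(v) log(max(v, 1e-10))
  th <- c(params$mu_T, params$beta_Q0, params$beta_F0)
  if (drift == "free" && J >= 2L)
    th <- c(th, params$mu_Q[-1], params$mu_F[-1], params$mu_M[-1])
  th <- c(th, params$beta_Q1, params$beta_F1,
          floorv(params$sigma2_T), floorv(params$sigma2_r),
          floorv(params$sigma2_s), atanh(min(max(params$rho_rs, -0.999), 0.999)),
          floorv(params$sigma2_eps), floorv(params$sigma2_u),
          floorv(params$sigma2_v))
  names(th) <- theta_names(J, drift)
  th
}

#' @rdname params_to_theta
#' @param theta Named numeric vector on the unconstrained scale.
#' @export
theta_to_params <- function(theta, design = design_spec(), drift = "free") {
  J <- design$n_occasions
  i <- 0L
  take <- function(n) { v <- theta[i + seq_len(n)]; i <<- i + n; unname(v) }
  mu_T <- take(1L); beta_Q0 <- take(1L); beta_F0 <- take(1L)
  if (drift == "free" && J >= 2L) {
    mu_Q <- c(0, take(J - 1L)); mu_F <- c(0, take(J - 1L))
    mu_M <- c(0, take(J - 1L))
  } else {
    mu_Q <- mu_F <- mu_M <- numeric(J)
  }
  beta_Q1 <- take(1L); beta_F1 <- take(1L)
  model_parameters(mu_T = mu_T, beta_Q0 = beta_Q0, beta_F0 = beta_F0,
                   beta_Q1 = beta_Q1, beta_F1 = beta_F1,
                   sigma2_T = exp(take(1L)), sigma2_r = exp(take(1L)),
                   sigma2_s = exp(take(1L)), rho_rs = tanh(take(1L)),
                   sigma2_eps = exp(take(1L)), sigma2_u = exp(take(1L)),
                   sigma2_v = exp(take(1L)),
                   mu_Q = mu_Q, mu_F = mu_F, mu_M = mu_M)
}

# --- missingness-pattern sufficient statistics ------------------------------

# y: n x 3J matrix with NA for missing cells.  Returns a list of patterns,
# each with obs (observed column indices), n, ybar, S (scatter about ybar).
# Participants with no observed values are dropped with a warning.
pattern_stats <- function(y, warn_empty = TRUE) {
  obs <- !is.na(y)
  none <- rowSums(obs) == 0L
  if (any(none)) {
    if (warn_empty)
      warning(sum(none), " participant(s) with no observed values excluded",
              call. = FALSE)
    y <- y[!none, , drop = FALSE]
    obs <- obs[!none, , drop = FALSE]
  }
  if (!nrow(y)) stop("no participants with observed data", call. = FALSE)
  key <- obs %*% (2^(seq_len(ncol(y)) - 1))
  groups <- split(seq_len(nrow(y)), key)
  pats <- lapply(groups, function(rows) {
    o <- which(obs[rows[1L], ])
    yp <- y[rows, o, drop = FALSE]
    ybar <- colMeans(yp)
    S <- if (length(rows) > 1L) crossprod(sweep(yp, 2L, ybar))
         else matrix(0, length(o), length(o))
    list(obs = o, n = length(rows), ybar = ybar, S = S)
  })
  attr(pats, "n_total") <- nrow(y)
  pats
}

# Flatten a pattern list into the contiguous arrays the compiled kernel
# consumes; done once per fit so each likelihood call is allocation-light.
flatten_patterns <- function(patterns) {
  lens <- vapply(patterns, function(p) length(p$obs), integer(1L))
  list(obs_all = as.integer(unlist(lapply(patterns, `[[`, "obs"),
                                   use.names = FALSE)),
       off = c(0L, cumsum(lens)),
       n_pat = as.numeric(vapply(patterns, `[[`, 0L, "n")),
       ybar_all = unlist(lapply(patterns, `[[`, "ybar"), use.names = FALSE),
       S_all = unlist(lapply(patterns, function(p) as.numeric(p$S)),
                      use.names = FALSE),
       soff = c(0L, cumsum(lens^2)))
}

fiml_eval_flat <- function(nat, J, drift_free, fp, want_grad) {
  fiml_eval_cpp(nat, J, drift_free, fp$obs_all, fp$off, fp$n_pat,
                fp$ybar_all, fp$S_all, fp$soff, want_grad)
}

# --- likelihood and gradient -------------------------------------------------

# Core evaluation at natural-scale params.  Returns loglik and, if gradient,
# the accumulated dl/dmu (gmu, 3J) and full-matrix dl/dSigma (W, 3J x 3J).
fiml_core <- function(params, patterns, design, gradient = FALSE) {
  # intermediate optimizer iterates may carry negative slopes; the warning
  # belongs to user-facing calls, not to every likelihood evaluation
  mo <- suppressWarnings(implied_moments(params, design))
  mu <- mo$mean; Sigma <- mo$cov
  d3 <- length(mu)
  ll <- 0
  gmu <- numeric(d3)
  W <- matrix(0, d3, d3)
  for (p in patterns) {
    o <- p$obs
    So <- Sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(R)) return(list(loglik = -Inf))
    P <- chol2inv(R)
    dvec <- p$ybar - mu[o]
    Pd <- P %*% dvec
    quad <- sum(dvec * Pd)
    ll <- ll - 0.5 * (p$n * length(o) * log(2 * pi) +
                      p$n * 2 * sum(log(diag(R))) +
                      sum(P * p$S) + p$n * quad)
    if (gradient) {
      gmu[o] <- gmu[o] + p$n * Pd
      A <- p$S + p$n * tcrossprod(dvec)
      W[o, o] <- W[o, o] + 0.5 * (P %*% A %*% P - p$n * P)
    }
  }
  if (!gradient) return(list(loglik = ll))
  list(loglik = ll, gmu = gmu, W = W)
}

# Chain rule from (gmu, W) to the gradient on the unconstrained theta scale.
fiml_grad_theta <- function(params, core, design, drift) {
  J <- design$n_occasions
  Qi <- seq_len(J); Fi <- J + Qi; Mi <- 2L * J + Qi
  a <- params$beta_Q1; b <- params$beta_F1
  s2T <- params$sigma2_T; s2r <- params$sigma2_r; s2s <- params$sigma2_s
  rho <- params$rho_rs
  srss <- sqrt(s2r * s2s)
  W <- core$W; gmu <- core$gmu
  TQQ <- sum(W[Qi, Qi]); TFF <- sum(W[Fi, Fi]); TMM <- sum(W[Mi, Mi])
  TQF <- 2 * sum(W[Qi, Fi]); TQM <- 2 * sum(W[Qi, Mi])
  TFM <- 2 * sum(W[Fi, Mi])
  dg <- diag(W)
  DQ <- sum(dg[Qi]); DF <- sum(dg[Fi]); DM <- sum(dg[Mi])
  gQ <- sum(gmu[Qi]); gF <- sum(gmu[Fi]); gM <- sum(gmu[Mi])

  g <- c(a * gQ + b * gF + gM,        # mu_T
         gQ,                          # beta_Q0
         gF)                          # beta_F0
  if (drift == "free" && J >= 2L)
    g <- c(g, gmu[Qi][-1], gmu[Fi][-1], gmu[Mi][-1])
  g <- c(g,
         2 * a * s2T * TQQ + b * s2T * TQF + s2T * TQM + params$mu_T * gQ,  # beta_Q1
         2 * b * s2T * TFF + a * s2T * TQF + s2T * TFM + params$mu_T * gF,  # beta_F1
         s2T * (a^2 * TQQ + b^2 * TFF + TMM + a * b * TQF + a * TQM + b * TFM),
         s2r * TQQ + 0.5 * rho * srss * TQF,   # d/d log sigma2_r
         s2s * TFF + 0.5 * rho * srss * TQF,   # d/d log sigma2_s
         (1 - rho^2) * srss * TQF,             # d/d atanh rho
         params$sigma2_eps * DQ,
         params$sigma2_u * DF,
         params$sigma2_v * DM)
  names(g) <- theta_names(J, drift)
  g
}

#' Full-information maximum likelihood of the measurement model
#'
#' Sum over participants of the multivariate-normal log-density of each
#' participant's *observed* measurement subvector under the moments implied
#' by `params`, i.e. with the implied mean/covariance restricted to the
#' observed coordinates.  Valid under missing-at-random; reduces exactly to
#' the complete-data log-likelihood when nothing is missing.  Participants
#' with no observed values are excluded with a warning.
#'
#' @param params A [model_parameters()] object.
#' @param cohort A [cohort_measurements()] with `log_transformed = TRUE`
#'   (alternatively a plain numeric matrix as produced by
#'   [cohort_wide()]`$y`).
#' @param design A [design_spec()].
#' @param nutrient Nutrient to select when the cohort holds several.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(params, cohort, design = design_spec(),
                           nutrient = NULL) {
  y <- cohort_matrix(cohort, nutrient, design)
  fiml_core(params, pattern_stats(y), design)$loglik
}

cohort_matrix <- function(cohort, nutrient = NULL, design = design_spec()) {
  if (is.matrix(cohort)) return(cohort)
  if (!isTRUE(attr(cohort, "log_transformed")))
    stop("cohort must be log-transformed before likelihood evaluation ",
         "(see read_cohort(log_transform = TRUE))", call. = FALSE)
  cohort_wide(cohort, nutrient, design)$y
}
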