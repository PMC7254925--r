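#' Mean vector and covariance matrix implied by the measurement model
#'
#' Computes the moments of the stacked observation vector
#' `(Q_1..Q_J, F_1..F_J, M_1..M_J)` implied by a parameter set.  These are the
#' moments the full-information maximum likelihood fit matches to the data,
#' and the moments the synthetic-cohort generator reproduces empirically.
#'
#' Structure (writing `a = beta_Q1`, `b = beta_F1`):
#' * `E[Q_j] = mu_Qj + beta_Q0 + a * mu_T`, and analogously for `F`, `M`;
#' * `cov(Q_j, Q_j') = a^2 sigma2_T + sigma2_r + [j == j'] sigma2_eps`;
#' * `cov(Q_j, F_j') = a b sigma2_T + rho_rs * sigma_r * sigma_s`;
#' * `cov(Q_j, M_j') = a sigma2_T`; `cov(F_j, M_j') = b sigma2_T`;
#' * `cov(M_j, M_j') = sigma2_T + [j == j'] sigma2_v`.
#'
#' @param params A [model_parameters()] object.
#' @param design A [design_spec()]; its `n_occasions` must match the length
#'   of the occasion-intercept vectors in `params`.
#' @return A list with components `mean` (length `3J` named vector) and
#'   `cov` (`3J x 3J` symmetric positive semi-definite matrix), ordered
#'   `webq` occasions, then `recall`, then `biomarker`.
#' @export
implied_moments <- function(params, design = design_spec()) {
  validate_parameters(params)
  J <- design$n_occasions
  if (length(params$mu_Q) != J)
    stop("parameters have ", length(params$mu_Q),
         " occasion intercepts but the design specifies J = ", J,
         call. = FALSE)
  a <- params$beta_Q1
  b <- params$beta_F1
  s2T <- params$sigma2_T
  crs <- params$rho_rs * sqrt(params$sigma2_r * params$sigma2_s)

  mu <- c(params$mu_Q + params$beta_Q0 + a * params$mu_T,
          params$mu_F + params$beta_F0 + b * params$mu_T,
          params$mu_M + params$mu_T)
  nm <- c(paste0("webq", seq_len(J)), paste0("recall", seq_len(J)),
          paste0("biomarker", seq_len(J)))
  names(mu) <- nm

  ones <- matrix(1, J, J)
  I <- diag(J)
  S <- rbind(
    cbind((a^2 * s2T + params$sigma2_r) * ones + params$sigma2_eps * I,
          (a * b * s2T + crs) * ones,
          (a * s2T) * ones),
    cbind((a * b * s2T + crs) * ones,
          (b^2 * s2T + params$sigma2_s) * ones + params$sigma2_u * I,
          (b * s2T) * ones),
    cbind((a * s2T) * ones,
          (b * s2T) * ones,
          s2T * ones + params$sigma2_v * I)
  )
  dimnames(S) <- list(nm, nm)
  list(mean = mu, cov = S)
}
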