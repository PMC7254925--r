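#' Parameters of the three-instrument measurement error model
#'
#' Container for every parameter of the latent true-intake model relating two
#' self-report instruments (an online 24-hour questionnaire `Q` and an
#' interviewer-administered multiple-pass recall `F`) and an objective
#' biomarker `M` to latent long-term true intake `T`, all on the natural-log
#' scale:
#' \deqn{Q_{ij} = \mu_{Qj} + \beta_{Q0} + \beta_{Q1} T_i + r_i + \epsilon_{ij}}
#' \deqn{F_{ij} = \mu_{Fj} + \beta_{F0} + \beta_{F1} T_i + s_i + u_{ij}}
#' \deqn{M_{ij} = \mu_{Mj} + T_i + v_{ij}}
#' where \eqn{T_i \sim N(\mu_T, \sigma^2_T)}, the person-specific reporting
#' biases \eqn{(r_i, s_i)} are bivariate normal with variances
#' \eqn{\sigma^2_r, \sigma^2_s} and correlation \eqn{\rho_{rs}}, and the
#' within-person errors \eqn{\epsilon_{ij}, u_{ij}, v_{ij}} are independent
#' mean-zero normals.  The biomarker carries no person-specific bias and its
#' slope is fixed at 1, which defines the units of `T`.
#'
#' Occasion intercepts (`mu_Q`, `mu_F`, `mu_M`) model drift over repeat
#' visits; the occasion-1 intercepts are fixed at 0 for identifiability
#' (absorbed into `beta_Q0`, `beta_F0` and `mu_T`).
#'
#' @param mu_T Mean of latent true intake on the log scale.
#' @param sigma2_T Between-person variance of true intake.
#' @param beta_Q0,beta_F0 Additive (constant) biases of the two self-report
#'   instruments.
#' @param beta_Q1,beta_F1 Multiplicative (slope) biases of the two
#'   self-report instruments.
#' @param sigma2_r,sigma2_s Variances of the person-specific biases.
#' @param rho_rs Correlation between the two person-specific biases.
#' @param sigma2_eps,sigma2_u,sigma2_v Within-person error variances of the
#'   questionnaire, the recall and the biomarker.
#' @param mu_Q,mu_F,mu_M Occasion intercepts, one per occasion; the first
#'   element must be 0.
#' @param n_occasions Number of occasions `J`; used to default the occasion
#'   intercepts to zero vectors.
#'
#' @return An object of class `model_parameters` (a named list).
#' @export
#' @examples
#' p <- model_parameters(mu_T = 4.25, sigma2_T = 0.0625,
#'                       beta_Q1 = 0.6, sigma2_r = 0.04, sigma2_eps = 0.07)
#' implied_moments(p, design_spec())
model_parameters <- function(mu_T = 0, sigma2_T = 1,
                             beta_Q0 = 0, beta_F0 = 0,
                             beta_Q1 = 1, beta_F1 = 1,
                             sigma2_r = 0, sigma2_s = 0, rho_rs = 0,
                             sigma2_eps = 0, sigma2_u = 0, sigma2_v = 0,
                             mu_Q = numeric(n_occasions),
                             mu_F = numeric(n_occasions),
                             mu_M = numeric(n_occasions),
                             n_occasions = 3L) {
  p <- structure(list(
    mu_T = as.numeric(mu_T), sigma2_T = as.numeric(sigma2_T),
    mu_Q = as.numeric(mu_Q), mu_F = as.numeric(mu_F), mu_M = as.numeric(mu_M),
    beta_Q0 = as.numeric(beta_Q0), beta_F0 = as.numeric(beta_F0),
    beta_Q1 = as.numeric(beta_Q1), beta_F1 = as.numeric(beta_F1),
    sigma2_r = as.numeric(sigma2_r), sigma2_s = as.numeric(sigma2_s),
    rho_rs = as.numeric(rho_rs),
    sigma2_eps = as.numeric(sigma2_eps), sigma2_u = as.numeric(sigma2_u),
    sigma2_v = as.numeric(sigma2_v)
  ), class = "model_parameters")
  validate_parameters(p)
  p
}

#' Validate a `model_parameters` object
#'
#' Checks the invariants of the model: all variances nonnegative,
#' `|rho_rs| <= 1`, finite slopes, occasion intercept vectors of equal
#' length with the first element anchored at 0.  A negative instrument slope
#' is allowed by the algebra but triggers a warning because the attenuation
#' interpretation breaks down.
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  num1 <- c("mu_T", "sigma2_T", "beta_Q0", "beta_F0", "beta_Q1", "beta_F1",
            "sigma2_r", "sigma2_s", "rho_rs",
            "sigma2_eps", "sigma2_u", "sigma2_v")
  for (f in num1) {
    v <- params[[f]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  for (f in c("sigma2_T", "sigma2_r", "sigma2_s",
              "sigma2_eps", "sigma2_u", "sigma2_v")) {
    if (params[[f]] < 0)
      stop("variance '", f, "' must be >= 0 (got ", params[[f]], ")",
           call. = FALSE)
  }
  if (abs(params$rho_rs) > 1)
    stop("correlation 'rho_rs' must lie in [-1, 1] (got ", params$rho_rs, ")",
         call. = FALSE)
  J <- length(params$mu_Q)
  if (length(params$mu_F) != J || length(params$mu_M) != J)
    stop("occasion intercepts 'mu_Q', 'mu_F', 'mu_M' must have equal length",
         call. = FALSE)
  if (!all(is.finite(c(params$mu_Q, params$mu_F, params$mu_M))))
    stop("occasion intercepts must be finite", call. = FALSE)
  if (abs(params$mu_Q[1]) > 1e-12 || abs(params$mu_F[1]) > 1e-12 ||
      abs(params$mu_M[1]) > 1e-12)
    stop("identification requires mu_Q[1] = mu_F[1] = mu_M[1] = 0",
         call. = FALSE)
  if (params$beta_Q1 <= 0 || params$beta_F1 <= 0)
    warning("nonpositive instrument slope: attenuation factors lose their ",
            "usual interpretation", call. = FALSE)
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Three-instrument measurement error model parameters\n")
  cat(sprintf("  latent intake:  mu_T = %.4g, sigma2_T = %.4g\n",
              x$mu_T, x$sigma2_T))
  cat(sprintf("  webq:    beta0 = %.4g, beta1 = %.4g, sigma2_r = %.4g, sigma2_eps = %.4g\n",
              x$beta_Q0, x$beta_Q1, x$sigma2_r, x$sigma2_eps))
  cat(sprintf("  recall:  beta0 = %.4g, beta1 = %.4g, sigma2_s = %.4g, sigma2_u = %.4g\n",
              x$beta_F0, x$beta_F1, x$sigma2_s, x$sigma2_u))
  cat(sprintf("  biomarker: sigma2_v = %.4g; rho_rs = %.4g\n",
              x$sigma2_v, x$rho_rs))
  cat(sprintf("  occasion drift (J = %d): mu_Q = %s; mu_F = %s; mu_M = %s\n",
              length(x$mu_Q),
              paste(signif(x$mu_Q, 3), collapse = ", "),
              paste(signif(x$mu_F, 3), collapse = ", "),
              paste(signif(x$mu_M, 3), collapse = ", ")))
  invisible(x)
}

#' Design of a repeated-measures validation study
#'
#' @param n_occasions Number of measurement cycles `J` (default 3, roughly two
#'   weeks apart in the motivating design).  `J >= 2` is required so that
#'   within- and between-person variance components are identifiable.
#' @param instruments Ordered instrument labels.
#' @param reference_instrument The instrument whose slope is fixed at 1
#'   (the biomarker), defining the scale of latent true intake.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_occasions = 3L,
                        instruments = c("webq", "recall", "biomarker"),
                        reference_instrument = "biomarker") {
  n_occasions <- as.integer(n_occasions)
  if (is.na(n_occasions) || n_occasions < 2L)
    stop("n_occasions must be an integer >= 2 for identifiability",
         call. = FALSE)
  if (!reference_instrument %in% instruments)
    stop("reference_instrument must be one of the instruments", call. = FALSE)
  structure(list(n_occasions = n_occasions,
                 instruments = instruments,
                 reference_instrument = reference_instrument),
            class = "design_spec")
}

#' Serialize model parameters to JSON
#'
#' Writes a flat key-value representation with exactly the field names of
#' [model_parameters()]; the round trip through [read_parameters()] is
#' lossless at full double precision.
#'
#' @param params A `model_parameters` object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_parameters <- function(params, path = NULL) {
  validate_parameters(params)
  # 17 significant digits so the double-precision round trip is lossless
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_parameters
#' @param text A JSON string, used instead of `path` when non-`NULL`.
#' @export
read_parameters <- function(path = NULL, text = NULL) {
  x <- jsonlite::fromJSON(if (is.null(text)) paste(readLines(path), collapse = "\n") else text)
  do.call(model_parameters, x[names(x) != "n_occasions"])
}
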