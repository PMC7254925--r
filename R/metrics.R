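#' Attenuation factor for the mean of k administrations
#'
#' The attenuation factor \eqn{\lambda_k} is the slope from regressing latent
#' true intake on the mean of `k` administrations of a self-report
#' instrument; it multiplies (and so dilutes) log relative risks estimated
#' from diet-disease models that use the error-prone measure.  For an
#' instrument with slope \eqn{\beta_1}, person-specific bias variance
#' \eqn{\sigma^2_b} and within-person error variance \eqn{\sigma^2_w},
#' averaging `k` administrations replaces \eqn{\sigma^2_w} by
#' \eqn{\sigma^2_w / k}, giving
#' \deqn{\lambda_k = \frac{\beta_1 \sigma^2_T}
#'                        {\beta_1^2 \sigma^2_T + \sigma^2_b + \sigma^2_w/k}.}
#'
#' @param params A [model_parameters()] object.
#' @param instrument `"webq"` or `"recall"` (the biomarker is the reference
#'   and has no attenuation factor).
#' @param k Number of repeat administrations averaged, integer `>= 1`.
#' @return The attenuation factor(s) \eqn{\lambda_k}; vectorized over `k`.
#' @seealso [correlation_with_truth()], [extrapolate_from_pair()]
#' @export
#' @examples
#' p <- model_parameters(sigma2_T = 1, sigma2_r = 1, sigma2_eps = 2)
#' attenuation_factor(p, "webq", k = 1:2)  # 0.25, 1/3
attenuation_factor <- function(params, instrument = c("webq", "recall"),
                               k = 1L) {
  validate_parameters(params)
  instrument <- match.arg(instrument)
  k <- check_k(k)
  cmp <- instrument_components(params, instrument)
  cmp$beta1 * params$sigma2_T /
    (cmp$beta1^2 * params$sigma2_T + cmp$sigma2_b + cmp$sigma2_w / k)
}

#' Correlation between the instrument mean and true intake
#'
#' \deqn{\rho_k = \frac{\beta_1 \sigma_T}
#'   {\sqrt{\beta_1^2 \sigma^2_T + \sigma^2_b + \sigma^2_w/k}}.}
#' This correlation governs the power lost when intake is used for ranking
#' or categorization, and equals the attenuation of log relative risks
#' between equal-sized intake categories.  It satisfies the identity
#' \eqn{(\rho_k/\rho_1)^2 = \lambda_k/\lambda_1}.
#'
#' @inheritParams attenuation_factor
#' @return The correlation(s) \eqn{\rho_k}; vectorized over `k`.
#' @export
#' @examples
#' p <- model_parameters(sigma2_T = 1, sigma2_r = 1, sigma2_eps = 2)
#' correlation_with_truth(p, "webq", k = 1:2)  # 0.5, 1/sqrt(3)
correlation_with_truth <- function(params, instrument = c("webq", "recall"),
                                   k = 1L) {
  validate_parameters(params)
  instrument <- match.arg(instrument)
  k <- check_k(k)
  cmp <- instrument_components(params, instrument)
  cmp$beta1 * sqrt(params$sigma2_T) /
    sqrt(cmp$beta1^2 * params$sigma2_T + cmp$sigma2_b + cmp$sigma2_w / k)
}

instrument_components <- function(params, instrument) {
  if (instrument == "webq")
    list(beta1 = params$beta_Q1, sigma2_b = params$sigma2_r,
         sigma2_w = params$sigma2_eps)
  else
    list(beta1 = params$beta_F1, sigma2_b = params$sigma2_s,
         sigma2_w = params$sigma2_u)
}

check_k <- function(k) {
  if (length(k) < 1L || any(!is.finite(k)) || any(k < 1) ||
      any(k != round(k)))
    stop("k must be integer repeat count(s) >= 1", call. = FALSE)
  as.integer(round(k))
}

#' Printed single- and two-administration metrics as extrapolation input
#'
#' Bundle of the three published quantities from which validity metrics for
#' any number of repeat administrations can be recovered in closed form:
#' the attenuation factors at `k = 1` and `k = 2` and the correlation with
#' true intake at `k = 1`.
#'
#' @param lambda1,lambda2 Attenuation factors for one and for the mean of
#'   two administrations.  `0 < lambda1 <= lambda2` and
#'   `lambda2/lambda1 < 2` are required (algebraically, no nonnegative
#'   within-person variance ratio yields a doubling or more).
#' @param rho1 Correlation with true intake at `k = 1`, in `(0, 1]`.
#' @return An object of class `extrapolation_input`.
#' @export
extrapolation_input <- function(lambda1, lambda2, rho1) {
  for (v in c("lambda1", "lambda2", "rho1")) {
    x <- get(v)
    if (length(x) != 1L || !is.finite(x))
      stop("'", v, "' must be a single finite number", call. = FALSE)
  }
  if (lambda1 <= 0) stop("lambda1 must be > 0", call. = FALSE)
  if (lambda2 < lambda1)
    stop("infeasible pair: lambda2 < lambda1 (averaging cannot worsen ",
         "attenuation)", call. = FALSE)
  if (lambda2 / lambda1 >= 2)
    stop("infeasible ratio: lambda2/lambda1 >= 2 has no nonnegative ",
         "variance-ratio solution", call. = FALSE)
  if (rho1 <= 0 || rho1 > 1)
    stop("rho1 must lie in (0, 1]", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, rho1 = rho1),
            class = "extrapolation_input")
}

#' Closed-form extrapolation of validity metrics to k administrations
#'
#' From printed `k = 1` and `k = 2` attenuation factors, solves
#' \deqn{\frac{1 + x}{1 + x/2} = \frac{\lambda_2}{\lambda_1}}
#' for the variance ratio
#' \eqn{x = \sigma^2_w / (\beta_1^2\sigma^2_T + \sigma^2_b)} (within-person
#' error variance relative to the stable part of the instrument signal), and
#' then evaluates
#' \deqn{\lambda_k = \lambda_1 \frac{1 + x}{1 + x/k}, \qquad
#'       \rho_k = \rho_1 \sqrt{\lambda_k / \lambda_1}.}
#' Both sequences are nondecreasing in `k`, with finite limits
#' \eqn{\lambda_1 (1 + x)} and \eqn{\rho_1 \sqrt{1 + x}}.  This reproduces
#' the substitution \eqn{\sigma^2_w \to \sigma^2_w / k} without access to
#' the underlying variance components.
#'
#' @param input An [extrapolation_input()] (or a plain list with elements
#'   `lambda1`, `lambda2`, `rho1`, which is validated on the way in).
#' @param k Repeat count(s), integer `>= 1`; vectorized.
#' @return A data frame with columns `k`, `lambda`, `rho` at full precision.
#' @export
#' @examples
#' extrapolate_from_pair(extrapolation_input(0.27, 0.37, 0.40), k = 1:5)
extrapolate_from_pair <- function(input, k = 1:5) {
  if (!inherits(input, "extrapolation_input"))
    input <- extrapolation_input(input$lambda1, input$lambda2, input$rho1)
  k <- check_k(k)
  r <- input$lambda2 / input$lambda1
  x <- (r - 1) / (1 - r / 2)     # solves (1+x)/(1+x/2) = r; x >= 0 since r in [1,2)
  lam <- input$lambda1 * (1 + x) / (1 + x / k)
  rho <- input$rho1 * sqrt(lam / input$lambda1)
  data.frame(k = k, lambda = lam, rho = rho)
}
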