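# Psychometric response models: truncated log-parabola contrast sensitivity
# (CSF) and probit gap acceptance (GAF), plus the Bernoulli likelihood that
# every downstream module consumes.

# Coerce a parameter point (named vector/list) or a node matrix to a numeric
# matrix with one row per parameter point and the requested column order.
.param_matrix <- function(params, names) {
  if (is.list(params) && !is.data.frame(params)) params <- unlist(params)
  if (is.matrix(params)) {
    if (!all(names %in% colnames(params)))
      stop("parameter matrix must have columns: ", paste(names, collapse = ", "))
    return(params[, names, drop = FALSE])
  }
  params <- as.numeric(params[names])
  if (anyNA(params))
    stop("parameter point must provide: ", paste(names, collapse = ", "))
  matrix(params, nrow = 1, dimnames = list(NULL, names))
}

# Column extraction that never carries a name onto scalar results.
.pcol <- function(m, nm) as.vector(m[, nm])

#' Log-parabola of log10 contrast sensitivity
#'
#' The untruncated log-parabola `S'(f)` giving log10 sensitivity as a function
#' of log10 spatial frequency: a downward parabola with vertex at
#' `(log10(f_max), log10(gamma_max))` whose width is set by the bandwidth
#' `beta1` (in octaves) through `beta' = log10(2 * beta1)`.
#'
#' @param params Parameter point (named vector or list) or node matrix with
#'   entries `gamma_max` (peak sensitivity), `f_max` (peak frequency,
#'   cycles/degree), `beta1` (bandwidth, octaves); `delta1` is accepted and
#'   ignored here.
#' @param log_f log10 spatial frequency (vectorized).
#' @return log10 sensitivity, recycled over parameter rows and `log_f`.
#' @seealso [csf_sensitivity()] for the truncated form actually used by the
#'   response model.
#' @export
#' @examples
#' p <- c(gamma_max = 100, f_max = 2.5, beta1 = 2.5, delta1 = 0.25)
#' csf_log_parabola(p, log10(2.5))  # vertex: log10(gamma_max) = 2
csf_log_parabola <- function(params, log_f) {
  th <- .param_matrix(params, c("gamma_max", "f_max", "beta1"))
  log_f <- as.vector(log_f)
  if (any(!is.finite(log_f))) stop("log_f must be finite")
  if (any(th <= 0)) stop("gamma_max, f_max and beta1 must be strictly positive")
  kappa <- log10(2)
  beta_prime <- log10(2 * .pcol(th, "beta1"))
  log10(.pcol(th, "gamma_max")) -
    kappa * ((log_f - log10(.pcol(th, "f_max"))) / (beta_prime / 2))^2
}

#' Truncated log-parabola contrast sensitivity
#'
#' Applies the low-frequency truncation to [csf_log_parabola()]: for
#' frequencies below the peak, sensitivity never falls below the plateau
#' `log10(gamma_max) - delta1`; at and above the peak the parabola is used
#' unmodified. The truncation condition is evaluated in log10 sensitivity
#' units, matching the units of the plateau it switches to.
#'
#' @inheritParams csf_log_parabola
#' @param params As in [csf_log_parabola()], additionally requiring `delta1`
#'   (truncation depth, log10 sensitivity units).
#' @return log10 sensitivity `S(f)`.
#' @export
csf_sensitivity <- function(params, log_f) {
  th <- .param_matrix(params, c("gamma_max", "f_max", "beta1", "delta1"))
  sp <- csf_log_parabola(th, log_f)
  plateau <- log10(.pcol(th, "gamma_max")) - .pcol(th, "delta1")
  low <- (log_f < log10(.pcol(th, "f_max"))) & (sp < plateau)
  ifelse(low, plateau, sp)
}

#' CSF probability of a correct response
#'
#' Probability that the observer responds correctly to a grating of log10
#' frequency `log_f` and log10 contrast `log_c`:
#' `min(1 - mu, 0.5 + 0.5 * 10^(2 * (S(f) + log_c)))`,
#' where `S(f)` is the truncated log-parabola sensitivity. The form rises
#' from the 0.5 guess rate at low contrast to the lapse-bounded ceiling
#' `1 - mu` and is non-decreasing in contrast.
#'
#' @inheritParams csf_sensitivity
#' @param log_f,log_c log10 grating frequency and log10 contrast.
#' @param mu Lapse bound; the response probability is capped at `1 - mu`.
#'   Default 0.04.
#' @return Probability of `y = 1`, in `[0.5, 1 - mu]`.
#' @export
csf_response_prob <- function(params, log_f, log_c, mu = 0.04) {
  s <- csf_sensitivity(params, as.vector(log_f))
  pmin(1 - mu, 0.5 + 0.5 * 10^(2 * (s + as.vector(log_c))))
}

#' Probit gap acceptance probability
#'
#' Probability that a driver accepts an offered gap of `gap` seconds:
#' `pnorm((gap - t_cr) / sigma)`, with critical gap mean `t_cr` and spread
#' `sigma`, both in seconds.
#'
#' @param params Parameter point (named vector or list) or node matrix with
#'   entries `t_cr` and `sigma`.
#' @param gap Offered gap in seconds (vectorized).
#' @return Acceptance probability in (0, 1), strictly increasing in `gap`.
#' @export
#' @examples
#' gaf_response_prob(c(t_cr = 7.3, sigma = 2.2804), 7.3)  # 0.5
gaf_response_prob <- function(params, gap) {
  th <- .param_matrix(params, c("t_cr", "sigma"))
  if (any(th[, "sigma"] <= 0)) stop("sigma must be strictly positive")
  gap <- as.vector(gap)
  stats::pnorm((gap - .pcol(th, "t_cr")) / .pcol(th, "sigma"))
}

#' Bernoulli likelihood of a binary response
#'
#' @param prob_y1 Probability of response `y = 1` (vectorized, in `[0, 1]`).
#' @param y Observed binary response, 0 or 1.
#' @return `prob_y1` if `y = 1`, `1 - prob_y1` if `y = 0`.
#' @export
likelihood <- function(prob_y1, y) {
  if (length(y) != 1 || !(y %in% c(0, 1))) stop("y must be 0 or 1")
  if (any(prob_y1 < 0 | prob_y1 > 1)) stop("prob_y1 must lie in [0, 1]")
  if (y == 1) prob_y1 else 1 - prob_y1
}

#' Psychometric model objects
#'
#' Constructors for the two bundled psychometric models. A model is a list
#' with a `response_prob(theta, stimulus)` member mapping a parameter node
#' matrix and a single stimulus point to per-node probabilities of `y = 1`;
#' every downstream module (likelihood tables, information sweeps, the trial
#' loop) depends only on this contract, so a new psychometric function plugs
#' in by supplying the same interface.
#'
#' @param mu Lapse bound for the CSF model (response ceiling `1 - mu`).
#' @return An object of class `psychometric_model`.
#' @export
csf_model <- function(mu = 0.04) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, mu < 0.5)
  structure(list(
    name = "csf",
    param_names = c("gamma_max", "f_max", "beta1", "delta1"),
    stimulus_names = c("log_f", "log_c"),
    mu = mu,
    response_prob = function(theta, stimulus) {
      csf_response_prob(theta, stimulus[1], stimulus[2], mu = mu)
    }
  ), class = "psychometric_model")
}

#' @rdname csf_model
#' @export
gaf_model <- function() {
  structure(list(
    name = "gaf",
    param_names = c("t_cr", "sigma"),
    stimulus_names = "gap",
    response_prob = function(theta, stimulus) {
      gaf_response_prob(theta, stimulus[1])
    }
  ), class = "psychometric_model")
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat("<psychometric_model>", x$name, "\n",
      " parameters:", paste(x$param_names, collapse = ", "), "\n",
      " stimulus:  ", paste(x$stimulus_names, collapse = ", "), "\n")
  invisible(x)
}
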