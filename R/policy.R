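# Stimulus-selection policies and the per-trial experiment loop.
#
# Three policies are exposed: "ee" (explore by maximal mutual information
# while the parameter entropy exceeds the threshold epsilon, otherwise
# exploit by uniform-random stimulus selection), "classical" (always
# explore), and "random" (always exploit). The entropy condition is
# re-evaluated on the prior of every trial, so the number of exploitation
# trials in an "ee" run is a random variable.

#' Policy configuration
#'
#' @param kind One of `"ee"`, `"classical"`, `"random"`.
#' @param epsilon Entropy threshold in bits; required (and strictly positive)
#'   for `kind = "ee"`, ignored otherwise.
#' @param trials Total number of trials, at least 1.
#' @return An object of class `policy_config`.
#' @export
policy_config <- function(kind = c("ee", "classical", "random"),
                          epsilon = NULL, trials = 1L) {
  kind <- match.arg(kind)
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1) stop("trials must be >= 1")
  if (kind == "ee") {
    if (is.null(epsilon) || !is.finite(epsilon) || epsilon <= 0)
      stop("kind = 'ee' requires a finite epsilon > 0")
  }
  structure(list(kind = kind, epsilon = epsilon, trials = trials),
            class = "policy_config")
}

#' Explore-or-exploit decision
#'
#' Explore (information-maximal selection) if and only if the current
#' parameter entropy strictly exceeds the threshold; at or below the
#' threshold the policy exploits (uniform-random selection).
#'
#' @param entropy_bits Current parameter entropy in bits.
#' @param epsilon Threshold in bits, `> 0`.
#' @return `"explore"` or `"exploit"`.
#' @export
ee_decide <- function(entropy_bits, epsilon) {
  if (!is.finite(entropy_bits) || !is.finite(epsilon) || epsilon <= 0)
    stop("entropy_bits must be finite and epsilon > 0")
  if (entropy_bits > epsilon) "explore" else "exploit"
}

#' Exploration selection: the most informative stimulus
#'
#' @param report An `information_report` from [information_sweep()].
#' @return Index of the maximizing stimulus (lowest index on ties).
#' @export
select_explore <- function(report) report$argmax_index

#' Exploitation selection: a uniform-random stimulus
#'
#' @param rng A stream from [rng_stream()].
#' @param point_count Number of stimulus points.
#' @return A stimulus index, uniform over `1..point_count`.
#' @export
select_exploit <- function(rng, point_count) {
  if (point_count < 1) stop("point_count must be >= 1")
  rng$sample_int(point_count)
}

# Map natural-unit coordinates onto each axis's spacing scale (identity for
# linear axes, log10 for log axes); used for error bookkeeping.
.error_coords <- function(x, grid, error_scale) {
  if (error_scale == "log10") {
    x <- unlist(x)
    return(log10(x))
  }
  unlist(x)
}

#' Run one adaptive estimation experiment
#'
#' Executes the full per-trial loop against a virtual subject with known true
#' parameters: compute the entropy of the current prior; choose a strategy
#' (per the policy); select a stimulus (information sweep for explore
#' trials, uniform draw for exploit trials -- no sweep is performed on
#' exploit trials, which is where the policy's speed-up comes from); draw the
#' binary response from the model evaluated at the continuous truth; update
#' the posterior; record the posterior-mean estimate and its per-parameter
#' squared errors.
#'
#' @param model A `psychometric_model`.
#' @param grid A `parameter_grid`.
#' @param stimuli A `stimulus_grid`.
#' @param table The `likelihood_table` for (`grid`, `stimuli`).
#' @param policy A `policy_config`.
#' @param truth Named true parameter point (natural units; need not be a grid
#'   node).
#' @param policy_seed,subject_seed Seeds for the two independent streams.
#' @param error_scale `"raw"` (natural units, default) or `"log10"` for the
#'   recorded squared errors.
#' @return A data frame with one row per trial: `trial`, `strategy`,
#'   `stimulus_index`, the stimulus components, `response`, `entropy_bits`
#'   (entropy of the prior used on that trial), `max_mi_bits` (`NA` on
#'   exploit trials), the estimate (`est_*`) and squared errors (`se_*`) per
#'   parameter. The attribute `"theorem1_slack"` carries the largest observed
#'   `max MI - H` over explore trials (non-positive when the entropy bound
#'   holds).
#' @export
run_experiment <- function(model, grid, stimuli, table, policy, truth,
                           policy_seed = 1L, subject_seed = 2L,
                           error_scale = c("raw", "log10")) {
  error_scale <- match.arg(error_scale)
  stopifnot(inherits(policy, "policy_config"))
  T <- policy$trials
  m <- stimuli$point_count
  rng_pol <- rng_stream(policy_seed)
  rng_sub <- rng_stream(subject_seed)
  truth <- unlist(truth)[model$param_names]
  truth_prob <- vapply(seq_len(m), function(j)
    model$response_prob(.param_matrix(truth, model$param_names),
                        stimuli$points[j, ]), numeric(1))
  truth_err <- .error_coords(truth, grid, error_scale)

  state <- uniform_prior(grid)
  k <- length(model$param_names)
  out <- list(
    trial = seq_len(T), strategy = character(T), stimulus_index = integer(T),
    response = integer(T), entropy_bits = numeric(T), max_mi_bits = rep(NA_real_, T)
  )
  est <- matrix(NA_real_, T, k, dimnames = list(NULL, model$param_names))
  se <- est
  slack <- -Inf

  for (t in seq_len(T)) {
    H <- parameter_entropy(state)
    strategy <- switch(policy$kind,
      classical = "explore",
      random = "exploit",
      ee = ee_decide(H, policy$epsilon))
    if (strategy == "explore") {
      report <- information_sweep(state, table)
      j <- select_explore(report)
      maxmi <- report$mi_per_stimulus[j]
      slack <- max(slack, maxmi - H)
      out$max_mi_bits[t] <- maxmi
    } else {
      j <- select_exploit(rng_pol, m)
    }
    y <- as.integer(rng_sub$runif(1) < truth_prob[j])
    state <- posterior_update(state, table$prob[, j], y)
    e <- estimate_mean(state, grid)
    est[t, ] <- e
    se[t, ] <- squared_error(.error_coords(e, grid, error_scale), truth_err)
    out$strategy[t] <- strategy
    out$stimulus_index[t] <- j
    out$response[t] <- y
    out$entropy_bits[t] <- H
  }

  stim_cols <- stimuli$points[out$stimulus_index, , drop = FALSE]
  colnames(stim_cols) <- model$stimulus_names
  rec <- data.frame(out[c("trial", "strategy", "stimulus_index")], stim_cols,
                    out[c("response", "entropy_bits", "max_mi_bits")],
                    stats::setNames(as.data.frame(est), paste0("est_", colnames(est))),
                    stats::setNames(as.data.frame(se), paste0("se_", colnames(se))))
  attr(rec, "theorem1_slack") <- slack
  rec
}

#' Number of exploitation trials in a trial log
#'
#' @param records A trial-record data frame from [run_experiment()].
#' @return Count of trials on which the strategy was `"exploit"`.
#' @export
exploitation_count <- function(records) sum(records$strategy == "exploit")
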