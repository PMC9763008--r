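# Virtual subject and replication harness: full experiment configurations,
# repeated seeded runs, per-trial aggregation across replications, and the
# head-to-head policy comparison.

#' Full experiment configuration
#'
#' Describes one simulated adaptive estimation experiment: the model, the
#' parameter and stimulus discretizations, the virtual subject's true
#' parameters, the stimulus-selection policy, and the replication protocol.
#'
#' @param model `"csf"` or `"gaf"`.
#' @param parameters Named list, one entry per model parameter, each a list
#'   with `range = c(lo, hi)`, `grid` (node count), and optionally `spacing`
#'   (`"linear"` or `"log10"`; defaults to `"log10"` for CSF parameters,
#'   whose ranges span orders of magnitude, and `"linear"` for GAF).
#' @param stimuli Named list per stimulus component with `range` and `grid`.
#' @param truth Named true parameter point; must lie inside the parameter
#'   ranges but need not be a grid node (the virtual subject is evaluated at
#'   the continuous truth).
#' @param policy A `policy_config`, or a list with `kind`, `epsilon`,
#'   `trials`.
#' @param replications Number of repeated experiments, `>= 1`.
#' @param seed Base seed from which per-replication stream seeds are derived.
#' @param mu CSF lapse bound (ignored for GAF).
#' @param error_scale `"raw"` or `"log10"` squared-error scale.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("gaf", "csf"), parameters, stimuli,
                              truth, policy, replications = 100L, seed = 1L,
                              mu = 0.04, error_scale = c("raw", "log10")) {
  model <- match.arg(model)
  error_scale <- match.arg(error_scale)
  mod <- if (model == "csf") csf_model(mu) else gaf_model()
  if (!setequal(names(parameters), mod$param_names))
    stop("parameters must be exactly: ", paste(mod$param_names, collapse = ", "))
  if (!setequal(names(stimuli), mod$stimulus_names))
    stop("stimuli must be exactly: ", paste(mod$stimulus_names, collapse = ", "))
  parameters <- parameters[mod$param_names]
  stimuli <- stimuli[mod$stimulus_names]
  default_spacing <- if (model == "csf") "log10" else "linear"
  for (nm in names(parameters)) {
    p <- parameters[[nm]]
    if (is.null(p$range) || length(p$range) != 2 || p$range[1] >= p$range[2])
      stop("parameter '", nm, "' needs range = c(lo, hi) with lo < hi")
    if (is.null(p$grid) || p$grid < 2) stop("parameter '", nm, "' needs grid >= 2")
    if (is.null(p$spacing)) parameters[[nm]]$spacing <- default_spacing
    else if (!p$spacing %in% c("linear", "log10"))
      stop("parameter '", nm, "': spacing must be 'linear' or 'log10'")
  }
  for (nm in names(stimuli)) {
    s <- stimuli[[nm]]
    if (is.null(s$range) || length(s$range) != 2 || s$range[1] >= s$range[2])
      stop("stimulus '", nm, "' needs range = c(lo, hi) with lo < hi")
    if (is.null(s$grid) || s$grid < 2) stop("stimulus '", nm, "' needs grid >= 2")
  }
  truth <- unlist(truth)
  if (!setequal(names(truth), mod$param_names))
    stop("truth must name exactly: ", paste(mod$param_names, collapse = ", "))
  truth <- truth[mod$param_names]
  for (nm in names(truth)) {
    r <- parameters[[nm]]$range
    if (truth[nm] < r[1] || truth[nm] > r[2])
      stop("truth for '", nm, "' lies outside its range [", r[1], ", ", r[2], "]")
  }
  if (!inherits(policy, "policy_config"))
    policy <- policy_config(kind = policy$kind, epsilon = policy$epsilon,
                            trials = policy$trials)
  replications <- as.integer(replications)
  if (is.na(replications) || replications < 1) stop("replications must be >= 1")
  structure(list(model = model, parameters = parameters, stimuli = stimuli,
                 truth = truth, policy = policy, replications = replications,
                 seed = as.integer(seed), mu = mu, error_scale = error_scale),
            class = "experiment_config")
}

# Instantiate model, grids and (optionally) the likelihood table a config
# describes. The table is the expensive part for the CSF grid, so callers
# that run several policies on one configuration build it once and share it.
.build_components <- function(config, table = TRUE) {
  mod <- if (config$model == "csf") csf_model(config$mu) else gaf_model()
  grid <- build_parameter_grid(
    ranges = lapply(config$parameters, `[[`, "range"),
    sizes = vapply(config$parameters, `[[`, numeric(1), "grid"),
    spacing = vapply(config$parameters, `[[`, character(1), "spacing"))
  stim <- build_stimulus_grid(
    ranges = lapply(config$stimuli, `[[`, "range"),
    sizes = vapply(config$stimuli, `[[`, numeric(1), "grid"))
  list(model = mod, grid = grid, stimuli = stim,
       table = if (table) precompute_likelihoods(mod, grid, stim))
}

#' Draw one binary response from the virtual subject
#'
#' @param rng A stream from [rng_stream()].
#' @param model A `psychometric_model`.
#' @param truth Named true parameter point (continuous; not snapped to the
#'   grid).
#' @param stimulus One stimulus point (numeric vector).
#' @return 1 with probability `response_prob(truth, stimulus)`, else 0.
#' @export
simulate_response <- function(rng, model, truth, stimulus) {
  p <- model$response_prob(.param_matrix(unlist(truth), model$param_names),
                           stimulus)
  as.integer(rng$runif(1) < p)
}

# Aggregate a list of per-replication trial logs into trajectory summaries.
.aggregate_logs <- function(logs, param_names, elapsed, config) {
  T <- nrow(logs[[1]])
  R <- length(logs)
  ent <- vapply(logs, function(l) l$entropy_bits, numeric(T))
  expl <- vapply(logs, function(l) l$strategy == "exploit", logical(T))
  se_cols <- paste0("se_", param_names)
  mse <- matrix(0, T, length(param_names), dimnames = list(NULL, param_names))
  for (l in logs) mse <- mse + as.matrix(l[, se_cols])
  mse <- mse / R
  counts <- vapply(logs, exploitation_count, numeric(1))
  slack <- max(vapply(logs, function(l) attr(l, "theorem1_slack"), numeric(1)))
  structure(list(
    trials = T, replications = R,
    mean_entropy_bits = rowMeans(matrix(ent, nrow = T)),
    mean_mse = mse,
    exploit_fraction = rowMeans(matrix(expl, nrow = T)),
    exploit_counts = counts,
    mean_exploit_count = mean(counts),
    theorem1_max_slack = slack,
    elapsed_sec = elapsed,
    config = config
  ), class = "aggregate_trajectory")
}

# Lockstep engine: advances all replications one trial at a time so the
# information sweep for every replication still exploring is a single
# matrix-matrix product against the shared likelihood table. Draw-for-draw
# equivalent to looping run_experiment() over replications with the same
# per-replication seeds (each replication owns its two streams and consumes
# them in the same order), which the test suite checks directly.
.run_replications_batch <- function(config, comps, seeds, keep_logs) {
  model <- comps$model; grid <- comps$grid; stimuli <- comps$stimuli
  table <- comps$table
  policy <- config$policy
  T <- policy$trials
  R <- config$replications
  n <- grid$node_count
  m <- stimuli$point_count
  k <- length(model$param_names)

  rng_pol <- lapply(seeds[, "policy"], rng_stream)
  rng_sub <- lapply(seeds[, "subject"], rng_stream)
  truth <- config$truth
  truth_prob <- vapply(seq_len(m), function(j)
    model$response_prob(.param_matrix(truth, model$param_names),
                        stimuli$points[j, ]), numeric(1))
  truth_err <- .error_coords(truth, grid, config$error_scale)

  P <- matrix(1 / n, n, R)
  strat_exploit <- matrix(FALSE, T, R)
  jmat <- matrix(0L, T, R)
  ymat <- matrix(0L, T, R)
  entmat <- matrix(0, T, R)
  mimat <- matrix(NA_real_, T, R)
  est_arr <- if (keep_logs) array(NA_real_, c(T, R, k))
  mse_sum <- matrix(0, T, k, dimnames = list(NULL, model$param_names))
  slack <- -Inf

  for (t in seq_len(T)) {
    H <- -colSums(P * .log2c(P))
    entmat[t, ] <- H
    exploit <- switch(policy$kind,
      classical = rep(FALSE, R),
      random = rep(TRUE, R),
      ee = H <= policy$epsilon)
    strat_exploit[t, ] <- exploit
    j <- integer(R)
    if (any(!exploit)) {
      idx <- which(!exploit)
      Q <- crossprod(table$prob, P[, idx, drop = FALSE])
      S <- crossprod(table$bent, P[, idx, drop = FALSE])
      MI <- pmax(binary_entropy(Q) - S, 0)
      # same 1e-10-bit argmax quantization as information_sweep()
      jx <- max.col(round(t(MI), 10), ties.method = "first")
      maxmi <- MI[cbind(jx, seq_along(idx))]
      over <- maxmi - H[idx]
      slack <- max(slack, max(over))
      if (any(over > 1e-9))
        stop(sprintf("entropy bound violated at trial %d: max MI exceeds H by %.3e",
                     t, max(over)))
      j[idx] <- jx
      mimat[t, idx] <- maxmi
    }
    if (any(exploit))
      for (r in which(exploit)) j[r] <- rng_pol[[r]]$sample_int(m)
    u <- vapply(rng_sub, function(s) s$runif(1), numeric(1))
    y <- as.integer(u < truth_prob[j])
    jmat[t, ] <- j
    ymat[t, ] <- y
    Lc <- table$prob[, j, drop = FALSE]
    if (any(y == 0L)) {
      z <- y == 0L
      Lc[, z] <- 1 - Lc[, z]
    }
    P <- P * Lc
    cs <- colSums(P)
    if (any(cs <= 0))
      stop("posterior update impossible in replication ", which(cs <= 0)[1])
    P <- P / rep(cs, each = n)
    Et <- crossprod(P, grid$nodes_t)
    islog <- grid$spacing == "log10"
    Et[, islog] <- 10^Et[, islog]
    if (keep_logs) est_arr[t, , ] <- Et
    err_est <- if (config$error_scale == "log10") log10(Et) else Et
    mse_sum[t, ] <- rowSums((t(err_est) - truth_err)^2) / R
  }

  logs <- NULL
  if (keep_logs) {
    logs <- lapply(seq_len(R), function(r) {
      stim_cols <- stimuli$points[jmat[, r], , drop = FALSE]
      colnames(stim_cols) <- model$stimulus_names
      est <- matrix(est_arr[, r, ], T, k, dimnames = list(NULL, model$param_names))
      err_est <- if (config$error_scale == "log10") log10(est) else est
      se <- t((t(err_est) - truth_err)^2)
      rec <- data.frame(
        trial = seq_len(T),
        strategy = ifelse(strat_exploit[, r], "exploit", "explore"),
        stimulus_index = jmat[, r], stim_cols,
        response = ymat[, r], entropy_bits = entmat[, r],
        max_mi_bits = mimat[, r],
        stats::setNames(as.data.frame(est), paste0("est_", model$param_names)),
        stats::setNames(as.data.frame(se), paste0("se_", model$param_names)))
      attr(rec, "theorem1_slack") <-
        if (all(strat_exploit[, r])) -Inf
        else max(mimat[, r] - entmat[, r], na.rm = TRUE)
      rec
    })
  }

  structure(list(
    trials = T, replications = R,
    mean_entropy_bits = rowMeans(entmat),
    mean_mse = mse_sum,
    exploit_fraction = rowMeans(strat_exploit),
    exploit_counts = colSums(strat_exploit),
    mean_exploit_count = mean(colSums(strat_exploit)),
    theorem1_max_slack = slack,
    elapsed_sec = NA_real_,
    config = config,
    logs = logs
  ), class = "aggregate_trajectory")
}

#' Run repeated seeded experiments and aggregate trajectories
#'
#' Repeats the experiment `config$replications` times with per-replication
#' seed pairs derived deterministically from the base seed, and aggregates
#' per-trial means across replications: entropy, per-parameter MSE (the
#' average of squared errors across replications), and the fraction of
#' replications exploiting on each trial.
#'
#' @param config An `experiment_config`.
#' @param engine `"batch"` (default; all replications advance in lockstep so
#'   explore-trial information sweeps share one matrix product) or `"loop"`
#'   (replications run one at a time through [run_experiment()]). Both
#'   produce identical results for identical seeds.
#' @param keep_logs Keep the per-replication trial logs (`$logs`)? Off by
#'   default to bound memory.
#' @param .components Prebuilt model/grids/likelihood table (internal reuse).
#' @return An object of class `aggregate_trajectory` with per-trial arrays
#'   `mean_entropy_bits`, `mean_mse` (trial-by-parameter), `exploit_fraction`,
#'   per-replication `exploit_counts`, `mean_exploit_count`,
#'   `theorem1_max_slack` (largest observed max-MI minus entropy over all
#'   explore trials), informational `elapsed_sec`, and the `config`.
#' @export
run_replications <- function(config, engine = c("batch", "loop"),
                             keep_logs = FALSE, .components = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "experiment_config"))
  comps <- if (is.null(.components)) .build_components(config) else .components
  seeds <- .replication_seeds(config$seed, config$replications)
  t0 <- proc.time()[["elapsed"]]
  if (engine == "batch") {
    agg <- .run_replications_batch(config, comps, seeds, keep_logs)
  } else {
    logs <- lapply(seq_len(config$replications), function(r)
      run_experiment(comps$model, comps$grid, comps$stimuli, comps$table,
                     config$policy, config$truth,
                     policy_seed = seeds[r, "policy"],
                     subject_seed = seeds[r, "subject"],
                     error_scale = config$error_scale))
    agg <- .aggregate_logs(logs, comps$model$param_names, NA_real_, config)
    if (keep_logs) agg$logs <- logs
  }
  agg$elapsed_sec <- proc.time()[["elapsed"]] - t0
  agg
}

#' Head-to-head policy comparison with shared random streams
#'
#' Runs the exploration-exploitation policy and the classical always-explore
#' policy on one configuration with identical per-replication seeds (common
#' random numbers: both policies see the same subject stream, and trials
#' before the entropy threshold is reached produce identical stimuli and
#' responses). The likelihood table is built once and shared.
#'
#' @param config An `experiment_config` whose policy has `kind = "ee"` (its
#'   `epsilon` defines the switch for the EE arm).
#' @param config_classical Optional explicit classical-arm configuration; it
#'   must equal `config` in everything but the policy kind. By default it is
#'   derived from `config`.
#' @param keep_logs Passed through to [run_replications()].
#' @return List with `ee` and `classical` (`aggregate_trajectory` objects)
#'   and `summary`: final-trial per-parameter MSE for both arms, their ratio
#'   (`ee / classical`), mean exploitation counts, and informational
#'   wall-clock seconds per arm.
#' @export
compare_policies <- function(config, config_classical = NULL, keep_logs = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$policy$kind != "ee")
    stop("compare_policies expects config$policy$kind == 'ee'")
  if (is.null(config_classical)) {
    config_classical <- config
    config_classical$policy <- policy_config("classical",
                                             trials = config$policy$trials)
  } else {
    a <- config; b <- config_classical
    a$policy <- b$policy <- NULL
    if (!identical(a, b))
      stop("configurations differ beyond the policy")
    if (config_classical$policy$kind != "classical")
      stop("second configuration must use the classical policy")
  }
  comps <- .build_components(config)
  ee <- run_replications(config, keep_logs = keep_logs, .components = comps)
  cl <- run_replications(config_classical, keep_logs = keep_logs,
                         .components = comps)
  Tf <- config$policy$trials
  final_ee <- ee$mean_mse[Tf, ]
  final_cl <- cl$mean_mse[Tf, ]
  list(ee = ee, classical = cl,
       summary = list(
         final_mse_ee = final_ee,
         final_mse_classical = final_cl,
         final_mse_ratio = final_ee / final_cl,
         mean_exploit_count_ee = ee$mean_exploit_count,
         mean_exploit_count_classical = cl$mean_exploit_count,
         elapsed_sec_ee = ee$elapsed_sec,
         elapsed_sec_classical = cl$elapsed_sec))
}

#' @export
print.aggregate_trajectory <- function(x, ...) {
  cat(sprintf("<aggregate_trajectory> %s, policy %s: %d trials x %d replications\n",
              x$config$model, x$config$policy$kind, x$trials, x$replications))
  cat(sprintf("  final mean entropy: %.4f bits; mean exploit count: %.1f\n",
              x$mean_entropy_bits[x$trials], x$mean_exploit_count))
  cat("  final per-parameter MSE:",
      paste(sprintf("%s=%.4g", colnames(x$mean_mse), x$mean_mse[x$trials, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s: %d trials, policy %s%s, %d replications, seed %d\n",
              x$model, x$policy$trials, x$policy$kind,
              if (x$policy$kind == "ee") sprintf(" (epsilon = %g bits)", x$policy$epsilon) else "",
              x$replications, x$seed))
  invisible(x)
}
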