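# Discrete Bayes over a parameter grid: grid construction, uniform prior,
# likelihood precomputation, posterior update, posterior-mean estimator and
# squared error.

.axis_nodes <- function(lo, hi, size, spacing) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) stop("range must satisfy lo < hi")
  if (size < 2 || size != round(size)) stop("axis size must be an integer >= 2")
  switch(spacing,
    linear = seq(lo, hi, length.out = size),
    log10  = {
      if (lo <= 0) stop("log10 spacing requires a strictly positive range")
      10^seq(log10(lo), log10(hi), length.out = size)
    },
    stop("spacing must be 'linear' or 'log10'")
  )
}

#' Discretize the parameter space
#'
#' Builds the finite parameter grid on which the posterior lives: the
#' Cartesian product of per-parameter node axes. Each axis spans its range
#' endpoints inclusively, spaced linearly or log10-equispaced.
#'
#' @param ranges Named list of `c(lo, hi)` per parameter (natural units).
#' @param sizes Node counts per axis (recycled if length 1).
#' @param spacing `"linear"` or `"log10"` per axis (recycled if length 1).
#' @return An object of class `parameter_grid` with members `axes` (named
#'   list of node coordinates), `nodes` (node-by-parameter matrix, natural
#'   units), `nodes_t` (same nodes on each axis's spacing scale: log10
#'   coordinates for log axes), `spacing`, and `node_count`.
#' @export
#' @examples
#' g <- build_parameter_grid(list(t_cr = c(5, 10), sigma = c(1, 4)), 20)
#' g$node_count  # 400
build_parameter_grid <- function(ranges, sizes, spacing = "linear") {
  if (is.null(names(ranges)) || any(names(ranges) == ""))
    stop("ranges must be a named list")
  k <- length(ranges)
  sizes <- rep_len(as.integer(sizes), k)
  spacing <- rep_len(spacing, k)
  axes <- mapply(function(r, s, sp) .axis_nodes(r[1], r[2], s, sp),
                 ranges, sizes, spacing, SIMPLIFY = FALSE)
  nodes <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(nodes) <- names(ranges)
  nodes_t <- nodes
  for (j in seq_len(k)) if (spacing[j] == "log10") nodes_t[, j] <- log10(nodes[, j])
  structure(list(axes = axes, nodes = nodes, nodes_t = nodes_t,
                 spacing = stats::setNames(spacing, names(ranges)),
                 node_count = nrow(nodes)),
            class = "parameter_grid")
}

#' Discretize the stimulus space
#'
#' @param ranges Named list of `c(lo, hi)` per stimulus component.
#' @param sizes Point counts per component (recycled if length 1).
#' @return An object of class `stimulus_grid` with `points` (point-by-component
#'   matrix, Cartesian product for multi-component stimuli) and `point_count`.
#' @export
build_stimulus_grid <- function(ranges, sizes) {
  g <- build_parameter_grid(ranges, sizes, spacing = "linear")
  structure(list(axes = g$axes, points = g$nodes, point_count = g$node_count),
            class = "stimulus_grid")
}

#' Uniform prior over grid nodes
#'
#' Equal mass `1 / node_count` on every node (uniform on the node set; on a
#' log-spaced axis this is not a uniform density in natural units).
#'
#' @param grid A `parameter_grid`.
#' @return An object of class `posterior_state`: list with `mass`
#'   (probability per node, sums to 1) and `trial_index` (0 before any data).
#' @export
uniform_prior <- function(grid) {
  n <- grid$node_count
  structure(list(mass = rep(1 / n, n), trial_index = 0L),
            class = "posterior_state")
}

.state_mass <- function(state) {
  if (inherits(state, "posterior_state")) state$mass else as.numeric(state)
}

#' Precompute the likelihood table over both grids
#'
#' Evaluates the model's probability of `y = 1` for every (parameter node,
#' stimulus point) pair once, so that trial loops and replications reuse the
#' same table. The per-entry binary response entropy is tabulated alongside,
#' which reduces the per-trial information sweep to two matrix-vector
#' products.
#'
#' @param model A `psychometric_model`.
#' @param grid A `parameter_grid`.
#' @param stimuli A `stimulus_grid`.
#' @return An object of class `likelihood_table`: list with `prob`
#'   (node-by-stimulus matrix of P(y=1)), `bent` (elementwise binary entropy
#'   of `prob`, bits), `node_count`, `point_count`.
#' @export
precompute_likelihoods <- function(model, grid, stimuli) {
  n <- grid$node_count
  m <- stimuli$point_count
  prob <- matrix(NA_real_, n, m)
  bent <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    pj <- model$response_prob(grid$nodes, stimuli$points[j, ])
    if (any(!is.finite(pj)) || any(pj < 0 | pj > 1)) {
      bad <- which(!is.finite(pj) | pj < 0 | pj > 1)[1]
      stop(sprintf("model '%s' returned an invalid probability at node %d, stimulus %d",
                   model$name, bad, j))
    }
    prob[, j] <- pj
    bent[, j] <- binary_entropy(pj)
  }
  structure(list(prob = prob, bent = bent, node_count = n, point_count = m),
            class = "likelihood_table")
}

#' Bayes update of the grid posterior
#'
#' Multiplies the current mass by the Bernoulli likelihood of the observed
#' response at the applied stimulus and renormalizes. Functionally pure: the
#' input state is not modified.
#'
#' @param state A `posterior_state`.
#' @param lik_column Per-node probability of `y = 1` at the applied stimulus
#'   (a column of the likelihood table).
#' @param y Observed binary response (0 or 1).
#' @return A new `posterior_state` with `trial_index` incremented.
#' @export
posterior_update <- function(state, lik_column, y) {
  mass <- .state_mass(state)
  if (length(lik_column) != length(mass))
    stop("lik_column length must match the number of grid nodes")
  w <- mass * likelihood(lik_column, y)
  z <- sum(w)
  if (z <= 0)
    stop("posterior update impossible: observed response has zero probability under the prior support")
  ti <- if (inherits(state, "posterior_state")) state$trial_index else 0L
  structure(list(mass = w / z, trial_index = ti + 1L), class = "posterior_state")
}

#' Posterior-mean (MEAN) estimate
#'
#' Component-wise posterior mean of the node coordinates, taken on each
#' axis's spacing scale: linear axes average natural coordinates; log10 axes
#' average log10 coordinates and map back, so the uniform-prior estimate is
#' the midpoint of each range on its own scale.
#'
#' @param state A `posterior_state` (or bare mass vector).
#' @param grid The `parameter_grid` the state lives on.
#' @return Named numeric parameter point in natural units.
#' @export
estimate_mean <- function(state, grid) {
  mass <- .state_mass(state)
  m <- as.numeric(crossprod(grid$nodes_t, mass))
  names(m) <- colnames(grid$nodes)
  islog <- grid$spacing == "log10"
  m[islog] <- 10^m[islog]
  m
}

#' Per-parameter squared error
#'
#' @param estimate,truth Parameter points of equal dimension.
#' @return `(estimate - truth)^2` per component; their sum is the squared
#'   Euclidean distance used as the scalar mean squared error.
#' @export
squared_error <- function(estimate, truth) {
  estimate <- unlist(estimate); truth <- unlist(truth)
  if (length(estimate) != length(truth))
    stop("estimate and truth must have the same dimension")
  (estimate - truth)^2
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("<parameter_grid>", x$node_count, "nodes\n")
  for (nm in names(x$axes))
    cat(sprintf("  %s: %d nodes in [%g, %g] (%s)\n", nm, length(x$axes[[nm]]),
                min(x$axes[[nm]]), max(x$axes[[nm]]), x$spacing[[nm]]))
  invisible(x)
}

#' @export
print.posterior_state <- function(x, ...) {
  cat("<posterior_state>", length(x$mass), "nodes, trial", x$trial_index,
      sprintf("; H = %.4f bits\n", parameter_entropy(x)))
  invisible(x)
}
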