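# Small in-code fixtures shared across test files.

# Compact GAF configuration: coarse grids and few trials, for fast tests.
small_gaf_config <- function(kind = "ee", epsilon = 4.5, trials = 40L,
                             replications = 5L, seed = 42L,
                             truth = c(t_cr = 7.3, sigma = 2.2804)) {
  experiment_config(
    model = "gaf",
    parameters = list(t_cr = list(range = c(5, 10), grid = 8),
                      sigma = list(range = c(1, 4), grid = 8)),
    stimuli = list(gap = list(range = c(4, 12), grid = 9)),
    truth = truth,
    policy = policy_config(kind, epsilon = epsilon, trials = trials),
    replications = replications, seed = seed)
}

paper_gaf_components <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- load_config(bundled_config("gaf_paper"))
      cache <<- eebae:::.build_components(cfg)
    }
    cache
  }
})

# Random small posterior/likelihood instances for property tests.
random_instance <- function(n) {
  mass <- stats::rexp(n)
  mass <- mass / sum(mass)
  list(mass = mass, lik = stats::runif(n))
}
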