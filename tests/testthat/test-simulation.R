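test_that("virtual subject matches the model's response probability", {
  model <- gaf_model()
  truth <- c(t_cr = 7.3, sigma = 2.2804)
  rng <- rng_stream(13)
  ys <- vapply(1:100000, function(i)
    simulate_response(rng, model, truth, 7.3), integer(1))
  se3 <- 3 * sqrt(0.25 / length(ys))
  expect_lt(abs(mean(ys) - 0.5), se3)
  # degenerate probabilities
  cm <- structure(list(name = "c", param_names = "a", stimulus_names = "x",
                       response_prob = function(theta, stimulus) 1),
                  class = "psychometric_model")
  expect_true(all(vapply(1:50, function(i)
    simulate_response(rng, cm, c(a = 1), 0), integer(1)) == 1L))
})

test_that("experiment_config validates truth, ranges and replication counts", {
  expect_error(small_gaf_config(truth = c(t_cr = 11, sigma = 2)), "outside")
  cfg <- small_gaf_config()
  expect_error(experiment_config("gaf", cfg$parameters, cfg$stimuli,
                                 c(t_cr = 7, wrong = 1), cfg$policy),
               "truth")
  expect_error(experiment_config("gaf", cfg$parameters, cfg$stimuli,
                                 cfg$truth, cfg$policy, replications = 0),
               "replications")
})

test_that("replication seeds are distinct and derived reproducibly", {
  s1 <- eebae:::.replication_seeds(42L, 50L)
  s2 <- eebae:::.replication_seeds(42L, 50L)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(as.vector(s1)), 0L)
  expect_false(identical(s1, eebae:::.replication_seeds(43L, 50L)))
})

test_that("batch and loop engines produce identical trajectories and logs", {
  cfg <- small_gaf_config(trials = 35L, replications = 6L, seed = 17L)
  a <- run_replications(cfg, engine = "batch", keep_logs = TRUE)
  b <- run_replications(cfg, engine = "loop", keep_logs = TRUE)
  expect_equal(a$mean_entropy_bits, b$mean_entropy_bits)
  expect_equal(a$mean_mse, b$mean_mse)
  expect_equal(a$exploit_counts, b$exploit_counts)
  for (r in seq_along(a$logs)) {
    la <- a$logs[[r]]; lb <- b$logs[[r]]
    attr(la, "theorem1_slack") <- attr(lb, "theorem1_slack") <- NULL
    expect_equal(la, lb, tolerance = 1e-12)
  }
})

test_that("single-replication aggregate equals the run's own trajectory", {
  cfg <- small_gaf_config(trials = 25L, replications = 1L, seed = 5L)
  agg <- run_replications(cfg, keep_logs = TRUE)
  log <- agg$logs[[1]]
  expect_equal(agg$mean_entropy_bits, log$entropy_bits)
  expect_equal(agg$mean_mse[, "t_cr"], log$se_t_cr)
  expect_equal(agg$exploit_fraction, as.numeric(log$strategy == "exploit"))
  expect_equal(agg$mean_exploit_count, exploitation_count(log))
})

test_that("same base seed reproduces aggregates; MSE falls with trials", {
  # truth off the prior midpoint so both parameters start with sizeable error
  cfg <- small_gaf_config(trials = 120L, replications = 200L, seed = 31L,
                          truth = c(t_cr = 8.7, sigma = 1.6))
  cfg$parameters$t_cr$grid <- 20L; cfg$parameters$sigma$grid <- 20L
  cfg$stimuli$gap$grid <- 25L
  a <- run_replications(cfg)
  b <- run_replications(cfg)
  expect_identical(a$mean_entropy_bits, b$mean_entropy_bits)
  expect_identical(a$mean_mse, b$mean_mse)
  # convergence: final MSE below initial for both parameters
  expect_lt(a$mean_mse[120, "t_cr"], a$mean_mse[1, "t_cr"])
  expect_lt(a$mean_mse[120, "sigma"], a$mean_mse[1, "sigma"])
  # and decreasing through the run
  expect_lt(a$mean_mse[120, "t_cr"], a$mean_mse[60, "t_cr"])
})

test_that("critical-gap mean converges faster than the spread parameter", {
  cfg <- load_config(bundled_config("gaf_paper"))
  cfg$replications <- 200L
  agg <- run_replications(cfg)
  # trials until the MSE first halves its initial value (Inf if never)
  half_life <- function(mse) {
    hit <- which(mse <= mse[1] / 2)[1]
    if (is.na(hit)) Inf else hit
  }
  expect_lt(half_life(agg$mean_mse[, "t_cr"]),
            half_life(agg$mean_mse[, "sigma"]))
})

test_that("compare_policies shares seeds and reports the head-to-head summary", {
  cfg <- small_gaf_config(trials = 50L, replications = 20L, seed = 61L)
  cmp <- compare_policies(cfg)
  expect_s3_class(cmp$ee, "aggregate_trajectory")
  expect_s3_class(cmp$classical, "aggregate_trajectory")
  expect_identical(cmp$classical$mean_exploit_count, 0)
  expect_length(cmp$summary$final_mse_ratio, 2)
  # identical-policy comparison with the same seeds gives ratio exactly 1
  cfg_cl <- cfg; cfg_cl$policy <- policy_config("classical", trials = 50L)
  a <- run_replications(cfg_cl)
  b <- run_replications(cfg_cl)
  expect_equal(a$mean_mse[50, ] / b$mean_mse[50, ], c(t_cr = 1, sigma = 1))
  # before the switch, ee and classical see identical stimuli and responses
  cmp2 <- compare_policies(small_gaf_config(trials = 10L, epsilon = 2,
                                            replications = 3L, seed = 71L),
                           keep_logs = TRUE)
  pre <- cmp2$ee$logs[[1]]$strategy == "explore"
  expect_true(all(pre[1:5]))
  expect_identical(cmp2$ee$logs[[1]]$stimulus_index[pre],
                   cmp2$classical$logs[[1]]$stimulus_index[pre])
  expect_identical(cmp2$ee$logs[[1]]$response[pre],
                   cmp2$classical$logs[[1]]$response[pre])
  # mismatched configurations beyond the policy are rejected
  other <- small_gaf_config(trials = 50L, replications = 20L, seed = 62L)
  other$policy <- policy_config("classical", trials = 50L)
  expect_error(compare_policies(cfg, other), "differ beyond the policy")
})

test_that("exploitation_count counts exploit trials", {
  cfg <- small_gaf_config(kind = "random", epsilon = NULL, trials = 30L,
                          replications = 1L, seed = 3L)
  agg <- run_replications(cfg, keep_logs = TRUE)
  expect_identical(exploitation_count(agg$logs[[1]]), 30L)
  cfg$policy <- policy_config("classical", trials = 30L)
  agg2 <- run_replications(cfg, keep_logs = TRUE)
  expect_identical(exploitation_count(agg2$logs[[1]]), 0L)
})
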