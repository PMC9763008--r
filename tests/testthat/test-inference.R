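test_that("parameter grids have requested node counts with endpoints included", {
  g <- build_parameter_grid(list(t_cr = c(5, 10), sigma = c(1, 4)), 20)
  expect_equal(g$node_count, 400)
  expect_equal(range(g$axes$t_cr), c(5, 10))
  expect_equal(range(g$axes$sigma), c(1, 4))
  expect_true(all(vapply(g$axes, function(a) all(diff(a) > 0), logical(1))))

  g2 <- build_parameter_grid(list(a = c(0, 1)), 2)
  expect_equal(g2$axes$a, c(0, 1))

  g4 <- build_parameter_grid(
    list(gamma_max = c(2, 2000), f_max = c(0.2, 100),
         beta1 = c(2, 128), delta1 = c(0.2, 3)),
    c(4, 4, 4, 4), spacing = "log10")
  expect_equal(g4$node_count, 256)
  expect_equal(g4$nodes_t[, "gamma_max"], log10(g4$nodes[, "gamma_max"]))

  expect_error(build_parameter_grid(list(a = c(1, 0)), 5), "lo < hi")
  expect_error(build_parameter_grid(list(a = c(0, 1)), 1), ">= 2")
})

test_that("uniform prior has equal mass and closed-form entropy", {
  g <- build_parameter_grid(list(t_cr = c(5, 10), sigma = c(1, 4)), 20)
  st <- uniform_prior(g)
  expect_equal(st$mass, rep(0.0025, 400))
  expect_equal(st$trial_index, 0L)
  expect_equal(parameter_entropy(st), log2(400), tolerance = 1e-12)
})

test_that("likelihood table matches direct model calls and model monotonicity", {
  comps <- paper_gaf_components()
  tab <- comps$table
  expect_equal(dim(tab$prob), c(400, 25))
  i <- which(comps$grid$nodes[, "t_cr"] == comps$grid$axes$t_cr[10] &
             comps$grid$nodes[, "sigma"] == comps$grid$axes$sigma[5])
  j <- 17
  expect_equal(tab$prob[i, j],
               gaf_response_prob(comps$grid$nodes[i, ],
                                 comps$stimuli$points[j, 1]))
  # each row monotone in gap
  expect_true(all(apply(tab$prob[sample.int(400, 20), ], 1,
                        function(r) all(diff(r) > 0))))
  # constant model gives constant table
  const_model <- structure(list(name = "const", param_names = "a",
                                stimulus_names = "x",
                                response_prob = function(theta, stimulus)
                                  rep(0.5, nrow(theta))),
                           class = "psychometric_model")
  cg <- build_parameter_grid(list(a = c(0, 1)), 3)
  cs <- build_stimulus_grid(list(x = c(0, 1)), 4)
  ct <- precompute_likelihoods(const_model, cg, cs)
  expect_true(all(ct$prob == 0.5))
  expect_equal(ct$bent, matrix(1, 3, 4))
})

test_that("posterior update follows Bayes rule, is pure, and preserves support", {
  g <- build_parameter_grid(list(a = c(0, 1)), 2)
  st <- uniform_prior(g)
  up1 <- posterior_update(st, c(0.2, 0.8), 1)
  expect_equal(up1$mass, c(0.2, 0.8))
  expect_equal(up1$trial_index, 1L)
  up0 <- posterior_update(st, c(0.2, 0.8), 0)
  expect_equal(up0$mass, c(0.8, 0.2))
  # input state untouched
  expect_equal(st$mass, c(0.5, 0.5))
  # uninformative column leaves the posterior unchanged
  expect_equal(posterior_update(st, c(0.7, 0.7), 1)$mass, st$mass)
  # zero-mass nodes stay at zero
  st2 <- structure(list(mass = c(0, 0.5, 0.5), trial_index = 0L),
                   class = "posterior_state")
  up2 <- posterior_update(st2, c(0.9, 0.4, 0.6), 1)
  expect_identical(up2$mass[1], 0)
  # impossible response errors
  expect_error(posterior_update(st2, c(1, 0, 0), 1), "impossible")
})

test_that("normalization survives 1e4 chained updates to within 1e-12", {
  set.seed(11)
  n <- 50
  st <- structure(list(mass = rep(1 / n, n), trial_index = 0L),
                  class = "posterior_state")
  for (i in 1:10000) {
    lik <- runif(n, 0.05, 0.95)
    st <- posterior_update(st, lik, sample(0:1, 1))
    if (i %% 1000 == 0) expect_lt(abs(sum(st$mass) - 1), 1e-12)
  }
  expect_lt(abs(sum(st$mass) - 1), 1e-12)
  expect_equal(st$trial_index, 10000L)
})

test_that("posterior mean estimator: point mass, midpoints, spacing scale", {
  g <- build_parameter_grid(list(t_cr = c(5, 10), sigma = c(1, 4)), 20)
  # point mass recovers the node exactly
  m <- rep(0, 400); m[137] <- 1
  expect_equal(estimate_mean(m, g), g$nodes[137, ])
  # uniform over two corner nodes -> midpoint
  i1 <- which(g$nodes[, 1] == 5 & g$nodes[, 2] == 1)
  i2 <- which(g$nodes[, 1] == 10 & g$nodes[, 2] == 4)
  m2 <- rep(0, 400); m2[c(i1, i2)] <- 0.5
  expect_equal(estimate_mean(m2, g), c(t_cr = 7.5, sigma = 2.5))
  # uniform prior -> per-axis midpoint on the spacing scale
  expect_equal(estimate_mean(uniform_prior(g), g), c(t_cr = 7.5, sigma = 2.5))
  glog <- build_parameter_grid(list(gamma_max = c(2, 2000)), 20,
                               spacing = "log10")
  expect_equal(estimate_mean(uniform_prior(glog), glog),
               c(gamma_max = sqrt(2 * 2000)))
})

test_that("squared error is per-parameter and sums to squared distance", {
  expect_equal(squared_error(c(7.3, 2.2804), c(7.3, 2.2804)), c(0, 0))
  se <- squared_error(c(7.5, 2.5), c(7.3, 2.2804))
  expect_equal(se, c(0.2^2, (2.5 - 2.2804)^2))
  expect_equal(sum(se), sum((c(7.5, 2.5) - c(7.3, 2.2804))^2))
  expect_error(squared_error(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("update and entropy are invariant under node permutation", {
  set.seed(21)
  n <- 30
  inst <- random_instance(n)
  perm <- sample.int(n)
  up <- posterior_update(inst$mass, inst$lik, 1)
  upp <- posterior_update(inst$mass[perm], inst$lik[perm], 1)
  expect_equal(up$mass[perm], upp$mass)
  expect_equal(parameter_entropy(inst$mass), parameter_entropy(inst$mass[perm]))
})
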