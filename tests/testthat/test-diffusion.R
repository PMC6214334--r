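test_that("model_params validates kinds and ranges", {
  p <- model_params("threshold", tau = 0.2)
  expect_s3_class(p, "model_params")
  expect_error(model_params("sir"), class = "contagion_param_error")
  expect_error(model_params("profile", gamma = 1.5),
               class = "contagion_param_error")
  expect_error(model_params("profile", blocking_p = -0.1),
               class = "contagion_param_error")
})

test_that("initialize_state seeds the ledger at iteration 0", {
  tri <- igraph::make_ring(3)
  st <- initialize_state(tri, 1)
  expect_equal(unname(status_counts(st)), c(2, 1, 0))
  expect_equal(st$iteration, 0L)
  expect_equal(st$cnt, c(0, 1, 1))
  expect_error(initialize_state(tri, 5), class = "contagion_param_error")
  # saturation: seeding all of V leaves the trend constant at 1
  r <- run_diffusion(tri, model_params("threshold", tau = 0.5), 1:3, 3)
  expect_equal(r$trend, rep(1, 4))
})

test_that("min_infected_neighbors inverts the strict threshold rule", {
  expect_equal(min_infected_neighbors(13, 0.2), 3L)
  expect_equal(min_infected_neighbors(13, 0), 1L)
  expect_equal(min_infected_neighbors(10, 0.5), 6L)
  expect_true(is.na(min_infected_neighbors(13, 1)))
  expect_true(is.na(min_infected_neighbors(0, 0.2)))
  expect_equal(min_infected_neighbors(c(13, 10), c(0.2, 0.5)), c(3L, 6L))
  # agrees with a linear scan over every (degree, tau) pair
  for (d in 1:20) for (tau in seq(0, 1, by = 0.05)) {
    ks <- which((seq_len(d) / d) > tau)
    expect_identical(min_infected_neighbors(d, tau),
                     if (length(ks)) ks[1] else NA_integer_)
  }
})

test_that("profile_trial adopts iff the draw is at least gamma", {
  expect_true(profile_trial(0, 0))     # gamma 0: always adopt
  expect_true(profile_trial(0.8, 0.8)) # boundary draw adopts
  expect_false(profile_trial(0.8, 0.79))
  expect_false(profile_trial(1, 0.999))
})

test_that("threshold steps follow the hand-simulated path cascade", {
  g <- path_graph(3) # A-B-C
  p <- model_params("threshold", tau = 0.4)
  st <- initialize_state(g, 1)
  st <- threshold_step(st, p)
  expect_equal(which(st$status == 1L), c(1L, 2L)) # B: 1/2 > 0.4
  expect_equal(st$last_record$newly_infected, 2L)
  st <- threshold_step(st, p)
  expect_equal(which(st$status == 1L), 1:3)       # C: 1/1 > 0.4
  st <- threshold_step(st, p)
  expect_equal(st$last_record$newly_infected, integer(0))
  expect_equal(st$iteration, 3L)
})

test_that("a degree-13 node needs three infected neighbors at tau = 0.2", {
  g <- star_graph(13)
  p <- model_params("threshold", tau = 0.2)
  st2 <- threshold_step(initialize_state(g, c(2, 3)), p)
  expect_equal(st2$status[1], 0L) # 2/13 = 0.154 <= 0.2
  st3 <- threshold_step(initialize_state(g, c(2, 3, 4)), p)
  expect_equal(st3$status[1], 1L) # 3/13 = 0.231 > 0.2
})

test_that("spontaneous adoption is a binomial flip over susceptibles only", {
  g <- edgeless_graph(1000)
  st <- initialize_state(g, integer(0))
  set.seed(1)
  expect_identical(spontaneous_step(st, 0)$status, st$status)
  news <- vapply(1:200, function(i) {
    sum(spontaneous_step(st, 0.01)$status == 1L)
  }, numeric(1))
  se <- sd(news) / sqrt(200)
  expect_lt(abs(mean(news) - 10), 3 * se)
  # no susceptibles left: no-op
  full <- initialize_state(g, 1:1000)
  expect_identical(spontaneous_step(full, 0.5)$status, full$status)
})

test_that("profile model with gamma=1, blocking_p=1 freezes at the seed set", {
  g <- rand_gnp(100, 0.05, 1)
  r <- run_diffusion(g, model_params("profile", gamma = 1, blocking_p = 1),
                     seeds = 1:5, iterations = 5, rng_seed = 2)
  expect_equal(r$trend, rep(0.05, 6))
  # every exposed susceptible is blocked after its first refusal
  exposed <- setdiff(unique(unlist(
    igraph::adjacent_vertices(g, 1:5))), 1:5)
  expect_setequal(r$newly_blocked[[1]], exposed)
})

test_that("profile_threshold with tau=1 never peer-adopts", {
  g <- rand_gnp(100, 0.1, 3)
  r <- run_diffusion(g, model_params("profile_threshold", tau = 1, gamma = 0.1),
                     seeds = 1:5, iterations = 10, rng_seed = 4)
  expect_equal(r$trend, rep(0.05, 11))
  expect_equal(sum(r$records$new_blocked), 0) # gate failed: no trials, no blocks
})

test_that("runs are reproducible and the threshold model is seed-invariant", {
  g <- rand_gnp(200, 0.05, 5)
  pp <- model_params("profile", gamma = 0.5, blocking_p = 0.2)
  r1 <- run_diffusion(g, pp, 1:10, 10, rng_seed = 11)
  r2 <- run_diffusion(g, pp, 1:10, 10, rng_seed = 11)
  expect_identical(r1$trend, r2$trend)
  expect_identical(r1$newly_infected, r2$newly_infected)
  # deterministic model: different RNG seeds give bit-identical trends
  pt <- model_params("threshold", tau = 0.3)
  expect_identical(run_diffusion(g, pt, 1:10, 10, rng_seed = 1)$trend,
                   run_diffusion(g, pt, 1:10, 10, rng_seed = 2)$trend)
})

test_that("empty seed set warns unless spontaneous adoption is active", {
  g <- rand_gnp(50, 0.1, 6)
  expect_warning(run_diffusion(g, model_params("threshold", tau = 0.5),
                               integer(0), 3), "empty seed")
  expect_no_warning(run_diffusion(
    g, model_params("threshold", tau = 0.5, spontaneous_a = 0.1),
    integer(0), 3, rng_seed = 1))
})
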