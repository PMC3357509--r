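test_that("a perfect multiplexer chromosome has zero error and unit fitness", {
  mux <- generate_mux()
  net <- perfect_mux_net()
  expect_equal(forward_dataset(net, mux$features)[, 1], as.numeric(mux$labels))
  fit <- evaluate_fitness(encode_weights(net), net, NULL, mux)
  expect_equal(fit$mse, 0)
  expect_equal(fit$fitness, 1)
})

test_that("inert astrocytes reproduce the astrocyte-free fitness exactly", {
  set.seed(61)
  mux <- generate_mux()
  net <- mux_experiment_net()
  genes <- runif(n_weights(net), -1, 1)
  base <- evaluate_fitness(genes, net, NULL, mux)
  for (alg in c("consecutive_limited", "nonconsecutive_unlimited",
                "attenuated")) {
    inert <- astro_params(alg, k = 6, mu = 2, a = 0, b = 0)
    expect_equal(evaluate_fitness(genes, net, inert, mux), base)
  }
  # determinism: same genes, same result
  astro <- astro_params("attenuated", k = 6, mu = 2)
  expect_identical(evaluate_fitness(genes, net, astro, mux),
                   evaluate_fitness(genes, net, astro, mux))
})

test_that("montecarlo selection is fitness-proportionate", {
  set.seed(71)
  expect_equal(unique(montecarlo_select(5, 50)), 1L)
  draws <- montecarlo_select(c(3, 1), 10000)
  freq <- mean(draws == 1L)
  expect_lt(abs(freq - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # all-zero fitness degenerates to a uniform draw
  zero_draws <- montecarlo_select(c(0, 0, 0, 0), 8000)
  expect_gt(min(table(factor(zero_draws, levels = 1:4))), 1700)
  expect_error(montecarlo_select(numeric(0), 1), "empty")
  expect_error(montecarlo_select(c(1, -1), 1), "non-negative")
})

test_that("single-point crossover swaps tails and conserves genes", {
  set.seed(81)
  a <- c(0, 0, 0, 0); b <- c(1, 1, 1, 1)
  for (rep in 1:20) {
    ch <- single_point_crossover(a, b, crossover_rate = 1)
    # children are complementary prefix/tail splits at some interior cut
    cut <- sum(ch[[1]] == 0)
    expect_gte(cut, 1); expect_lte(cut, 3)
    expect_equal(ch[[1]], c(rep(0, cut), rep(1, 4 - cut)))
    expect_equal(ch[[2]], c(rep(1, cut), rep(0, 4 - cut)))
  }
  p1 <- runif(9); p2 <- runif(9)
  for (rep in 1:20) {
    ch <- single_point_crossover(p1, p2, crossover_rate = 0.5)
    expect_equal(sort(c(ch[[1]], ch[[2]])), sort(c(p1, p2)))
  }
  same <- single_point_crossover(p1, p1, crossover_rate = 1)
  expect_equal(same[[1]], p1)
  expect_equal(same[[2]], p1)
  expect_error(single_point_crossover(1:3, 1:4), "length")
})

test_that("mutation redraws genes at the configured rate within bounds", {
  set.seed(91)
  g <- runif(50, -1, 1)
  expect_identical(mutate_genes(g, 0, 1), g)
  all_new <- mutate_genes(g, 1, 0.5)
  expect_true(all(abs(all_new) <= 0.5))
  n_changed <- 0
  for (rep in 1:200) {
    n_changed <- n_changed + sum(mutate_genes(g, 0.1, 1) != g)
  }
  frac <- n_changed / (200 * 50)
  expect_lt(abs(frac - 0.1), 0.01)
})

test_that("darwinian replacement displaces the worst and keeps the size", {
  pop <- rbind(c(1, 1), c(2, 2), c(3, 3))
  mse <- c(0.1, 0.9, 0.5)     # fitness 0.9 > 0.5 > 0.1 holder order 1, 3, 2
  out <- darwinian_replace(pop, mse, matrix(c(9, 9), 1), 0.2)
  expect_equal(nrow(out$genes), 3)
  expect_equal(out$genes[2, ], c(9, 9))   # the mse-0.9 row was displaced
  expect_equal(out$mse, c(0.1, 0.2, 0.5))
  untouched <- darwinian_replace(pop, mse, pop[0, , drop = FALSE], numeric(0))
  expect_identical(untouched$genes, pop)
  expect_error(darwinian_replace(pop, mse, rbind(pop, pop), rep(0, 6)),
               "more offspring")
})

test_that("evolution is elitist, reproducible, and inert without operators", {
  mux <- generate_mux()
  sp <- split_dataset(mux, 58 / 64, stratified = TRUE, seed = 3)
  net <- mux_experiment_net()
  ga <- ga_config(population_size = 20, generations = 30, rng_seed = 17)
  rec <- evolve(net, sp$train, sp$validation, ga, NULL)
  expect_true(all(diff(rec$history$best_mse) <= 0))
  expect_identical(evolve(net, sp$train, sp$validation, ga, NULL)$history,
                   rec$history)
  frozen <- ga_config(population_size = 10, crossover_rate = 0,
                      mutation_rate = 0, generations = 10, rng_seed = 5)
  rec0 <- evolve(net, sp$train, sp$validation, frozen, NULL)
  expect_equal(length(unique(rec0$history$best_mse)), 1L)
  expect_equal(rec$generation_of_best,
               which(rec$history$best_mse <= rec$best_mse)[1])
})

test_that("evolution works under each astrocyte rule", {
  mux <- generate_mux()
  sp <- split_dataset(mux, 58 / 64, stratified = TRUE, seed = 3)
  net <- mux_experiment_net()
  ga <- ga_config(population_size = 10, generations = 5, rng_seed = 9)
  for (alg in c("consecutive_limited", "global_effect")) {
    rec <- evolve(net, sp$train, sp$validation, ga,
                  astro_params(alg, k = 4, mu = 2))
    expect_true(all(diff(rec$history$best_mse) <= 0))
    expect_gte(rec$val_accuracy, 0)
    expect_lte(rec$val_accuracy, 1)
  }
})
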