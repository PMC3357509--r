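test_that("fire indicator maps outputs to signed activity", {
  expect_equal(fire_indicator(0), -1L)
  expect_equal(fire_indicator(0.7), 1L)
  expect_equal(fire_indicator(-3), -1L)
  expect_equal(fire_indicator(c(0, 1, -0.2)), c(-1L, 1L, -1L))
})

test_that("counter recurrences match their definitions instant by instant", {
  cons <- astro_params("consecutive_unlimited", k = 8, mu = 2)
  expect_equal(counter_trace(c(1L, 1L), cons), c(1L, 2L))
  expect_equal(counter_trace(c(1L, -1L), cons), c(1L, -1L))  # restart on flip
  noncons <- astro_params("nonconsecutive_unlimited", k = 8, mu = 2)
  expect_equal(counter_trace(c(1L, -1L, 1L, 1L), noncons), c(1L, 0L, 1L, 2L))
  att <- astro_params("attenuated", k = 8, mu = 2)
  expect_equal(counter_trace(c(1L, 1L, 1L), att), c(1L, 2L, 2L))  # retained
  expect_error(update_counter(astro_state(), 1L,
                              astro_params("global_effect", k = 4, mu = 2)),
               "per-instant counter")
})

test_that("counters stay within [-mu, mu] and reset semantics differ by rule", {
  algos <- c("consecutive_limited", "consecutive_unlimited",
             "nonconsecutive_limited", "nonconsecutive_unlimited",
             "attenuated")
  for (k in c(4L, 6L, 8L)) {
    seqs <- all_firing_sequences(k)
    for (mu in 2:3) {
      for (alg in algos) {
        p <- astro_params(alg, k = k, mu = mu)
        for (i in seq_len(nrow(seqs))) {
          r <- counter_trace(seqs[i, ], p)
          expect_true(all(abs(r) <= mu))
        }
      }
    }
  }
})

test_that("consecutive and nonconsecutive rules agree when signs only flip at saturation", {
  for (k in c(4L, 6L, 8L)) {
    seqs <- all_firing_sequences(k)
    for (mu in 2:3) {
      cons <- astro_params("consecutive_unlimited", k = k, mu = mu)
      noncons <- astro_params("nonconsecutive_unlimited", k = k, mu = mu)
      n_checked <- 0L
      for (i in seq_len(nrow(seqs))) {
        u <- seqs[i, ]
        r_nc <- counter_trace(u, noncons)
        flips <- which(diff(u) != 0) + 1L    # instants where the sign changes
        if (all(abs(r_nc[flips - 1L]) == mu)) {
          expect_identical(counter_trace(u, cons), r_nc)
          n_checked <- n_checked + 1L
        }
      }
      expect_gt(n_checked, 0L)
    }
  }
})

test_that("attenuated triggers more often than nonconsecutive on sustained firing", {
  for (k in c(4L, 6L, 8L)) {
    for (mu in 2:3) {
      u <- rep(1L, k)
      att <- counter_trace(u, astro_params("attenuated", k = k, mu = mu))
      nc <- counter_trace(u, astro_params("nonconsecutive_unlimited",
                                          k = k, mu = mu))
      expect_equal(sum(att == mu), k - mu + 1L)
      expect_equal(sum(nc == mu), floor(k / mu))
    }
  }
})

test_that("trigger converts a saturated counter into the relative change", {
  expect_equal(trigger(2, 2, a = 0.25, b = 0.5), 0.25)
  expect_equal(trigger(-2, 2, a = 0.25, b = 0.5), -0.5)
  expect_equal(trigger(0, 2, a = 0.25, b = 0.5), 0)
  expect_equal(trigger(c(-2, 1, 2), 2, 0.25, 0.5), c(-0.5, 0, 0.25))
})

test_that("weight deltas scale by magnitude, preserve sign, respect the limit", {
  expect_equal(apply_weight_delta(0.8, 0.25), 1.0)
  expect_equal(apply_weight_delta(0.9, 0.25, limited = TRUE, wM = 1), 1.0)
  expect_equal(apply_weight_delta(0, 0.7), 0)
  expect_equal(apply_weight_delta(-0.4, 0.25), -0.3)
  expect_equal(apply_weight_delta(-0.4, -0.5), -0.6)
})

test_that("a pattern window steps weights exactly as hand-derived", {
  net <- angn_network(c(2, 1), activation_spec("threshold", 0.5),
                      weights = list(matrix(c(0.8, 0.8), 1)))
  p <- astro_params("nonconsecutive_unlimited", k = 4, mu = 2,
                    a = 0.25, b = 0.5, attachment = "incoming")
  res <- process_pattern(net, c(1, 1), p, return_trace = TRUE)
  # fires every instant; triggers at t = 2 and 4; each weight 0.8 * 1.25^2
  expect_equal(drop(res$trace$counters), c(1L, 2L, 1L, 2L))
  expect_equal(unlist(res$net$weights), c(0.8, 0.8) * 1.25^2,
               ignore_attr = TRUE)
  expect_equal(res$output, 1)
  lim <- astro_params("nonconsecutive_limited", k = 4, mu = 2,
                      attachment = "incoming")
  res_lim <- process_pattern(net, c(1, 1), lim)
  expect_equal(unlist(res_lim$net$weights), c(1, 1), ignore_attr = TRUE)
})

test_that("inert astrocytes (a = b = 0) leave weights and outputs unchanged", {
  set.seed(21)
  algos <- c("consecutive_limited", "consecutive_unlimited",
             "nonconsecutive_limited", "nonconsecutive_unlimited",
             "attenuated")
  for (alg in algos) {
    for (att in c("incoming", "outgoing", "both")) {
      net <- random_net(c(4, 3, 2))
      x <- sample(0:1, 4, replace = TRUE)
      p <- astro_params(alg, k = 6, mu = 2, a = 0, b = 0, attachment = att)
      res <- process_pattern(net, x, p)
      expect_equal(res$net$weights, net$weights)
      expect_equal(res$output, forward_pass(net, x)[[3]])
    }
  }
})

test_that("pattern windows match the naive scalar simulator", {
  set.seed(31)
  algos <- c("consecutive_limited", "consecutive_unlimited",
             "nonconsecutive_limited", "nonconsecutive_unlimited",
             "attenuated")
  for (alg in algos) {
    for (att in c("incoming", "outgoing", "both")) {
      for (rep in 1:3) {
        net <- random_net(c(5, 4, 2), kind = "threshold")
        p <- astro_params(alg, k = sample(4:8, 1), mu = sample(2:3, 1),
                          attachment = att)
        x <- sample(0:1, 5, replace = TRUE)
        got <- process_pattern(net, x, p)
        want <- oracle_process_pattern(net, x, p)
        expect_equal(got$net$weights, want$weights)
        expect_equal(got$output, want$output)
      }
    }
  }
  # continuous activations exercise the tanh path
  net <- random_net(c(3, 4, 2), kind = "hyperbolic_tangent")
  p <- astro_params("attenuated", k = 6, mu = 2, attachment = "outgoing")
  x <- runif(3)
  got <- process_pattern(net, x, p)
  want <- oracle_process_pattern(net, x, p)
  expect_equal(got$net$weights, want$weights)
  expect_equal(got$output, want$output)
})

test_that("global processing rescales by per-pass activity counts", {
  # 1-1 net, threshold 0.5, w = 0.8: fires on instance x=1 only (s=1, n=2);
  # pass 1: w *= (2+1)/2 = 1.2; pass 2 (w=1.2 still fires on x=1): w = 1.8
  net <- angn_network(c(1, 1), activation_spec("threshold", 0.5),
                      weights = list(matrix(0.8, 1, 1)))
  p <- astro_params("global_effect", k = 2, mu = 2, attachment = "incoming")
  res <- global_effect_pass(net, matrix(c(1, 0), ncol = 1), p)
  expect_equal(unlist(res$net$weights), 0.8 * 1.5 * 1.5, ignore_attr = TRUE)
  expect_equal(drop(res$outputs), c(1, 0))  # final-pass outputs
  # a never-firing network is a fixed point
  silent <- angn_network(c(2, 2, 1), activation_spec("threshold", 0.5))
  res2 <- global_effect_pass(silent, matrix(c(1, 0, 0, 1), 2), p)
  expect_equal(res2$net$weights, silent$weights)
  # negative weight with a fully active neuron collapses to zero
  neg <- angn_network(c(1, 1), activation_spec("hyperbolic_tangent"),
                      weights = list(matrix(-0.5, 1, 1)))
  # neuron output tanh(-0.5 * x); with x = -1 it fires on every instance
  p1 <- astro_params("global_effect", k = 1, mu = 1, attachment = "incoming")
  res3 <- global_effect_pass(neg, matrix(-1, 1, 1), p1)
  expect_equal(unlist(res3$net$weights), 0, ignore_attr = TRUE)
})

test_that("global processing matches the naive simulator on random nets", {
  set.seed(41)
  for (att in c("incoming", "outgoing", "both")) {
    for (rep in 1:3) {
      net <- random_net(c(4, 3, 2), kind = "threshold")
      p <- astro_params("global_effect", k = sample(2:4, 1), mu = 2,
                        attachment = att)
      X <- matrix(sample(0:1, 20, replace = TRUE), 5)
      got <- global_effect_pass(net, X, p)
      want <- oracle_global(net, X, p)
      expect_equal(got$net$weights, want$weights)
      expect_equal(got$outputs, want$outputs)
    }
  }
})

test_that("the unsupervised phase gives each pattern an independent window", {
  set.seed(51)
  net <- random_net(c(5, 4, 1), kind = "threshold")
  X <- matrix(sample(0:1, 30, replace = TRUE), 6)
  p <- astro_params("attenuated", k = 6, mu = 2)
  phase <- run_unsupervised_phase(net, X, p)
  for (i in seq_len(nrow(X))) {
    expect_equal(phase$outputs[i, ], process_pattern(net, X[i, ], p)$output)
  }
  expect_equal(phase$net$weights, net$weights)   # windows are transient
  # with no astrocytes the phase is a plain forward evaluation
  plain <- run_unsupervised_phase(net, X, NULL)
  expect_equal(plain$outputs, forward_dataset(net, X))
})

test_that("parameter validation rejects out-of-range astrocyte settings", {
  expect_error(astro_params("attenuated", k = 0, mu = 1), "positive")
  expect_error(astro_params("attenuated", k = 2, mu = 3), "\\[1, k\\]")
  expect_error(astro_params("attenuated", k = 4, mu = 2, a = 1.2), "\\[0, 1\\]")
})
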