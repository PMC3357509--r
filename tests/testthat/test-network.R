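test_that("activation functions follow their definitions", {
  th <- activation_spec("threshold", 0.5)
  expect_equal(apply_activation(th, 0.6), 1)
  expect_equal(apply_activation(th, 0.5), 0)  # boundary does not fire
  expect_equal(apply_activation(th, c(-1, 0.49, 0.51)), c(0, 0, 1))
  expect_equal(apply_activation(activation_spec("hyperbolic_tangent"), 0), 0)
  expect_equal(apply_activation(activation_spec("hyperbolic_tangent"), 2),
               tanh(2))
  expect_equal(apply_activation(activation_spec("identity"), -3.7), -3.7)
  expect_error(apply_activation(list(kind = "threshold"), 1),
               "activation_spec")
})

test_that("forward pass computes f(sum w x) layer by layer", {
  net <- angn_network(c(2, 1), activation_spec("threshold", 0.5),
                      weights = list(matrix(c(0.6, 0.9), 1)))
  st <- forward_pass(net, c(1, 0))
  expect_equal(st[[1]], c(1, 0))      # input layer is pass-through
  expect_equal(st[[2]], 1)            # 0.6 > 0.5
  zero <- angn_network(c(3, 2, 1), activation_spec("threshold", 0.5))
  st0 <- forward_pass(zero, c(1, 1, 1))
  expect_equal(st0[[2]], c(0, 0))
  expect_equal(st0[[3]], 0)
  expect_error(forward_pass(net, c(1, 2, 3)), "input layer size")
})

test_that("forward pass agrees with a scalar loop oracle on random nets", {
  set.seed(11)
  shapes <- list(c(6, 4, 1), c(3, 5, 2), c(4, 8, 8, 3), c(2, 7))
  for (kind in c("threshold", "hyperbolic_tangent")) {
    for (shape in shapes) {
      net <- random_net(shape, kind)
      for (rep in 1:5) {
        x <- round(runif(shape[1]), 3)
        got <- forward_pass(net, x)
        want <- oracle_forward(net$weights, rep(kind, length(shape) - 1),
                               rep(0.5, length(shape) - 1), x)
        for (l in seq_along(got)) expect_equal(got[[l]], want[[l]])
        # repeated evaluation on fixed weights is idempotent
        expect_identical(unclass(got), unclass(forward_pass(net, x)))
      }
      X <- matrix(runif(4 * shape[1]), 4)
      batch <- forward_dataset(net, X)
      for (p in 1:4) {
        expect_equal(batch[p, ], forward_pass(net, X[p, ])[[length(shape)]])
      }
    }
  }
})

test_that("mean squared error averages over patterns and outputs", {
  expect_equal(mean_squared_error(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(mean_squared_error(0, 1), 1)
  expect_equal(mean_squared_error(c(0.5, -0.5), c(0, 0)), 0.25)
  expect_error(mean_squared_error(matrix(0, 2, 2), matrix(0, 3, 2)),
               "identical dimensions")
})

test_that("one-hot classification rejects ambiguous outputs", {
  expect_equal(classify(c(1, 0, 0), "one_hot"), 1L)
  expect_equal(classify(c(0, 0, 1), "one_hot"), 3L)
  expect_true(is.na(classify(c(1, 1, 0), "one_hot")))
  expect_true(is.na(classify(c(0, 0, 0), "one_hot")))
  expect_equal(classify(1, "binary"), 1)
  expect_equal(classify(0, "binary"), 0)
  expect_error(classify(numeric(0), "binary"), "empty")
})

test_that("accuracy equals 1 - (misclassified + unclassifiable)/n", {
  outputs <- rbind(c(1, 0, 0),   # correct (class 1)
                   c(0, 1, 0),   # wrong (true class 3)
                   c(1, 1, 0),   # unclassifiable
                   c(0, 0, 1))   # correct (class 3)
  labels <- c(1, 3, 2, 3)
  acc <- accuracy(outputs, labels, "one_hot")
  expect_equal(acc, 1 - (1 + 1) / 4)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  set.seed(3)
  bin_out <- matrix(as.numeric(runif(20) > 0.5), ncol = 1)
  labs <- sample(0:1, 20, replace = TRUE)
  expect_equal(accuracy(bin_out, labs, "binary"), mean(bin_out[, 1] == labs))
})

test_that("gene encoding round-trips and validates length", {
  set.seed(5)
  net <- random_net(c(4, 3, 2))
  genes <- encode_weights(net)
  expect_length(genes, n_weights(net))
  blank <- angn_network(c(4, 3, 2), activation_spec("threshold", 0.5))
  expect_equal(decode_genes(blank, genes)$weights, net$weights)
  expect_error(decode_genes(blank, genes[-1]), "gene count")
})

test_that("weights survive a text round trip at full precision", {
  set.seed(7)
  net <- random_net(c(5, 4, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(net, path)
  blank <- angn_network(c(5, 4, 2), activation_spec("threshold", 0.5))
  expect_equal(read_weights(blank, path)$weights, net$weights)
  wrong <- angn_network(c(5, 3, 2), activation_spec("threshold", 0.5))
  expect_error(read_weights(wrong, path), "shape")
})
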