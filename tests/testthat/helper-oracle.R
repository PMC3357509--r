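# Naive scalar reference simulator, written directly from the counter
# recurrences and weight rules, independent of the package's production
# paths (which go through compiled code). Everything here is plain R
# loops over scalars.

oracle_algo_num <- function(name) {
  match(name, c("consecutive_limited", "consecutive_unlimited",
                "nonconsecutive_limited", "nonconsecutive_unlimited",
                "attenuated", "global_effect"))
}

# counter trajectory for one neuron given its firing signs u (+1/-1)
oracle_counter_trace <- function(u, algorithm, mu) {
  n <- oracle_algo_num(algorithm)
  r <- integer(length(u))
  for (t in seq_along(u)) {
    r[t] <- if (t == 1L) {
      u[t]
    } else if (n %in% 1:2) {            # consecutive rules
      if (u[t] == u[t - 1L] && r[t - 1L] > -mu && r[t - 1L] < mu) {
        r[t - 1L] + u[t]
      } else u[t]
    } else if (r[t - 1L] > -mu && r[t - 1L] < mu) {
      r[t - 1L] + u[t]
    } else if (n == 5L) {               # attenuated: saturation retained
      r[t - 1L]
    } else u[t]
  }
  r
}

# scalar forward evaluation of a layered net (list of dest x source
# matrices, one activation kind + theta per non-input layer)
oracle_forward <- function(weights, kinds, thetas, x) {
  layers <- list(x)
  for (l in seq_along(weights)) {
    w <- weights[[l]]
    y <- numeric(nrow(w))
    for (j in seq_len(nrow(w))) {
      s <- 0
      for (i in seq_len(ncol(w))) s <- s + w[j, i] * layers[[l]][i]
      y[j] <- switch(kinds[l],
                     threshold = if (s > thetas[l]) 1 else 0,
                     hyperbolic_tangent = tanh(s),
                     identity = s)
    }
    layers[[l + 1L]] <- y
  }
  layers
}

# full per-instant simulation of one pattern window for the five
# per-pattern rules; astrocytes act on the monitored neuron's attachment
# set, in layer order, immediately after the instant's forward evaluation
oracle_process_pattern <- function(net, x, params) {
  kinds <- vapply(net$activations, function(a) a$kind, "")
  thetas <- vapply(net$activations, function(a) a$theta, 0)
  weights <- net$weights
  L <- length(net$layer_sizes)
  r <- u_prev <- lapply(net$layer_sizes[-1L], function(nn) rep(NA_integer_, nn))
  final <- NULL
  for (t in seq_len(params$k)) {
    layers <- oracle_forward(weights, kinds, thetas, x)
    for (l in 2:L) {
      for (j in seq_len(net$layer_sizes[l])) {
        u <- if (layers[[l]][j] > 0) 1L else -1L
        prev <- r[[l - 1L]][j]
        consec <- params$algorithm %in% c("consecutive_limited",
                                          "consecutive_unlimited")
        r[[l - 1L]][j] <- if (t == 1L) {
          u
        } else if (consec) {
          if (u == u_prev[[l - 1L]][j] && abs(prev) < params$mu) prev + u
          else u
        } else if (abs(prev) < params$mu) {
          prev + u
        } else if (params$algorithm == "attenuated") {
          prev
        } else u
        u_prev[[l - 1L]][j] <- u
        z <- if (r[[l - 1L]][j] == params$mu) params$a
             else if (r[[l - 1L]][j] == -params$mu) -params$b
             else 0
        if (z != 0) {
          bump <- function(w) {
            w2 <- w + abs(w) * z
            if (params$limited && abs(w2) > net$weight_limit) {
              w2 <- sign(w2) * net$weight_limit
            }
            w2
          }
          if (params$attachment %in% c("incoming", "both")) {
            for (i in seq_len(net$layer_sizes[l - 1L])) {
              weights[[l - 1L]][j, i] <- bump(weights[[l - 1L]][j, i])
            }
          }
          if (params$attachment %in% c("outgoing", "both") && l < L) {
            for (m in seq_len(net$layer_sizes[l + 1L])) {
              weights[[l]][m, j] <- bump(weights[[l]][m, j])
            }
          }
        }
      }
    }
    if (t == params$k) final <- layers[[L]]
  }
  list(output = final, weights = weights)
}

# global processing effect: k full passes over the instance matrix
oracle_global <- function(net, X, params) {
  kinds <- vapply(net$activations, function(a) a$kind, "")
  thetas <- vapply(net$activations, function(a) a$theta, 0)
  weights <- net$weights
  L <- length(net$layer_sizes)
  n <- nrow(X)
  outputs <- NULL
  for (pass in seq_len(params$k)) {
    s <- lapply(net$layer_sizes[-1L], function(nn) rep(0L, nn))
    outs <- matrix(0, n, net$layer_sizes[L])
    for (p in seq_len(n)) {
      layers <- oracle_forward(weights, kinds, thetas, X[p, ])
      for (l in 2:L) {
        for (j in seq_len(net$layer_sizes[l])) {
          if (layers[[l]][j] > 0) s[[l - 1L]][j] <- s[[l - 1L]][j] + 1L
        }
      }
      outs[p, ] <- layers[[L]]
    }
    for (l in 2:L) {
      for (j in seq_len(net$layer_sizes[l])) {
        fac <- function(w) w * (n + sign(w) * s[[l - 1L]][j]) / n
        if (params$attachment %in% c("incoming", "both")) {
          for (i in seq_len(net$layer_sizes[l - 1L])) {
            weights[[l - 1L]][j, i] <- fac(weights[[l - 1L]][j, i])
          }
        }
        if (params$attachment %in% c("outgoing", "both") && l < L) {
          for (m in seq_len(net$layer_sizes[l + 1L])) {
            weights[[l]][m, j] <- fac(weights[[l]][m, j])
          }
        }
      }
    }
    if (pass == params$k) outputs <- outs
  }
  list(outputs = outputs, weights = weights)
}

# all 2^k firing-sign sequences as rows of a matrix
all_firing_sequences <- function(k) {
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
  dimnames(grid) <- NULL
  grid
}

# a random small network with the given activation kind everywhere
random_net <- function(layer_sizes, kind = "threshold", theta = 0.5, wM = 1) {
  net <- angn_network(layer_sizes, activation_spec(kind, theta),
                      weight_limit = wM)
  net$weights <- lapply(net$weights, function(w) {
    matrix(runif(length(w), -wM, wM), nrow = nrow(w))
  })
  net
}
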