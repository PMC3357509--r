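#' Astrocyte parameter set
#'
#' Each artificial astrocyte is attached to one non-input neuron and watches
#' its firing over a temporal window of `k` instants (the same input pattern
#' is presented `k` times, emulating the slow astrocytic timescale relative
#' to neuronal signalling). A signed activity counter accumulates firings;
#' when it reaches `+mu` the astrocyte potentiates the weights of the
#' neuron's attached connections by the fraction `a`, and when it reaches
#' `-mu` it depresses them by the fraction `b`.
#'
#' The six plasticity rules differ in how the counter accumulates and in
#' whether the weight limit `wM` is respected:
#' \describe{
#'   \item{`consecutive_limited` / `consecutive_unlimited`}{only runs of
#'     same-sign activity count; any alternation restarts the counter. The
#'     counter resets after each weight modification.}
#'   \item{`nonconsecutive_limited` / `nonconsecutive_unlimited`}{firings and
#'     silences offset one another; the counter resets after each weight
#'     modification.}
#'   \item{`attenuated`}{non-consecutive accumulation, but a saturated
#'     counter retains its value instead of resetting, so the astrocyte
#'     keeps acting on every subsequent instant of the window.}
#'   \item{`global_effect`}{no per-pattern counter at all: the network
#'     processes the whole instance set `k` times and each neuron's
#'     per-pass firing count rescales its connections multiplicatively
#'     (see [global_effect_pass()]); `mu` is unused.}
#' }
#'
#' @param algorithm one of `"consecutive_limited"`, `"consecutive_unlimited"`,
#'   `"nonconsecutive_limited"`, `"nonconsecutive_unlimited"`, `"attenuated"`,
#'   `"global_effect"`.
#' @param k integer >= 1, iterations per pattern (or full passes over the
#'   instance set for `global_effect`).
#' @param mu integer in `[1, k]`, the firing-count threshold.
#' @param a potentiation fraction in `[0, 1]` (default 0.25, a 25\% increment).
#' @param b depression fraction in `[0, 1]` (default 0.5, a 50\% decrement).
#' @param attachment which connections of the monitored neuron the astrocyte
#'   rescales: `"outgoing"` (default), `"incoming"`, or `"both"`. The
#'   default matters: on an all-threshold network an astrocyte that only
#'   rescales its own neuron's incoming weights can never flip that
#'   neuron's state within a pattern window (potentiation of a firing
#'   neuron only ever raises its net input, depression of a silent one only
#'   lowers it), so incoming-only astrocytes leave a threshold network's
#'   outputs unchanged. Acting on outgoing connections lets a hidden
#'   neuron's activity reshape the downstream layer's computation
#'   mid-window, which is what gives the neuron-glia network its extra
#'   expressive power.
#' @return an object of class `astro_params`. The weight-limited flag is
#'   derived from the algorithm name.
#' @export
astro_params <- function(algorithm = c("consecutive_limited",
                                       "consecutive_unlimited",
                                       "nonconsecutive_limited",
                                       "nonconsecutive_unlimited",
                                       "attenuated", "global_effect"),
                         k = 4L, mu = 2L, a = 0.25, b = 0.5,
                         attachment = c("outgoing", "incoming", "both")) {
  algorithm <- match.arg(algorithm)
  attachment <- match.arg(attachment)
  k <- as.integer(k); mu <- as.integer(mu)
  if (k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  if (mu < 1L || mu > k) stop("`mu` must lie in [1, k]", call. = FALSE)
  if (a < 0 || a > 1 || b < 0 || b > 1) {
    stop("`a` and `b` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(algorithm = algorithm, k = k, mu = mu, a = a, b = b,
         attachment = attachment,
         limited = algorithm %in% c("consecutive_limited",
                                    "nonconsecutive_limited")),
    class = "astro_params"
  )
}

#' @export
print.astro_params <- function(x, ...) {
  cat("Astrocyte rule:", x$algorithm, "\n")
  cat(sprintf("  k = %d, mu = %d, a = %g, b = %g, attachment = %s%s\n",
              x$k, x$mu, x$a, x$b, x$attachment,
              if (x$limited) ", weight-limited" else ""))
  invisible(x)
}

.algo_code <- function(algorithm) {
  match(algorithm, c("consecutive_limited", "consecutive_unlimited",
                     "nonconsecutive_limited", "nonconsecutive_unlimited",
                     "attenuated", "global_effect")) - 1L
}

astro_pack <- function(params) {
  if (is.null(params)) {
    return(list(algo = -1L, k = 1L, mu = 1L, a = 0, b = 0,
                limited = FALSE, attach = 0L))
  }
  list(algo = .algo_code(params$algorithm), k = params$k, mu = params$mu,
       a = params$a, b = params$b, limited = params$limited,
       attach = match(params$attachment, c("incoming", "outgoing", "both")) - 1L)
}

#' Firing indicator
#'
#' Maps a neuron output to the signed activity increment seen by its
#' astrocyte: +1 when the neuron fired (output > 0), -1 otherwise
#' (output <= 0).
#'
#' @param y numeric vector of neuron outputs.
#' @return integer vector of -1 / +1.
#' @export
fire_indicator <- function(y) {
  ifelse(y > 0, 1L, -1L)
}

#' Fresh astrocyte counter state
#'
#' @return an `astro_state`: counter `r` unset (`NA`) until the first
#'   instant of a pattern window, plus the previous instant's firing sign
#'   needed by the consecutive rules.
#' @export
astro_state <- function() {
  structure(list(r = NA_integer_, last_fired = NA_integer_),
            class = "astro_state")
}

#' Advance an astrocyte activity counter by one instant
#'
#' Implements the counter recurrences of the five per-pattern rules. At the
#' first instant of a window the counter is set to the firing sign. After
#' that, the consecutive rules accumulate only while the sign matches the
#' previous instant and the counter has not yet saturated, restarting to the
#' current sign otherwise; the non-consecutive rules accumulate whenever the
#' counter has not saturated; the attenuated rule additionally retains a
#' saturated counter unchanged instead of restarting.
#'
#' @param state an [astro_state()].
#' @param fired -1 or +1 from [fire_indicator()].
#' @param params an [astro_params()]; must be one of the five per-pattern
#'   algorithms (the global rule keeps no per-instant counter).
#' @return the updated state; `state$r` is the new counter value, always in
#'   `[-mu, mu]`.
#' @export
update_counter <- function(state, fired, params) {
  if (params$algorithm == "global_effect") {
    stop("the global_effect rule does not use a per-instant counter",
         call. = FALSE)
  }
  fired <- as.integer(fired)
  stopifnot(fired %in% c(-1L, 1L))
  mu <- params$mu
  r_prev <- state$r
  consecutive <- params$algorithm %in% c("consecutive_limited",
                                         "consecutive_unlimited")
  attenuated <- params$algorithm == "attenuated"
  r <- if (is.na(r_prev)) {
    fired                                   # first instant of the window
  } else if (consecutive) {
    if (fired == state$last_fired && abs(r_prev) < mu) r_prev + fired
    else fired
  } else if (abs(r_prev) < mu) {
    r_prev + fired
  } else if (attenuated) {
    r_prev                                  # saturation retained
  } else {
    fired
  }
  state$r <- r
  state$last_fired <- fired
  state
}

#' Counter trajectory over a firing sequence
#'
#' Convenience wrapper running [update_counter()] along a whole firing
#' sequence, as happens during the `k` iterations of one pattern window.
#'
#' @param fired integer vector of -1 / +1 firing signs.
#' @param params an [astro_params()] (per-pattern algorithm).
#' @return integer vector of counter values, one per instant.
#' @export
counter_trace <- function(fired, params) {
  state <- astro_state()
  vapply(fired, function(u) {
    state <<- update_counter(state, u, params)
    state$r
  }, 0L)
}

#' Weight-modification trigger
#'
#' Converts a counter value into the relative weight change `z`: `a` when
#' the counter has reached `+mu` (potentiation), `-b` at `-mu` (depression),
#' 0 otherwise.
#'
#' @param counter integer counter value(s) in `[-mu, mu]`.
#' @param mu activation threshold.
#' @param a,b potentiation / depression fractions.
#' @return numeric vector of `z` values.
#' @export
trigger <- function(counter, mu, a, b) {
  ifelse(counter == mu, a, ifelse(counter == -mu, -b, 0))
}

#' Apply a relative weight change
#'
#' The change is proportional to the weight's magnitude,
#' `w' = w + |w| * z`, so a weight never changes sign and zero weights are
#' fixed points. Weight-limited rules then clamp the magnitude to `wM`
#' while preserving the sign.
#'
#' @param w numeric vector of weights.
#' @param z relative change from [trigger()].
#' @param limited logical; clamp to the weight limit?
#' @param wM positive weight limit (required when `limited`).
#' @return the updated weights.
#' @export
apply_weight_delta <- function(w, z, limited = FALSE, wM = 1) {
  w2 <- w + abs(w) * z
  if (limited) {
    stopifnot(wM > 0)
    w2 <- sign(w2) * pmin(abs(w2), wM)
  }
  w2
}

#' Process one pattern through the neuron-glia loop
#'
#' Presents `pattern` to the network for `k` consecutive instants. At each
#' instant the network is evaluated with the current weights; then every
#' astrocyte (one per hidden- and output-layer neuron) reads its neuron's
#' firing sign, advances its counter, and — if the counter has reached
#' `+mu` or `-mu` — rescales the weights of its attached connections.
#' Weight changes take effect from the next instant. Counters start fresh:
#' the window belongs to this pattern presentation.
#'
#' @param net an [angn_network()].
#' @param pattern numeric input vector.
#' @param params an [astro_params()] with a per-pattern algorithm.
#' @param return_trace if `TRUE`, also return the per-instant counter matrix
#'   and per-instant output-layer outputs for inspection.
#' @return a list with `output` (final-instant output-layer vector), `net`
#'   (the network with mutated weights) and, if requested, `trace`.
#' @export
process_pattern <- function(net, pattern, params, return_trace = FALSE) {
  if (params$algorithm == "global_effect") {
    stop("use global_effect_pass() for the global rule", call. = FALSE)
  }
  pattern <- as.numeric(pattern)
  if (length(pattern) != net$layer_sizes[1L]) {
    stop("pattern length must equal the input layer size", call. = FALSE)
  }
  res <- cpp_process_pattern(net_pack(net), pattern, astro_pack(params),
                             return_trace)
  net <- set_flat_weights(net, res$weights)
  out <- list(output = res$output, net = net)
  if (return_trace) out$trace <- res$trace
  out
}

set_flat_weights <- function(net, flat) {
  offset <- 0L
  for (l in seq_along(net$weights)) {
    len <- length(net$weights[[l]])
    net$weights[[l]][] <- flat[(offset + 1L):(offset + len)]
    offset <- offset + len
  }
  net
}

#' Global processing effect
#'
#' The sixth neuron-glia rule treats the instance set as a whole: for each
#' of `k` passes the network evaluates all `n` instances with fixed weights
#' while each astrocyte counts on how many instances its neuron fired
#' (`s`, in `[0, n]`); at the end of the pass every attached connection is
#' rescaled multiplicatively, `w <- w * (n + sign(w) * s) / n`, and `s`
#' resets. The factor lies in `[0, 2]`: positive weights grow with
#' activity, negative weights shrink toward zero, zero weights stay put.
#'
#' @param net an [angn_network()].
#' @param instances numeric matrix of input patterns, one per row.
#' @param params an [astro_params()] with `algorithm = "global_effect"`.
#' @return a list with `outputs` (the instance outputs of the final pass)
#'   and `net` (the network with mutated weights).
#' @export
global_effect_pass <- function(net, instances, params) {
  if (params$algorithm != "global_effect") {
    stop("`params$algorithm` must be \"global_effect\"", call. = FALSE)
  }
  instances <- as.matrix(instances)
  if (nrow(instances) < 1L) stop("empty instance set", call. = FALSE)
  if (ncol(instances) != net$layer_sizes[1L]) {
    stop("instance width must equal the input layer size", call. = FALSE)
  }
  res <- cpp_phase(net_pack(net), instances, astro_pack(params))
  list(outputs = res$outputs, net = set_flat_weights(net, res$weights))
}

#' Run the unsupervised astrocyte phase over a dataset
#'
#' For the five per-pattern rules every pattern gets its own independent
#' k-instant window, exactly as in [process_pattern()]: the window starts
#' from the network's entry weights, and its weight modifications are
#' transient — they shape that pattern's final-instant output and are then
#' discarded. The astrocytes are a per-presentation processing mechanism;
#' learning across patterns belongs to the genetic algorithm. For the
#' global rule this is [global_effect_pass()], whose weight changes do
#' persist across its k passes. With `params = NULL` the phase degenerates
#' to a plain forward evaluation of the dataset.
#'
#' @param net an [angn_network()].
#' @param features numeric matrix of input patterns, one per row.
#' @param params an [astro_params()] or `NULL`.
#' @return a list with `outputs` (patterns x output units) and `net` (for
#'   the global rule, the network with the final pass's weights; otherwise
#'   unchanged).
#' @export
run_unsupervised_phase <- function(net, features, params = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != net$layer_sizes[1L]) {
    stop("feature count must equal the input layer size", call. = FALSE)
  }
  res <- cpp_phase(net_pack(net), features, astro_pack(params))
  list(outputs = res$outputs, net = set_flat_weights(net, res$weights))
}
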