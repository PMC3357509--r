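#' Activation function specification
#'
#' Defines the transfer function of a network layer. Three kinds are
#' supported: a hard `"threshold"` unit that outputs 1 when its net input
#' strictly exceeds `theta` and 0 otherwise, the `"hyperbolic_tangent"`,
#' and the `"identity"` (used internally for the pass-through input layer).
#'
#' @param kind one of `"threshold"`, `"hyperbolic_tangent"`, `"identity"`.
#' @param theta threshold level; only used when `kind = "threshold"`.
#' @return an object of class `activation_spec`.
#' @examples
#' apply_activation(activation_spec("threshold", 0.5), c(0.4, 0.6))
#' @export
activation_spec <- function(kind = c("threshold", "hyperbolic_tangent", "identity"),
                            theta = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  structure(list(kind = kind, theta = theta), class = "activation_spec")
}

#' Apply an activation function
#'
#' @param spec an [activation_spec()].
#' @param x numeric vector of net inputs.
#' @return numeric vector of the same length. Threshold outputs are in
#'   \{0, 1\} (the boundary `x == theta` does not fire), hyperbolic tangent
#'   outputs lie in (-1, 1), identity returns `x` unchanged.
#' @export
apply_activation <- function(spec, x) {
  if (!inherits(spec, "activation_spec")) {
    stop("`spec` must be an activation_spec", call. = FALSE)
  }
  switch(spec$kind,
    threshold = as.numeric(x > spec$theta),
    hyperbolic_tangent = tanh(x),
    identity = x,
    stop("unknown activation kind: ", spec$kind, call. = FALSE)
  )
}

# integer codes shared with the C++ engine
.act_code <- function(spec) {
  switch(spec$kind, threshold = 0L, hyperbolic_tangent = 1L, identity = 2L)
}

#' Feed-forward multilayer network
#'
#' Constructs a layered feed-forward network without bias terms. The input
#' layer is a pass-through; every subsequent neuron j computes
#' `f(sum_i w_ji x_i)` where `f` is the layer's activation. Weight matrices
#' are stored destination-by-source: `weights[[l]]` has one row per neuron
#' of layer `l + 1` and one column per neuron of layer `l`.
#'
#' @param layer_sizes integer vector (length >= 2) of neurons per layer.
#' @param activations a single [activation_spec()] applied to all non-input
#'   layers, or a list with one spec per non-input layer.
#' @param weights optional list of weight matrices; if omitted the network
#'   is created with zero weights (use [init_weights()] or the genetic
#'   algorithm to populate them).
#' @param weight_limit positive scalar `wM`, the maximum admissible weight
#'   magnitude enforced by the weight-limited plasticity rules and used as
#'   the initialisation/mutation range of the genetic algorithm.
#' @return an object of class `angn_network`.
#' @examples
#' net <- angn_network(c(2, 1), activation_spec("threshold", 0.5),
#'                     weights = list(matrix(c(0.6, 0.9), 1)))
#' forward_pass(net, c(1, 0))
#' @export
angn_network <- function(layer_sizes, activations, weights = NULL,
                         weight_limit = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("`layer_sizes` must contain at least two positive integers",
         call. = FALSE)
  }
  n_act <- length(layer_sizes) - 1L
  if (inherits(activations, "activation_spec")) {
    activations <- rep(list(activations), n_act)
  }
  if (length(activations) != n_act ||
      !all(vapply(activations, inherits, TRUE, "activation_spec"))) {
    stop("`activations` must supply one activation_spec per non-input layer",
         call. = FALSE)
  }
  stopifnot(is.numeric(weight_limit), length(weight_limit) == 1L,
            weight_limit > 0)
  if (is.null(weights)) {
    weights <- lapply(seq_len(n_act), function(l) {
      matrix(0, nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
    })
  }
  net <- structure(
    list(layer_sizes = layer_sizes, activations = activations,
         weights = weights, weight_limit = weight_limit),
    class = "angn_network"
  )
  check_weights(net)
  net
}

check_weights <- function(net) {
  ls <- net$layer_sizes
  for (l in seq_along(net$weights)) {
    w <- net$weights[[l]]
    if (!is.matrix(w) || nrow(w) != ls[l + 1L] || ncol(w) != ls[l]) {
      stop(sprintf("weight matrix %d must be %d x %d", l, ls[l + 1L], ls[l]),
           call. = FALSE)
    }
  }
  invisible(net)
}

#' @export
print.angn_network <- function(x, ...) {
  acts <- vapply(x$activations, function(a) a$kind, "")
  cat("Feed-forward network ", paste(x$layer_sizes, collapse = "-"),
      " (no biases)\n", sep = "")
  cat("  activations:", paste(acts, collapse = ", "), "\n")
  cat("  weight limit wM:", x$weight_limit, "\n")
  invisible(x)
}

#' Number of connection weights in a network
#' @param net an [angn_network()].
#' @return integer; the gene count of a chromosome for this architecture.
#' @export
n_weights <- function(net) {
  sum(vapply(net$weights, length, 1L))
}

#' Randomly initialise network weights
#'
#' Draws every weight independently from the uniform distribution on
#' `[-wM, wM]`, the same range the genetic algorithm uses for its initial
#' population. Uses the current R random number generator state.
#'
#' @param net an [angn_network()].
#' @return the network with weights filled in.
#' @export
init_weights <- function(net) {
  wM <- net$weight_limit
  net$weights <- lapply(net$weights, function(w) {
    matrix(runif(length(w), -wM, wM), nrow = nrow(w))
  })
  net
}

#' Evaluate the network on one input pattern
#'
#' The input layer passes the raw pattern through unchanged; each subsequent
#' layer computes `f(W y)` for its weight matrix `W` and the previous layer's
#' output `y`.
#'
#' @param net an [angn_network()].
#' @param input numeric vector whose length equals the input layer size.
#' @return a list of per-layer output vectors (`forward_state`); element 1 is
#'   the input, the last element is the network output.
#' @export
forward_pass <- function(net, input) {
  input <- as.numeric(input)
  if (length(input) != net$layer_sizes[1L]) {
    stop("input length must equal the input layer size", call. = FALSE)
  }
  outputs <- vector("list", length(net$layer_sizes))
  outputs[[1L]] <- input
  for (l in seq_along(net$weights)) {
    pre <- drop(net$weights[[l]] %*% outputs[[l]])
    outputs[[l + 1L]] <- apply_activation(net$activations[[l]], pre)
  }
  structure(outputs, class = "forward_state")
}

#' Network outputs over a whole dataset
#'
#' @param net an [angn_network()].
#' @param features numeric matrix, one pattern per row.
#' @return numeric matrix (patterns x output units) of final-layer outputs.
#' @export
forward_dataset <- function(net, features) {
  features <- as.matrix(features)
  if (ncol(features) != net$layer_sizes[1L]) {
    stop("feature count must equal the input layer size", call. = FALSE)
  }
  cpp_forward_dataset(net_pack(net), features)
}

# flatten network description for the C++ engine
net_pack <- function(net) {
  list(
    sizes = net$layer_sizes,
    act = vapply(net$activations, .act_code, 0L),
    theta = vapply(net$activations, function(a) a$theta, 0),
    weights = unlist(lapply(net$weights, as.numeric)),
    wM = net$weight_limit
  )
}

#' Flatten network weights to a gene vector / restore them
#'
#' Chromosomes of the genetic algorithm are flat real vectors holding every
#' connection weight, layer by layer in column-major order.
#'
#' @param net an [angn_network()].
#' @param genes numeric vector of length [n_weights()].
#' @return `encode_weights` returns a numeric vector; `decode_genes` returns
#'   the network with its weights replaced.
#' @export
encode_weights <- function(net) {
  unlist(lapply(net$weights, as.numeric))
}

#' @rdname encode_weights
#' @export
decode_genes <- function(net, genes) {
  if (length(genes) != n_weights(net)) {
    stop("gene count does not match the network architecture", call. = FALSE)
  }
  offset <- 0L
  for (l in seq_along(net$weights)) {
    len <- length(net$weights[[l]])
    net$weights[[l]][] <- genes[(offset + 1L):(offset + len)]
    offset <- offset + len
  }
  net
}

#' Mean squared error
#'
#' Mean over patterns and output units of the squared difference between
#' network outputs and targets; the error signal the genetic algorithm
#' minimises.
#'
#' @param outputs,targets numeric matrices (patterns x output units) or
#'   vectors of equal shape.
#' @return a single number.
#' @export
mean_squared_error <- function(outputs, targets) {
  outputs <- as.matrix(outputs)
  targets <- as.matrix(targets)
  if (!identical(dim(outputs), dim(targets))) {
    stop("`outputs` and `targets` must have identical dimensions",
         call. = FALSE)
  }
  mean((outputs - targets)^2)
}

#' Classify a network output vector
#'
#' For a `"binary"` task the single (already thresholded) output is the
#' class, 0 or 1. For a `"one_hot"` task the outputs are first passed
#' through a threshold activation; a pattern is assigned the class of the
#' single active output. When zero or more than one output is active the
#' prediction carries no information and `NA` (unclassifiable) is returned;
#' such patterns count as errors in [accuracy()].
#'
#' @param outputs numeric vector of final-layer outputs for one pattern.
#' @param task `"binary"` or `"one_hot"`.
#' @param theta threshold applied to one-hot outputs before decoding.
#' @return class label: 0/1 for binary, 1-based class index for one-hot,
#'   `NA` when unclassifiable.
#' @export
classify <- function(outputs, task = c("binary", "one_hot"), theta = 0.5) {
  task <- match.arg(task)
  if (length(outputs) == 0L) stop("empty output vector", call. = FALSE)
  if (task == "binary") {
    if (length(outputs) != 1L) {
      stop("binary classification expects a single output", call. = FALSE)
    }
    return(as.numeric(outputs > theta))
  }
  if (length(outputs) < 2L) {
    stop("one-hot classification expects at least two outputs", call. = FALSE)
  }
  active <- which(outputs > theta)
  if (length(active) == 1L) active else NA_integer_
}

#' Classification accuracy over a labelled output matrix
#'
#' @param outputs numeric matrix (patterns x output units).
#' @param labels true labels: 0/1 for binary, 1-based indices for one-hot.
#' @param task `"binary"` or `"one_hot"`.
#' @param theta threshold used by [classify()].
#' @return fraction of patterns classified correctly, in `[0, 1]`;
#'   unclassifiable patterns count as incorrect.
#' @export
accuracy <- function(outputs, labels, task = c("binary", "one_hot"),
                     theta = 0.5) {
  task <- match.arg(task)
  outputs <- as.matrix(outputs)
  if (nrow(outputs) != length(labels)) {
    stop("`labels` must have one entry per output row", call. = FALSE)
  }
  pred <- apply(outputs, 1L, classify, task = task, theta = theta)
  mean(!is.na(pred) & pred == labels)
}

#' Save / load network weights as delimited text
#'
#' Weight matrices are written one per layer as tab-separated blocks
#' separated by blank lines, full precision.
#'
#' @param net an [angn_network()].
#' @param path file path.
#' @return `write_weights` returns `path` invisibly; `read_weights` returns
#'   the network with weights replaced.
#' @export
write_weights <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (w in net$weights) {
    writeLines(apply(w, 1L, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(net, path) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  if (length(blocks) != length(net$weights)) {
    stop("file holds ", length(blocks), " weight blocks; network needs ",
         length(net$weights), call. = FALSE)
  }
  for (l in seq_along(blocks)) {
    m <- do.call(rbind, lapply(strsplit(blocks[[l]], "\t"), as.numeric))
    if (!identical(dim(m), dim(net$weights[[l]]))) {
      stop("weight block ", l, " has the wrong shape", call. = FALSE)
    }
    net$weights[[l]] <- m
  }
  check_weights(net)
}
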