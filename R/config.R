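
.valid_algorithms <- c("consecutive_limited", "consecutive_unlimited",
                       "nonconsecutive_limited", "nonconsecutive_unlimited",
                       "attenuated", "global_effect", "ann")

#' Validate a run configuration
#'
#' Reads a structured (YAML) run configuration, checks every cross-field
#' constraint, fills documented defaults, and returns a normalised
#' `run_config`. Constraint violations are reported with the offending
#' field paths. The recognised sections are `dataset` (`type` `"mux"` or
#' `"tabular"`), `network` (`layer_sizes`, `activations`, `theta`,
#' `weight_limit`), `astrocyte` (`a`, `b`, `attachment`), `ga`, and
#' `experiment` (`algorithms`, `combos`, `seeds`, `train_fraction`,
#' `stratified`); plus the top-level `seed` and `output_dir`.
#'
#' @param raw path to a YAML file, or an already-parsed list.
#' @return an object of class `run_config`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw)) {
    if (!file.exists(raw)) stop("config file not found: ", raw, call. = FALSE)
    raw <- yaml::read_yaml(raw)
  }
  if (!is.list(raw)) stop("configuration must be a list", call. = FALSE)
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  dflt <- function(section, field, default) {
    v <- raw[[section]][[field]]
    if (is.null(v)) default else v
  }

  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  ## dataset
  ds_type <- dflt("dataset", "type", "mux")
  if (!ds_type %in% c("mux", "tabular")) {
    note("dataset.type: must be \"mux\" or \"tabular\"")
  }
  select_lines <- as.integer(dflt("dataset", "select_lines", 2L))
  data_lines <- as.integer(dflt("dataset", "data_lines", 2L^select_lines))
  if (ds_type == "mux" && data_lines != 2L^select_lines) {
    note(sprintf(
      "dataset.data_lines: must equal 2^dataset.select_lines (got %d, expected %d)",
      data_lines, 2L^select_lines))
  }
  if (ds_type == "tabular" && is.null(raw$dataset$path)) {
    note("dataset.path: required when dataset.type is \"tabular\"")
  }

  ## network
  layer_sizes <- dflt("network", "layer_sizes", c(6L, 4L, 1L))
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    note("network.layer_sizes: need at least two positive layer sizes")
  }
  theta <- dflt("network", "theta", 0.5)
  act_kinds <- dflt("network", "activations", "threshold")
  if (length(act_kinds) == 1L) {
    act_kinds <- rep(act_kinds, length(layer_sizes) - 1L)
  }
  if (length(act_kinds) != length(layer_sizes) - 1L) {
    note("network.activations: need one activation per non-input layer")
  }
  bad_act <- setdiff(act_kinds, c("threshold", "hyperbolic_tangent", "identity"))
  if (length(bad_act) > 0L) {
    note(paste0("network.activations: unknown kind(s) ",
                paste(bad_act, collapse = ", ")))
  }
  wM <- dflt("network", "weight_limit", 1)
  if (wM <= 0) note("network.weight_limit: must be positive")

  ## astrocyte + experiment
  algorithms <- dflt("experiment", "algorithms",
                     dflt("astrocyte", "algorithm", .valid_algorithms))
  bad_alg <- setdiff(algorithms, .valid_algorithms)
  if (length(bad_alg) > 0L) {
    note(paste0("experiment.algorithms: unknown algorithm(s) ",
                paste(bad_alg, collapse = ", "), "; valid names are ",
                paste(.valid_algorithms, collapse = ", ")))
  }
  a <- dflt("astrocyte", "a", 0.25)
  b <- dflt("astrocyte", "b", 0.5)
  if (a < 0 || a > 1) note("astrocyte.a: must lie in [0, 1]")
  if (b < 0 || b > 1) note("astrocyte.b: must lie in [0, 1]")
  attachment <- dflt("astrocyte", "attachment", "outgoing")
  if (!attachment %in% c("incoming", "outgoing", "both")) {
    note("astrocyte.attachment: must be incoming, outgoing or both")
  }
  combos <- dflt("experiment", "combos",
                 list(c(4, 2), c(6, 2), c(6, 3), c(8, 3)))
  if (!is.null(raw$astrocyte$k) || !is.null(raw$astrocyte$mu)) {
    combos <- list(c(dflt("astrocyte", "k", 4L), dflt("astrocyte", "mu", 2L)))
  }
  for (cm in combos) {
    if (length(cm) != 2L || cm[2L] < 1L) {
      note("experiment.combos: each entry must be a (k, mu) pair with mu >= 1")
    } else if (cm[2L] > cm[1L]) {
      note(sprintf(
        "astrocyte.mu: mu = %d exceeds astrocyte.k = %d (mu must lie in [1, k])",
        cm[2L], cm[1L]))
    }
  }

  n_seeds <- dflt("experiment", "seeds", 10L)
  seeds <- if (length(n_seeds) > 1L) as.integer(n_seeds) else {
    vapply(seq_len(as.integer(n_seeds)),
           function(i) derive_seed(seed, paste0("population", i)), 1L)
  }
  if (anyDuplicated(seeds)) note("experiment.seeds: seeds must be distinct")

  train_fraction <- dflt("experiment", "train_fraction", 58 / 64)
  if (train_fraction <= 0 || train_fraction >= 1) {
    note("experiment.train_fraction: must lie strictly between 0 and 1")
  }

  ga <- tryCatch(
    ga_config(
      population_size = dflt("ga", "population_size", 100L),
      crossover_rate = dflt("ga", "crossover_rate", 0.9),
      mutation_rate = dflt("ga", "mutation_rate", 0.1),
      generations = dflt("ga", "generations", 4000L),
      rng_seed = seed
    ),
    error = function(e) {
      note(paste0("ga: ", conditionMessage(e)))
      NULL
    }
  )

  if (length(errs) > 0L) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }

  structure(list(
    seed = seed,
    dataset = list(type = ds_type, path = raw$dataset$path,
                   class_column = raw$dataset$class_column,
                   normalize = isTRUE(dflt("dataset", "normalize", TRUE)),
                   select_lines = select_lines, data_lines = data_lines),
    network = list(layer_sizes = as.integer(layer_sizes),
                   activations = act_kinds, theta = theta, weight_limit = wM),
    astrocyte = list(a = a, b = b, attachment = attachment),
    experiment = list(algorithms = algorithms, combos = combos, seeds = seeds,
                      train_fraction = train_fraction,
                      stratified = isTRUE(dflt("experiment", "stratified", TRUE))),
    ga = ga,
    output_dir = if (is.null(raw$output_dir)) "angn_run" else raw$output_dir
  ), class = "run_config")
}

#' Execute a validated run configuration
#'
#' Builds the dataset and network the configuration describes, runs the
#' planned experiment, and (optionally) writes the result tables and run
#' ledger to the configured output directory.
#'
#' @param cfg a [validate_config()] result, a raw list, or a YAML path.
#' @param write if `TRUE`, write outputs to `cfg$output_dir`.
#' @param verbose passed to [run_experiment()].
#' @return the [experiment_result][run_experiment()], invisibly when
#'   writing.
#' @export
run_from_config <- function(cfg, write = TRUE, verbose = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  ds <- if (cfg$dataset$type == "mux") {
    generate_mux(cfg$dataset$select_lines, cfg$dataset$data_lines)
  } else {
    load_tabular(cfg$dataset$path, cfg$dataset$class_column,
                 normalize = cfg$dataset$normalize)
  }
  acts <- lapply(cfg$network$activations, activation_spec,
                 theta = cfg$network$theta)
  net <- angn_network(cfg$network$layer_sizes, acts,
                      weight_limit = cfg$network$weight_limit)
  plan <- experiment_plan(
    net, cfg$experiment$algorithms, combos = cfg$experiment$combos,
    a = cfg$astrocyte$a, b = cfg$astrocyte$b,
    attachment = cfg$astrocyte$attachment,
    seeds = cfg$experiment$seeds, ga = cfg$ga,
    train_fraction = cfg$experiment$train_fraction,
    stratified = cfg$experiment$stratified,
    split_seed = derive_seed(cfg$seed, "split")
  )
  result <- run_experiment(plan, ds, verbose = verbose)
  if (write) {
    write_result(result, cfg$output_dir, config = unclass(cfg))
    invisible(result)
  } else {
    result
  }
}
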