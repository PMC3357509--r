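
# canonical method ordering used in reports: the six neuron-glia rules
# followed by the astrocyte-free network
.method_order <- c("consecutive_limited", "consecutive_unlimited",
                   "nonconsecutive_limited", "nonconsecutive_unlimited",
                   "attenuated", "global_effect", "ann")

#' Experiment plan
#'
#' Describes a full comparison run: which methods to train (the six
#' neuron-glia rules and/or the plain `"ann"`), the `(k, mu)` combinations
#' to try for each astrocyte rule, the shared plasticity fractions, the
#' replicate seeds (one independently initialised population per seed), the
#' genetic-algorithm settings, and the train/validation split.
#'
#' @param net template [angn_network()].
#' @param algorithms character vector of method names; `"ann"` denotes the
#'   astrocyte-free baseline.
#' @param combos list of `c(k, mu)` pairs tried for each astrocyte rule
#'   (ignored by `"ann"`); default the four combinations 4-2, 6-2, 6-3, 8-3.
#' @param a,b potentiation / depression fractions shared by all astrocytes.
#' @param attachment connection set each astrocyte acts on.
#' @param seeds distinct integer seeds, one per replicate population.
#' @param ga a [ga_config()]; its `rng_seed` is replaced by each replicate's
#'   seed.
#' @param train_fraction,stratified,split_seed the dataset split (see
#'   [split_dataset()]).
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(net, algorithms,
                            combos = list(c(4, 2), c(6, 2), c(6, 3), c(8, 3)),
                            a = 0.25, b = 0.5, attachment = "outgoing",
                            seeds = 1:10, ga = ga_config(),
                            train_fraction = NULL, stratified = TRUE,
                            split_seed = 1L) {
  algorithms <- match.arg(algorithms, .method_order, several.ok = TRUE)
  if (length(combos) == 0L) stop("`combos` must be non-empty", call. = FALSE)
  if (anyDuplicated(seeds)) stop("`seeds` must be distinct", call. = FALSE)
  for (cm in combos) {
    if (length(cm) != 2L || cm[2L] > cm[1L] || cm[2L] < 1L) {
      stop("each combo must be c(k, mu) with 1 <= mu <= k", call. = FALSE)
    }
  }
  structure(list(net = net, algorithms = algorithms, combos = combos,
                 a = a, b = b, attachment = attachment,
                 seeds = as.integer(seeds), ga = ga,
                 train_fraction = train_fraction, stratified = stratified,
                 split_seed = as.integer(split_seed)),
            class = "experiment_plan")
}

#' Run a comparison experiment
#'
#' Trains every planned method on the dataset: for each astrocyte rule,
#' every replicate seed is run once per `(k, mu)` combination and the
#' combination with the highest validation accuracy is kept for that seed
#' (ties broken by lower training MSE, then smaller `k`); the plain
#' `"ann"` is run once per seed. Per-method means and standard deviations
#' of the kept runs are then aggregated.
#'
#' @param plan an [experiment_plan()].
#' @param ds an [angn_dataset()]; split according to the plan.
#' @param split optional precomputed list with `train` and `validation`
#'   datasets, overriding the plan's split of `ds`.
#' @param verbose print one line per completed run.
#' @return an object of class `experiment_result` with `runs` (every run),
#'   `best` (the kept run per method and seed), `summary` (per-method
#'   aggregates) and the `plan`.
#' @export
run_experiment <- function(plan, ds, split = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(split)) {
    if (is.null(plan$train_fraction)) {
      stop("plan has no `train_fraction` and no explicit split was given",
           call. = FALSE)
    }
    split <- split_dataset(ds, plan$train_fraction, plan$stratified,
                           plan$split_seed)
  }
  runs <- list()
  for (alg in plan$algorithms) {
    combos <- if (alg == "ann") list(c(NA_real_, NA_real_)) else plan$combos
    for (seed in plan$seeds) {
      for (cm in combos) {
        astro <- if (alg == "ann") NULL else {
          astro_params(alg, k = cm[1L], mu = cm[2L], a = plan$a, b = plan$b,
                       attachment = plan$attachment)
        }
        ga <- plan$ga
        ga$rng_seed <- seed
        rec <- evolve(plan$net, split$train, split$validation, ga, astro)
        runs[[length(runs) + 1L]] <- data.frame(
          algorithm = alg, seed = seed, k = cm[1L], mu = cm[2L],
          generation = rec$generation_of_best, train_mse = rec$best_mse,
          val_accuracy = rec$val_accuracy, time = rec$elapsed
        )
        if (verbose) {
          message(sprintf("%s seed %d k=%s mu=%s: mse %.4f acc %.1f%%",
                          alg, seed, cm[1L], cm[2L], rec$best_mse,
                          100 * rec$val_accuracy))
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  best <- select_best_runs(runs)
  structure(list(runs = runs, best = best,
                 summary = summarize_best(best), plan = plan,
                 train_idx = split$train_idx),
            class = "experiment_result")
}

# per method and seed, keep the (k, mu) run with the highest validation
# accuracy; ties broken by lower training MSE, then smaller k
select_best_runs <- function(runs) {
  pick <- function(g) {
    ord <- order(-g$val_accuracy, g$train_mse, g$k)
    g[ord[1L], , drop = FALSE]
  }
  parts <- split(runs, list(runs$algorithm, runs$seed), drop = TRUE)
  best <- do.call(rbind, lapply(parts, pick))
  best[order(match(best$algorithm, .method_order), best$seed), ]
}

summarize_best <- function(best) {
  agg <- function(g) {
    data.frame(
      algorithm = g$algorithm[1L], n_seeds = nrow(g),
      generation = mean(g$generation),
      train_mse = mean(g$train_mse), train_sd = sd(g$train_mse),
      val_accuracy = mean(g$val_accuracy), val_sd = sd(g$val_accuracy),
      time = mean(g$time)
    )
  }
  parts <- split(best, best$algorithm)
  out <- do.call(rbind, lapply(parts, agg))
  out <- out[order(match(out$algorithm, .method_order)), ]
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", nrow(x$runs), "runs,",
      length(unique(x$runs$seed)), "seeds\n")
  print(render_summary(x), row.names = FALSE)
  invisible(x)
}

#' Best-result tallies across methods
#'
#' For every seed and each of the four measurements — fewer generations,
#' lower training error, higher validation accuracy, shorter time — every
#' method attaining the per-seed optimum receives one count (ties are all
#' counted), using each method's kept run for that seed.
#'
#' @param result an [experiment_result][run_experiment()] with at least two
#'   methods.
#' @return a data frame of counts per method and measurement plus a total.
#' @export
tally_best <- function(result) {
  best <- result$best
  algs <- unique(best$algorithm)
  if (length(algs) < 2L) {
    stop("tallies need at least two methods", call. = FALSE)
  }
  measures <- list(
    generation = function(g) g$generation == min(g$generation),
    train_error = function(g) g$train_mse == min(g$train_mse),
    val_accuracy = function(g) g$val_accuracy == max(g$val_accuracy),
    time = function(g) g$time == min(g$time)
  )
  counts <- matrix(0L, nrow = length(algs), ncol = length(measures),
                   dimnames = list(algs, names(measures)))
  for (seed_group in split(best, best$seed)) {
    for (m in names(measures)) {
      winners <- seed_group$algorithm[measures[[m]](seed_group)]
      counts[winners, m] <- counts[winners, m] + 1L
    }
  }
  out <- data.frame(algorithm = algs, counts, row.names = NULL)
  out$total <- rowSums(counts)
  out[order(match(out$algorithm, .method_order)), ]
}
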