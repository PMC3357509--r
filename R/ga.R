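#' Genetic algorithm configuration
#'
#' Settings of the real-coded genetic algorithm that evolves initial weight
#' vectors: fitness-proportionate ("Montecarlo") parent selection,
#' single-point crossover, per-gene uniform-redraw mutation, and
#' replace-worst ("Darwinian") substitution.
#'
#' @param population_size number of chromosomes (>= 2); default 100.
#' @param crossover_rate probability a parent pair recombines; default 0.9.
#' @param mutation_rate per-gene probability of a uniform redraw on
#'   `[-wM, wM]`; default 0.1.
#' @param generations number of generations to run.
#' @param rng_seed integer seed; identical seed and configuration reproduce
#'   a run bit-exactly.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, crossover_rate = 0.9,
                      mutation_rate = 0.1, generations = 4000L,
                      rng_seed = 1L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  if (generations < 1L) stop("`generations` must be >= 1", call. = FALSE)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(population_size = population_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = generations,
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Fitness of one chromosome
#'
#' Decodes the genes into the template network's weights, runs the
#' unsupervised astrocyte phase over the training set (or a plain forward
#' evaluation when `astro` is `NULL`), and scores each pattern's
#' final-instant output against its target. The phase never writes back
#' into the chromosome — the genetic algorithm searches the space of
#' initial weights, not trained ones — and the error is mapped onto the
#' bounded, higher-is-better fitness `1 / (1 + MSE)`.
#'
#' @param genes numeric gene vector (see [encode_weights()]).
#' @param net template [angn_network()].
#' @param astro an [astro_params()] or `NULL` for the astrocyte-free network.
#' @param data an [angn_dataset()].
#' @return a list with `mse` and `fitness`.
#' @export
evaluate_fitness <- function(genes, net, astro, data) {
  mse <- cpp_eval_population(net_pack(net),
                             matrix(genes, nrow = 1L),
                             data$features, data$targets,
                             astro_pack(astro))[1L]
  list(mse = mse, fitness = 1 / (1 + mse))
}

#' Fitness-proportionate (Montecarlo) selection
#'
#' Samples parent indices with replacement, each individual drawn with
#' probability proportional to its fitness; if every fitness is zero the
#' draw is uniform. Uses the current R random number generator state.
#'
#' @param fitness numeric vector of non-negative fitnesses.
#' @param count number of parents to draw.
#' @return integer vector of selected indices.
#' @export
montecarlo_select <- function(fitness, count) {
  if (length(fitness) == 0L) stop("empty population", call. = FALSE)
  if (any(fitness < 0)) stop("fitness must be non-negative", call. = FALSE)
  prob <- if (sum(fitness) == 0) rep(1, length(fitness)) else fitness
  sample.int(length(fitness), count, replace = TRUE, prob = prob)
}

#' Single-point crossover
#'
#' With probability `crossover_rate` a cut point is drawn uniformly from
#' the `L - 1` interior positions and the parents' tails are swapped;
#' otherwise the children are copies of the parents.
#'
#' @param parent_a,parent_b numeric gene vectors of equal length >= 2.
#' @param crossover_rate recombination probability.
#' @return a list of two child gene vectors.
#' @export
single_point_crossover <- function(parent_a, parent_b, crossover_rate = 1) {
  L <- length(parent_a)
  if (L != length(parent_b)) stop("parents differ in length", call. = FALSE)
  if (L < 2L) stop("chromosomes need at least two genes", call. = FALSE)
  if (runif(1) < crossover_rate) {
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    child_a <- parent_a; child_b <- parent_b
    child_a[tail_idx] <- parent_b[tail_idx]
    child_b[tail_idx] <- parent_a[tail_idx]
    list(child_a, child_b)
  } else {
    list(parent_a, parent_b)
  }
}

#' Per-gene uniform mutation
#'
#' Each gene is independently replaced, with probability `mutation_rate`,
#' by a fresh uniform draw from `[-wM, wM]`.
#'
#' @param genes numeric vector or matrix of genes (matrix: one chromosome
#'   per row).
#' @param mutation_rate per-gene mutation probability.
#' @param wM weight limit defining the redraw range.
#' @return the mutated genes, same shape as the input.
#' @export
mutate_genes <- function(genes, mutation_rate, wM) {
  if (mutation_rate <= 0) return(genes)
  mask <- runif(length(genes)) < mutation_rate
  genes[mask] <- runif(sum(mask), -wM, wM)
  genes
}

#' Replace-worst (Darwinian) substitution
#'
#' The `|offspring|` lowest-fitness (highest-MSE) members of the population
#' are displaced by the offspring; population size is preserved. Whenever
#' fewer offspring than population members are supplied the incumbent best
#' survives, giving the generation loop its implicit elitism.
#'
#' @param pop_genes population gene matrix (one chromosome per row).
#' @param pop_mse training MSE of each population member.
#' @param off_genes offspring gene matrix.
#' @param off_mse training MSE of each offspring.
#' @return a list with the new `genes` matrix and `mse` vector.
#' @export
darwinian_replace <- function(pop_genes, pop_mse, off_genes, off_mse) {
  n_off <- NROW(off_genes)
  if (n_off == 0L) return(list(genes = pop_genes, mse = pop_mse))
  if (n_off > NROW(pop_genes)) {
    stop("more offspring than population members", call. = FALSE)
  }
  worst <- order(pop_mse, decreasing = TRUE)[seq_len(n_off)]
  pop_genes[worst, ] <- off_genes
  pop_mse[worst] <- off_mse
  list(genes = pop_genes, mse = pop_mse)
}

#' Evolve network weights by the hybrid genetic-algorithm scheme
#'
#' Initialises a population of flattened weight vectors uniformly on
#' `[-wM, wM]`, then iterates generations of fitness evaluation (the
#' unsupervised astrocyte phase providing the MSE when `astro` is given),
#' Montecarlo selection, single-point crossover, per-gene mutation and
#' replace-worst substitution. Each generation produces
#' `population_size - 1` offspring, so the incumbent best chromosome always
#' survives and the best training MSE is non-increasing.
#'
#' Each generation records the best individual's training MSE and that same
#' individual's validation accuracy, evaluated under the identical
#' astrocyte protocol (plain forward evaluation for the astrocyte-free
#' network). The run's headline `val_accuracy` is the validation accuracy
#' of the final best-training chromosome — the solution the algorithm
#' delivers; the full per-generation history is returned for other
#' summaries.
#'
#' @param net template [angn_network()] (architecture, activations, wM).
#' @param train,validation [angn_dataset()] splits.
#' @param ga a [ga_config()].
#' @param astro an [astro_params()] or `NULL` for the plain network.
#' @return an object of class `training_record`: `history` (data frame with
#'   `generation`, `best_mse`, `val_accuracy`), `best_genes`, `best_mse`,
#'   `val_accuracy`, `best_val_accuracy` (the maximum of the per-generation
#'   trace), `generation_of_best` (first generation at which the final best
#'   training MSE was reached), `elapsed` (seconds), and the configuration
#'   used.
#' @export
evolve <- function(net, train, validation, ga, astro = NULL) {
  stopifnot(inherits(ga, "ga_config"), inherits(train, "angn_dataset"),
            inherits(validation, "angn_dataset"))
  if (nrow(train$features) == 0L || nrow(validation$features) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  packed <- net_pack(net)
  apacked <- astro_pack(astro)
  L <- n_weights(net)
  P <- ga$population_size
  wM <- net$weight_limit
  theta_out <- net$activations[[length(net$activations)]]$theta

  val_accuracy_of <- function(genes) {
    res <- cpp_phase(modifyList(packed, list(weights = genes)),
                     validation$features, apacked)
    accuracy(res$outputs, validation$labels, validation$task,
             theta = theta_out)
  }

  record <- with_seed(ga$rng_seed, {
    genes <- matrix(runif(P * L, -wM, wM), nrow = P)
    mse <- cpp_eval_population(packed, genes, train$features, train$targets,
                               apacked)
    best_mse_hist <- numeric(ga$generations)
    val_hist <- numeric(ga$generations)
    best_idx <- which.min(mse)
    best_genes <- genes[best_idx, ]
    val_acc <- val_accuracy_of(best_genes)
    n_off <- P - 1L
    n_pairs <- ceiling(n_off / 2)
    for (gen in seq_len(ga$generations)) {
      if (n_off > 0L && (ga$crossover_rate > 0 || ga$mutation_rate > 0)) {
        fitness <- 1 / (1 + mse)
        parents <- montecarlo_select(fitness, 2L * n_pairs)
        off <- matrix(0, nrow = 2L * n_pairs, ncol = L)
        for (p in seq_len(n_pairs)) {
          ch <- single_point_crossover(genes[parents[2L * p - 1L], ],
                                       genes[parents[2L * p], ],
                                       ga$crossover_rate)
          off[2L * p - 1L, ] <- ch[[1L]]
          off[2L * p, ] <- ch[[2L]]
        }
        off <- off[seq_len(n_off), , drop = FALSE]
        off <- mutate_genes(off, ga$mutation_rate, wM)
        off_mse <- cpp_eval_population(packed, off, train$features,
                                       train$targets, apacked)
        new_pop <- darwinian_replace(genes, mse, off, off_mse)
        genes <- new_pop$genes
        mse <- new_pop$mse
      }
      best_idx <- which.min(mse)
      if (!identical(genes[best_idx, ], best_genes)) {
        best_genes <- genes[best_idx, ]
        val_acc <- val_accuracy_of(best_genes)
      }
      best_mse_hist[gen] <- mse[best_idx]
      val_hist[gen] <- val_acc
    }
    list(best_genes = best_genes, best_mse = min(mse),
         best_mse_hist = best_mse_hist, val_hist = val_hist)
  })

  final_val <- record$val_hist[ga$generations]
  structure(list(
    history = data.frame(generation = seq_len(ga$generations),
                         best_mse = record$best_mse_hist,
                         val_accuracy = record$val_hist),
    best_genes = record$best_genes,
    best_mse = record$best_mse,
    val_accuracy = final_val,
    best_val_accuracy = max(record$val_hist),
    generation_of_best = which(record$best_mse_hist <= record$best_mse)[1L],
    elapsed = proc.time()[["elapsed"]] - t0,
    ga = ga, astro = astro
  ), class = "training_record")
}

#' @export
print.training_record <- function(x, ...) {
  cat("Training record:", x$ga$generations, "generations, population",
      x$ga$population_size, "\n")
  cat(sprintf("  best training MSE %.4f | validation accuracy %.1f%% (first at generation %d)\n",
              x$best_mse, 100 * x$val_accuracy, x$generation_of_best))
  cat(sprintf("  astrocyte rule: %s | elapsed %.1fs\n",
              if (is.null(x$astro)) "none (plain ANN)" else x$astro$algorithm,
              x$elapsed))
  invisible(x)
}
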