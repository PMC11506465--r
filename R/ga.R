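#' Genetic-algorithm settings
#'
#' Controls the real-coded genetic algorithm that searches the network's
#' weight/bias chromosome. Selection is roulette-wheel on fitness with
#' elitism; crossover is arithmetic (blend) crossover; mutation perturbs
#' individual genes with Gaussian noise clipped to `gene_bounds`.
#'
#' @param population_size Number of chromosomes, at least 2.
#' @param generations Number of generations to run.
#' @param crossover_prob Per-pair probability of arithmetic crossover.
#' @param mutation_prob Per-gene probability of Gaussian perturbation.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation; must be below `population_size`. Elitism of at least 1
#'   guarantees a nondecreasing best-fitness trace.
#' @param gene_bounds Length-2 `c(low, high)` range for initialisation and
#'   mutation clipping; `[-1, 1]` keeps sigmoid units responsive on
#'   normalised inputs.
#' @param mutation_sd Standard deviation of the mutation perturbation.
#' @return A list of class `"ga_control"`.
#' @export
ga_control <- function(population_size = 40, generations = 100,
                       crossover_prob = 0.8, mutation_prob = 0.1,
                       elitism = 1, gene_bounds = c(-1, 1),
                       mutation_sd = 0.1) {
  if (population_size < 2) stop("'population_size' must be >= 2", call. = FALSE)
  if (elitism < 0 || elitism >= population_size)
    stop("'elitism' must be in [0, population_size)", call. = FALSE)
  if (length(gene_bounds) != 2 || gene_bounds[1] >= gene_bounds[2])
    stop("'gene_bounds' must be c(low, high) with low < high", call. = FALSE)
  for (p in c(crossover_prob, mutation_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 gene_bounds = gene_bounds, mutation_sd = mutation_sd),
            class = "ga_control")
}

#' Evolve an initial weight chromosome
#'
#' Runs the genetic algorithm over chromosomes encoding the full network
#' parameter vector, scoring each by [chromosome_fitness()] on the training
#' set. Each generation applies elitism, roulette-wheel selection,
#' arithmetic crossover and clipped Gaussian mutation. The best-so-far
#' individual is tracked across generations, so the returned fitness trace
#' is nondecreasing. Deterministic given the RNG state (seed the session or
#' pass `seed`).
#'
#' @param x Training feature matrix.
#' @param y Integer grades in `1..spec$n_output`.
#' @param spec A [network_spec()] with `n_input == ncol(x)`.
#' @param control A [ga_control()].
#' @param seed Optional integer seed.
#' @param init_population Optional matrix (`population_size` x
#'   `spec$n_params`) of starting chromosomes; by default the population is
#'   drawn uniformly from `gene_bounds`.
#' @return List of class `"ga_result"`: `best` (chromosome), `best_fitness`,
#'   `trace` (best fitness per generation, including the initial
#'   population as generation 0).
#' @export
ga_evolve <- function(x, y, spec, control = ga_control(), seed = NULL,
                      init_population = NULL) {
  stopifnot(inherits(spec, "mlp_spec"), inherits(control, "ga_control"))
  x <- as_numeric_matrix(x, min_rows = 1)
  if (nrow(x) == 0 || length(y) != nrow(x))
    stop("training set must be nonempty with one grade per row", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lo <- control$gene_bounds[1]; hi <- control$gene_bounds[2]
  np <- control$population_size
  target <- one_hot(y, spec$n_output)
  score <- function(genes) {
    o <- mlp_forward(decode_params(genes, spec), x)
    if (any(!is.finite(o))) return(0)
    1 / (1 + sum((o - target)^2))
  }

  if (is.null(init_population)) {
    pop <- matrix(stats::runif(np * spec$n_params, lo, hi), nrow = np)
  } else {
    pop <- as.matrix(init_population)
    if (!identical(dim(pop), c(np, spec$n_params)))
      stop("'init_population' must be population_size x n_params",
           call. = FALSE)
  }
  fit <- apply(pop, 1, score)
  best_i <- which.max(fit)
  best <- pop[best_i, ]; best_fit <- fit[best_i]
  trace <- best_fit

  for (gen in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    new_pop <- matrix(0, np, spec$n_params)
    ne <- control$elitism
    if (ne > 0) new_pop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
    # roulette-wheel parent selection on fitness
    prob <- fit / sum(fit)
    i <- ne
    while (i < np) {
      parents <- sample.int(np, 2, replace = TRUE, prob = prob)
      c1 <- pop[parents[1], ]; c2 <- pop[parents[2], ]
      if (stats::runif(1) < control$crossover_prob) {
        a <- stats::runif(1)
        tmp <- a * c1 + (1 - a) * c2
        c2 <- a * c2 + (1 - a) * c1
        c1 <- tmp
      }
      for (child in list(c1, c2)) {
        if (i >= np) break
        m <- stats::runif(spec$n_params) < control$mutation_prob
        if (any(m))
          child[m] <- pmin(pmax(child[m] +
            stats::rnorm(sum(m), 0, control$mutation_sd), lo), hi)
        i <- i + 1
        new_pop[i, ] <- child
      }
    }
    pop <- new_pop
    fit <- apply(pop, 1, score)
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best_fit <- fit[gen_best]
      best <- pop[gen_best, ]
    }
    trace <- c(trace, best_fit)
  }
  structure(list(best = best, best_fitness = best_fit, trace = trace),
            class = "ga_result")
}
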