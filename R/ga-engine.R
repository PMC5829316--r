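# Real-coded genetic algorithm for partitional clustering. A chromosome is
# the row-wise concatenation of k candidate centers (n = k*p genes); its
# fitness is the same within-cluster squared-distance objective the
# K-Means engine minimises, so the two methods are directly comparable.
# Generations evolve by truncation selection of the lowest-fitness
# members, block crossover that exchanges whole centers between parents,
# per-gene Gaussian mutation clipped to the search bounds, and elitism
# (the best members pass unchanged, making best-so-far fitness monotone).

#' Genetic-algorithm configuration
#'
#' The literature describing this clustering approach fixes the operator
#' sequence (selection, crossover, mutation, elitist replacement) but no
#' numeric settings; these defaults are this package's declared choices
#' and every one can be overridden.
#'
#' @param pop_size population size `m` (>= 2).
#' @param n_generations number of generations (>= 0).
#' @param n_parents how many lowest-fitness members become parents
#'   (even, >= 2).
#' @param crossover_rate probability a parent pair exchanges a center
#'   block.
#' @param mutation_rate per-gene probability of a Gaussian perturbation.
#' @param mutation_sd perturbation standard deviation as a fraction of the
#'   gene's search-bound width.
#' @param elitism number of best members copied unchanged each generation
#'   (`< pop_size`).
#' @param seed integer seed driving the whole run's random stream.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, n_generations = 200L,
                      n_parents = 20L, crossover_rate = 0.9,
                      mutation_rate = 0.05, mutation_sd = 0.05,
                      elitism = 2L, seed = 1L) {
  stopifnot(pop_size >= 2, n_generations >= 0,
            n_parents >= 2, n_parents %% 2 == 0, n_parents <= pop_size,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, mutation_sd >= 0,
            elitism >= 0, elitism < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 n_parents = as.integer(n_parents),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf(paste0("GA config: pop %d, %d generations, %d parents, ",
                     "crossover %.2f, mutation %.2f (sd %.2f), ",
                     "elitism %d, seed %d\n"),
              x$pop_size, x$n_generations, x$n_parents, x$crossover_rate,
              x$mutation_rate, x$mutation_sd, x$elitism, x$seed))
  invisible(x)
}

# per-gene search bounds: the per-feature data range repeated k times,
# degenerate (zero-width) features widened by an epsilon-scaled margin
search_bounds <- function(x, k) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  degenerate <- hi - lo <= 0
  if (any(degenerate)) {
    eps <- pmax(abs(lo[degenerate]), 1) * sqrt(.Machine$double.eps)
    lo[degenerate] <- lo[degenerate] - eps
    hi[degenerate] <- hi[degenerate] + eps
    warning("zero-width feature range widened by a machine-epsilon margin",
            call. = FALSE)
  }
  list(lo = rep(lo, k), hi = rep(hi, k))
}

#' Initialise a GA population
#'
#' `pop_size` chromosomes of length `k * p`, genes drawn uniformly within
#' the per-feature search bounds.
#'
#' @param config a [ga_config()].
#' @param k number of centers encoded per chromosome.
#' @param p feature dimension.
#' @param bounds list with `lo` and `hi` gene bounds (as from the
#'   per-feature data range); each of length `k * p`.
#' @param seed seed for the draw; `NULL` continues the current RNG stream.
#' @return numeric matrix, one chromosome per row.
#' @export
init_population <- function(config, k, p, bounds, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- k * p
  stopifnot(length(bounds$lo) == n_genes, length(bounds$hi) == n_genes)
  m <- config$pop_size
  pop <- matrix(stats::runif(m * n_genes, rep(bounds$lo, each = m),
                             rep(bounds$hi, each = m)), m, n_genes)
  pop
}

#' Fitness of a chromosome
#'
#' Reshapes the gene vector into a `k x p` center matrix (row-wise) and
#' returns [total_within_cluster_distance()]; lower is better.
#'
#' @param genes numeric vector of length `k * p`.
#' @param x feature matrix (`n x p`).
#' @param k number of centers encoded.
#' @return non-negative scalar.
#' @export
chromosome_fitness <- function(genes, x, k) {
  x <- as_feature_matrix(x)
  if (length(genes) != k * ncol(x)) {
    stop(sprintf("chromosome length %d does not match k * p = %d",
                 length(genes), k * ncol(x)), call. = FALSE)
  }
  total_within_cluster_distance(x, chromosome_centers(genes, k))
}

chromosome_centers <- function(genes, k) {
  matrix(genes, nrow = k, byrow = TRUE)
}

#' Truncation selection
#'
#' Returns the indices of the `n_parents` lowest-fitness members, ties
#' broken by member index (the problem is a minimisation, so the smallest
#' fitness values are the strongest candidates).
#'
#' @param fitness numeric vector of evaluated fitnesses.
#' @param n_parents how many to select (`<= length(fitness)`).
#' @return integer vector of selected member indices.
#' @export
select_parents <- function(fitness, n_parents) {
  if (n_parents > length(fitness)) {
    stop("cannot select more parents than population members", call. = FALSE)
  }
  order(fitness)[seq_len(n_parents)]  # order() is stable: ties by index
}

#' Block crossover of two parent chromosomes
#'
#' With probability `crossover_rate` a contiguous run of whole center
#' blocks (each block is `p` consecutive genes) is exchanged between the
#' parents, so children always encode valid center sets; otherwise the
#' parents are returned unchanged. With `p = 1` this reduces to exchanging
#' a run of individual genes. The multiset of genes across the two
#' children always equals that across the two parents.
#'
#' @param a,b parent gene vectors of equal length `k * p`.
#' @param config a [ga_config()] (supplies `crossover_rate`).
#' @param k,p encoding shape.
#' @return list of two children gene vectors.
#' @export
crossover_pair <- function(a, b, config, k, p) {
  if (length(a) != length(b) || length(a) != k * p) {
    stop("parents must both have length k * p", call. = FALSE)
  }
  if (stats::runif(1) >= config$crossover_rate) {
    return(list(a, b))
  }
  blocks <- sort(sample.int(k, 2, replace = TRUE))
  idx <- ((blocks[1] - 1) * p + 1):(blocks[2] * p)
  tmp <- a[idx]
  a[idx] <- b[idx]
  b[idx] <- tmp
  list(a, b)
}

#' Gaussian mutation of a chromosome
#'
#' Each gene is independently perturbed with probability `mutation_rate`
#' by a zero-mean Gaussian step whose standard deviation is
#' `mutation_sd` times that gene's search-bound width, then clipped back
#' into the bounds.
#'
#' @param genes gene vector.
#' @param config a [ga_config()].
#' @param bounds list with `lo`/`hi` per-gene bounds.
#' @return mutated gene vector (same length).
#' @export
mutate_chromosome <- function(genes, config, bounds) {
  hit <- stats::runif(length(genes)) < config$mutation_rate
  if (any(hit)) {
    width <- bounds$hi[hit] - bounds$lo[hit]
    genes[hit] <- genes[hit] +
      stats::rnorm(sum(hit), 0, config$mutation_sd * width)
    genes <- pmin(pmax(genes, bounds$lo), bounds$hi)
  }
  genes
}

#' Fit cluster centers with the genetic algorithm
#'
#' Runs the full evolutionary loop: initialise, evaluate, then for each
#' generation keep the `elitism` best members unchanged, breed children
#' from the selected parents by block crossover, and mutate the children.
#' The best chromosome ever evaluated (monotone under elitism) is
#' reshaped into the fitted centers, and points are labelled by
#' [assign_clusters()] against them. One seed drives the entire random
#' stream, so identical seeds give identical models.
#'
#' @param x numeric matrix (or data frame) of observations, `n x p`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param config a [ga_config()].
#' @return a `cluster_model` (see [kmeans_fit()]) whose `trace` is a data
#'   frame of per-generation best/mean fitness; `n_iterations` is the
#'   number of generations run.
#' @examples
#' b <- well_separated_blobs(k = 2, n_per_cluster = 15, seed = 2)
#' fit <- ga_cluster_fit(b$x, k = 2,
#'                       config = ga_config(n_generations = 50, seed = 3))
#' fit$objective
#' @export
ga_cluster_fit <- function(x, k, config = ga_config()) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n == 0) stop("empty data", call. = FALSE)
  if (k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and n = %d", n), call. = FALSE)
  }
  p <- ncol(x)
  set.seed(config$seed)
  bounds <- search_bounds(x, k)
  pop <- init_population(config, k, p, bounds, seed = NULL)
  fitness <- apply(pop, 1, chromosome_fitness, x = x, k = k)

  best_idx <- which.min(fitness)
  best_genes <- pop[best_idx, ]
  best_fitness <- fitness[best_idx]
  trace <- data.frame(generation = 0L, best = best_fitness,
                      mean = mean(fitness))

  for (gen in seq_len(config$n_generations)) {
    elite_idx <- order(fitness)[seq_len(config$elitism)]
    parents <- pop[select_parents(fitness, config$n_parents), ,
                   drop = FALSE]
    children <- matrix(NA_real_, config$pop_size - config$elitism,
                       k * p)
    filled <- 0L
    pair <- 1L
    while (filled < nrow(children)) {
      i <- (2L * pair - 2L) %% nrow(parents) + 1L
      j <- (2L * pair - 1L) %% nrow(parents) + 1L
      kids <- crossover_pair(parents[i, ], parents[j, ], config, k, p)
      for (child in kids) {
        if (filled >= nrow(children)) break
        filled <- filled + 1L
        children[filled, ] <- mutate_chromosome(child, config, bounds)
      }
      pair <- pair + 1L
    }
    pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    fitness <- apply(pop, 1, chromosome_fitness, x = x, k = k)
    gen_best <- which.min(fitness)
    if (fitness[gen_best] < best_fitness) {
      best_fitness <- fitness[gen_best]
      best_genes <- pop[gen_best, ]
    }
    trace <- rbind(trace, data.frame(generation = gen, best = best_fitness,
                                     mean = mean(fitness)))
  }

  centers <- chromosome_centers(best_genes, k)
  structure(
    list(centers = centers, cluster = assign_clusters(x, centers),
         objective = best_fitness, n_iterations = config$n_generations,
         converged = NA, trace = trace, k = as.integer(k), method = "ga",
         seed = config$seed),
    class = "cluster_model"
  )
}

#' Write a per-generation fitness trace to TSV
#'
#' @param model a `cluster_model` fitted by [ga_cluster_fit()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fitness_trace <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"), is.data.frame(model$trace))
  utils::write.table(model$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
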