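test_that("population initialisation respects size, shape, bounds and seed", {
  cfg <- ga_config(pop_size = 20, seed = 5)
  bounds <- list(lo = rep(0, 9), hi = rep(1, 9))
  pop <- init_population(cfg, k = 3, p = 3, bounds)
  expect_identical(dim(pop), c(20L, 9L))  # n = k * p genes
  expect_true(all(pop >= 0 & pop <= 1))
  expect_identical(pop, init_population(cfg, k = 3, p = 3, bounds))
  cfg2 <- ga_config(pop_size = 2, n_parents = 2, elitism = 0, seed = 1)
  pop2 <- init_population(cfg2, k = 1, p = 1, list(lo = 0, hi = 1))
  expect_identical(dim(pop2), c(2L, 1L))
})

test_that("fitness equals the clustering objective and is block-symmetric", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(chromosome_fitness(c(0.5, 10.5), x, k = 2), 1.0)
  # centers placed on two data points covering all points
  expect_equal(chromosome_fitness(c(0, 1), matrix(c(0, 1), ncol = 1), k = 2), 0)
  expect_error(chromosome_fitness(c(0.5, 10.5, 3), x, k = 2), "length")
  # permuting whole center blocks never changes fitness
  set.seed(71)
  data2 <- matrix(rnorm(40), ncol = 2)
  genes <- rnorm(6)
  f0 <- chromosome_fitness(genes, data2, k = 3)
  for (i in 1:5) {
    perm <- sample(3)
    blocks <- split(genes, rep(1:3, each = 2))
    expect_equal(chromosome_fitness(unlist(blocks[perm]), data2, k = 3), f0)
  }
})

test_that("truncation selection takes the lowest fitnesses, ties by index", {
  expect_identical(select_parents(c(3, 1, 2), 2), c(2L, 3L))
  expect_identical(select_parents(c(5, 5, 5, 5), 2), c(1L, 2L))
  expect_identical(sort(select_parents(1:6, 6)), 1:6)
  expect_error(select_parents(1:3, 4), "more parents")
})

test_that("crossover swaps center blocks and conserves the gene multiset", {
  a <- c(1, 2, 3, 4)
  b <- c(5, 6, 7, 8)
  cfg_off <- ga_config(crossover_rate = 0)
  set.seed(1)
  expect_identical(crossover_pair(a, b, cfg_off, k = 4, p = 1), list(a, b))

  cfg_on <- ga_config(crossover_rate = 1)
  set.seed(2)
  for (i in 1:20) {
    kids <- crossover_pair(a, b, cfg_on, k = 2, p = 2)
    expect_identical(sort(c(kids[[1]], kids[[2]])), sort(c(a, b)))
    # children are whole-block recombinations: each 2-gene block comes
    # intact from one parent
    for (kid in kids) {
      for (blk in list(kid[1:2], kid[3:4])) {
        expect_true(identical(blk, a[1:2]) || identical(blk, a[3:4]) ||
                      identical(blk, b[1:2]) || identical(blk, b[3:4]))
      }
    }
  }
  # with p = 1 a single-block swap exchanges individual genes
  set.seed(3)
  kids1 <- crossover_pair(a, b, cfg_on, k = 4, p = 1)
  expect_identical(sort(c(kids1[[1]], kids1[[2]])), sort(c(a, b)))
})

test_that("mutation is rate- and sd-controlled and respects bounds", {
  genes <- seq(0, 1, length.out = 6)
  bounds <- list(lo = rep(0, 6), hi = rep(1, 6))
  set.seed(4)
  expect_identical(mutate_chromosome(genes, ga_config(mutation_rate = 0),
                                     bounds), genes)
  expect_identical(
    mutate_chromosome(genes, ga_config(mutation_rate = 1, mutation_sd = 0),
                      bounds), genes)
  cfg <- ga_config(mutation_rate = 1, mutation_sd = 0.5)
  for (i in 1:20) {
    mutated <- mutate_chromosome(genes, cfg, bounds)
    expect_true(all(mutated >= 0 & mutated <= 1))
    expect_false(identical(mutated, genes))
  }
})

test_that("the GA finds the data mean for k = 1 (closed-form optimum)", {
  set.seed(81)
  x <- matrix(rnorm(60, sd = 2), ncol = 2)
  fit <- ga_cluster_fit(x, k = 1,
                        config = ga_config(n_generations = 100, seed = 9))
  expect_equal(as.vector(fit$centers), colMeans(x), tolerance = 0.05)
  # and the objective approaches the total sum of squares about the mean
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  expect_lt(fit$objective, tss * 1.01)
})

test_that("elitism makes best-so-far fitness monotone non-increasing", {
  b <- well_separated_blobs(k = 3, n_per_cluster = 20, separation = 6,
                            noise_sd = 0.8, seed = 91)
  fit <- ga_cluster_fit(b$x, k = 3,
                        config = ga_config(n_generations = 60, seed = 10))
  expect_true(all(diff(fit$trace$best) <= 0))
  expect_equal(fit$objective, tail(fit$trace$best, 1))
})

test_that("zero generations returns the best initial member", {
  set.seed(101)
  x <- matrix(rnorm(40), ncol = 2)
  cfg <- ga_config(n_generations = 0, pop_size = 10, n_parents = 4,
                   seed = 11)
  fit <- ga_cluster_fit(x, k = 2, cfg)
  set.seed(11)
  pop <- init_population(cfg, k = 2, p = 2,
                         search_bounds_for(x, 2), seed = NULL)
  fits <- apply(pop, 1, chromosome_fitness, x = x, k = 2)
  expect_equal(fit$objective, min(fits))
})

test_that("GA runs are fully seed-deterministic", {
  b <- well_separated_blobs(k = 2, n_per_cluster = 15, seed = 12)
  cfg <- ga_config(n_generations = 30, seed = 13)
  f1 <- ga_cluster_fit(b$x, k = 2, cfg)
  f2 <- ga_cluster_fit(b$x, k = 2, cfg)
  expect_identical(f1, f2)
  f3 <- ga_cluster_fit(b$x, k = 2, ga_config(n_generations = 30, seed = 14))
  expect_false(identical(f1$centers, f3$centers))
})

test_that("GA recovers blob centers and matches K-Means on separable data", {
  b <- well_separated_blobs(k = 3, n_per_cluster = 50, separation = 10,
                            noise_sd = 0.5, seed = 15)
  ga_objs <- numeric(5)
  km_objs <- numeric(5)
  for (s in 1:5) {
    ga <- ga_cluster_fit(b$x, k = 3,
                         config = ga_config(n_generations = 150, seed = s))
    km <- kmeans_fit(b$x, k = 3, seed = s, nstart = 1)
    ga_objs[s] <- ga$objective
    km_objs[s] <- km$objective
    if (s == 1) {
      perm <- align_labels(b$labels, ga$cluster)
      expect_identical(perm[ga$cluster], b$labels)
      aligned <- ga$centers[order(perm), , drop = FALSE]
      expect_true(all(sqrt(rowSums((aligned - b$centers)^2)) < 3 * 0.5))
    }
  }
  expect_lte(min(ga_objs), 1.05 * min(km_objs))
})

test_that("fitness traces are written as TSV", {
  b <- well_separated_blobs(k = 2, n_per_cluster = 10, seed = 16)
  fit <- ga_cluster_fit(b$x, k = 2,
                        config = ga_config(n_generations = 10, seed = 17))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_trace(fit, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("generation", "best", "mean"))
  expect_identical(nrow(back), 11L)  # generation 0 plus 10
})
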