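# Shared fixtures and independent oracles.

# a small, hand-checkable subject table spanning all three clusters
make_subjects <- function() {
  data.frame(
    age    = c(45, 25, 25, 50, 22),
    weight = c(70, 55, 75, 80, 48),
    height = c(1.80, 1.65, 1.82, 1.75, 1.60),
    rter   = c(10, 45, 70, 30, 20),
    rtir   = c(25, 30, 40, 66, 15),
    lter   = c(50, 55, 60, 21, 64),
    ltir   = c(45, 35, 25, 80, 5)
  )
}

# random feasible 3x3 type-by-cluster count table with a fixed total
random_joint_table <- function(n_total = 60) {
  cells <- as.vector(stats::rmultinom(1, n_total, rep(1 / 9, 9)))
  matrix(cells, 3, 3)
}

# Independent oracle: the global K-Means optimum by exhaustive enumeration
# of all k^n assignments (small n only). Returns the minimal within-group
# sum of squared distances to group centroids.
brute_force_kmeans_objective <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 3^8)
  best <- Inf
  assignment <- rep(1L, n)
  repeat {
    obj <- 0
    for (g in unique(assignment)) {
      pts <- x[assignment == g, , drop = FALSE]
      ctr <- colMeans(pts)
      obj <- obj + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, obj)
    # next assignment in base-k counting
    i <- 1L
    while (i <= n && assignment[i] == k) {
      assignment[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    assignment[i] <- assignment[i] + 1L
  }
  best
}

# Independent oracle for label alignment: try all 6 permutations directly
brute_force_alignment <- function(reference, predicted) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p) sum(p[predicted] == reference),
                   numeric(1))
  perms[[which.max(scores)]]
}

# mirror of the GA engine's internal search-bound computation (per-feature
# data range repeated k times), for replaying its initial population
search_bounds_for <- function(x, k) {
  list(lo = rep(apply(x, 2, min), k), hi = rep(apply(x, 2, max), k))
}

# default generator ranges with one entry replaced, for infeasibility tests
default_ranges_with <- function(...) {
  ranges <- list(
    age    = rbind(c(31, 60), c(18, 30), c(18, 30)),
    weight = rbind(c(45, 100), c(45, 60), c(61, 100)),
    height = rbind(c(1.50, 1.95), c(1.50, 1.70), c(1.71, 1.95))
  )
  utils::modifyList(ranges, list(...))
}
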