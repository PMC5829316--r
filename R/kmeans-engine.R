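# From-scratch K-Means (Lloyd's algorithm) minimising the within-cluster
# sum of squared Euclidean distances D = sum_i min_j ||x_i - C_j||^2.
# Written out rather than delegated so the GA engine and the baseline
# share one objective and one assignment rule; stats::kmeans is used only
# as an independent cross-check in the test suite.

#' Euclidean distance between two points
#'
#' @param x,y numeric vectors of equal length.
#' @return the non-negative scalar `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same dimension", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

# n x k matrix of squared distances from every row of x to every center
squared_distances <- function(x, centers) {
  if (ncol(x) != ncol(centers)) {
    stop("data and centers must have the same number of columns",
         call. = FALSE)
  }
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  d2 <- outer(xs, cs, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)  # clamp tiny negative values from cancellation
}

#' Clustering objective: total within-cluster squared distance
#'
#' The quantity both engines minimise:
#' `D = sum_i min_j ||x_i - C_j||^2`, each point counted against its
#' nearest center. Zero exactly when every point coincides with a center.
#'
#' @param x numeric matrix (`n x p`) of observations.
#' @param centers numeric matrix (`k x p`) of cluster centers.
#' @return non-negative scalar.
#' @export
total_within_cluster_distance <- function(x, centers) {
  x <- as_feature_matrix(x)
  centers <- as_feature_matrix(centers)
  sum(apply(squared_distances(x, centers), 1, min))
}

#' Assign points to their nearest center
#'
#' Ties (a point exactly equidistant from two centers) go to the
#' lower-indexed center.
#'
#' @inheritParams total_within_cluster_distance
#' @return integer vector of cluster indices in `1..k`.
#' @export
assign_clusters <- function(x, centers) {
  x <- as_feature_matrix(x)
  centers <- as_feature_matrix(centers)
  max.col(-squared_distances(x, centers), ties.method = "first")
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("features must be a numeric matrix with no missing or infinite values",
         call. = FALSE)
  }
  x
}

#' Build a (scaled) clustering feature matrix from a subject table
#'
#' Extracts the physical-attribute columns and, by default, z-standardises
#' each one. Standardisation matters here: height is measured in metres
#' (spread ~0.1) and weight in kilograms (spread ~15), so unscaled
#' Euclidean distances would be dominated by weight alone. The centring
#' and scaling constants are kept as attributes (`"scaled:center"`,
#' `"scaled:scale"`) so fitted centers can be reported in original units.
#'
#' @param subjects subject data frame (see [validate_subjects()]).
#' @param features character vector of columns to use.
#' @param scale z-standardise each feature (default `TRUE`).
#' @return numeric matrix, one row per subject.
#' @export
feature_matrix <- function(subjects, features = c("age", "weight", "height"),
                           scale = TRUE) {
  validate_subjects(subjects)
  missing <- setdiff(features, names(subjects))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(subjects[, features, drop = FALSE])
  if (scale) {
    x <- base::scale(x)
    sd0 <- attr(x, "scaled:scale") == 0
    if (any(sd0)) {  # constant feature: leave centred zeros
      x[, sd0] <- 0
      attr(x, "scaled:scale")[sd0] <- 1
    }
  }
  x
}

#' Report cluster centers in original (unscaled) units
#'
#' @param centers `k x p` matrix of centers on the scale of a
#'   [feature_matrix()].
#' @param x the feature matrix whose scaling attributes apply.
#' @return `k x p` matrix of centers in original units (unchanged if `x`
#'   was not scaled).
#' @export
unscale_centers <- function(centers, x) {
  ctr <- attr(x, "scaled:center")
  scl <- attr(x, "scaled:scale")
  if (is.null(ctr)) return(centers)
  sweep(sweep(centers, 2, scl, "*"), 2, ctr, "+")
}

#' Fit K-Means from scratch
#'
#' Lloyd's algorithm: initial centers are `k` distinct observations drawn
#' without replacement under the seed, then assignment to nearest center
#' and centroid update (mean of assigned points) alternate until the
#' assignment is a fixed point or `max_iter` is reached. A cluster that
#' loses all members is re-seeded at the point farthest from its nearest
#' center. The objective is non-increasing across iterations.
#'
#' @param x numeric matrix (or data frame) of observations, `n x p`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed for the initial centers.
#' @param max_iter iteration cap (default 300).
#' @param nstart number of seeded restarts; the best objective wins.
#' @return a `cluster_model`: list with `centers` (`k x p`), `k`,
#'   `cluster` (assignments), `objective`, `n_iterations`, `converged`,
#'   `method`, `seed`, and `trace` (objective after each iteration).
#' @examples
#' x <- matrix(c(0, 1, 10, 11), ncol = 1)
#' kmeans_fit(x, k = 2, seed = 1)$centers
#' @export
kmeans_fit <- function(x, k, seed = 1L, max_iter = 300L, nstart = 1L) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n == 0) stop("empty data", call. = FALSE)
  if (k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and n = %d", n), call. = FALSE)
  }
  set.seed(seed)
  best <- NULL
  for (run in seq_len(nstart)) {
    fit <- kmeans_single(x, k, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(
    c(best, list(k = as.integer(k), method = "km", seed = as.integer(seed))),
    class = "cluster_model"
  )
}

kmeans_single <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  labels <- assign_clusters(x, centers)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members) == 0) {
        # empty-cluster repair: re-seed at the worst-covered point
        d2 <- apply(squared_distances(x, centers), 1, min)
        centers[j, ] <- x[which.max(d2), ]
      } else {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    new_labels <- assign_clusters(x, centers)
    trace <- c(trace, total_within_cluster_distance(x, centers))
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  list(centers = centers, cluster = labels,
       objective = total_within_cluster_distance(x, centers),
       n_iterations = iter, converged = converged, trace = trace)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("%s cluster model: k = %d, objective = %.6g\n",
              toupper(x$method), x$k, x$objective))
  cat(sprintf("  %d iteration%s%s, seed %d\n", x$n_iterations,
              if (x$n_iterations == 1) "" else "s",
              if (isTRUE(x$converged)) " (converged)" else "", x$seed))
  cat("Centers:\n")
  print(round(x$centers, 4))
  invisible(x)
}

#' Serialise a cluster model to JSON
#'
#' Writes centers (and, when `x` carries scaling attributes, centers in
#' original units), the objective, iteration count and seed.
#'
#' @param model a `cluster_model`.
#' @param path output file.
#' @param x optional feature matrix supplying scaling attributes.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path, x = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  out <- list(method = model$method, k = model$k,
              centers = model$centers, objective = model$objective,
              n_iterations = model$n_iterations,
              converged = model$converged, seed = model$seed)
  if (!is.null(x) && !is.null(attr(x, "scaled:center"))) {
    out$centers_original_units <- unscale_centers(model$centers, x)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
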