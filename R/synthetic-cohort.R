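# Synthetic cohort generation. The motivating study's per-subject data were
# never deposited, so cohorts with the same categorical structure are
# simulated: rule-based cluster membership fixes the admissible attribute
# ranges and rotation type fixes the admissible angle interval, and values
# are drawn uniformly within each cell. Uniform-within-cell is a declared
# modelling assumption (the published record gives thresholds, not
# distributions), not an inference about the real cohort.

default_attribute_ranges <- function() {
  list(
    # rows: cluster 1..3; rule thresholds: age 30 y, weight 60 kg
    age    = rbind(c(31, 60), c(18, 30), c(18, 30)),
    weight = rbind(c(45, 100), c(45, 60), c(61, 100)),
    height = rbind(c(1.50, 1.95), c(1.50, 1.70), c(1.71, 1.95))
  )
}

default_angle_ranges <- function() {
  rbind(c(0, 20), c(20, 65), c(65, 90))  # rows: type 1..3, degrees
}

#' Specify a synthetic cohort
#'
#' Builds a validated specification for [generate_cohort()]. Two modes:
#'
#' * `"parametric"`: cluster membership is multinomial with
#'   `cluster_props`, and each rotation component's type is multinomial
#'   with the corresponding row of `type_props`. Defaults reproduce the
#'   motivating study's marginal structure (cluster sizes 52/249/183 out
#'   of 484 and its per-component type totals).
#' * `"table_exact"`: `joint_counts` gives one or more 3x3 type-by-cluster
#'   count tables (named by rotation component); the generated cohort
#'   reproduces every supplied table exactly under the rule-based
#'   classifiers. Components without a table are drawn as Type 2
#'   (nonpathological). All supplied tables must share the same column
#'   (cluster) sums, since cluster membership is a property of the subject.
#'
#' Attributes and angles are drawn uniformly within the range that defines
#' each cluster/type cell; ranges can be overridden but must stay
#' consistent with the classification thresholds (an age range reaching
#' below 30 years cannot produce Cluster 1 subjects, and is rejected).
#'
#' @param n_subjects cohort size; in table-exact mode it must equal the
#'   grand total of the supplied tables (default: that total).
#' @param mode `"parametric"` or `"table_exact"`.
#' @param joint_counts a single 3x3 count matrix (taken as `rter`), or a
#'   named list of them keyed by rotation component.
#' @param cluster_props length-3 probabilities of Clusters 1..3
#'   (parametric mode).
#' @param type_props 4x3 matrix of type probabilities, one row per
#'   rotation component (parametric mode).
#' @param attribute_ranges,angle_ranges optional overrides of the
#'   per-cluster attribute ranges and per-type angle intervals.
#' @param seed integer used by [generate_cohort()] unless overridden there.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(joint_counts = reference_joint_counts("real"),
#'                     mode = "table_exact", seed = 1)
#' spec
#' @export
cohort_spec <- function(n_subjects = NULL,
                        mode = c("parametric", "table_exact"),
                        joint_counts = NULL,
                        cluster_props = c(52, 249, 183) / 484,
                        type_props = NULL,
                        attribute_ranges = default_attribute_ranges(),
                        angle_ranges = default_angle_ranges(),
                        seed = 1L) {
  mode <- match.arg(mode)
  validate_ranges(attribute_ranges, angle_ranges)

  if (mode == "table_exact") {
    if (is.null(joint_counts)) {
      stop("table-exact mode requires `joint_counts`", call. = FALSE)
    }
    if (is.matrix(joint_counts)) joint_counts <- list(rter = joint_counts)
    if (is.null(names(joint_counts)) ||
        !all(names(joint_counts) %in% rotation_components())) {
      stop("`joint_counts` must be named by rotation component (",
           paste(rotation_components(), collapse = ", "), ")", call. = FALSE)
    }
    for (nm in names(joint_counts)) {
      m <- joint_counts[[nm]]
      if (!is.matrix(m) || !all(dim(m) == c(3, 3)) ||
          any(m < 0) || any(m != round(m))) {
        stop(sprintf("`joint_counts$%s` must be a 3x3 matrix of non-negative integer counts", nm),
             call. = FALSE)
      }
    }
    csums <- lapply(joint_counts, colSums)
    if (length(unique(vapply(csums, paste, character(1), collapse = ","))) != 1) {
      stop("all joint-count tables must have identical cluster (column) sums",
           call. = FALSE)
    }
    total <- sum(joint_counts[[1]])
    if (is.null(n_subjects)) n_subjects <- total
    if (n_subjects != total) {
      stop(sprintf("joint_counts sum to %d but n_subjects is %d",
                   total, n_subjects), call. = FALSE)
    }
    if (total == 0) stop("joint_counts must place at least one subject", call. = FALSE)
  } else {
    if (is.null(n_subjects) || n_subjects < 1) {
      stop("parametric mode requires `n_subjects` >= 1", call. = FALSE)
    }
    if (length(cluster_props) != 3 || any(cluster_props < 0) ||
        abs(sum(cluster_props) - 1) > 1e-8) {
      stop("`cluster_props` must be 3 non-negative proportions summing to 1",
           call. = FALSE)
    }
    if (is.null(type_props)) type_props <- default_type_props()
    type_props <- as.matrix(type_props)
    if (!all(dim(type_props) == c(4, 3)) || any(type_props < 0) ||
        any(abs(rowSums(type_props) - 1) > 1e-8)) {
      stop("`type_props` must be a 4x3 matrix (one row per rotation component) of proportions summing to 1 per row",
           call. = FALSE)
    }
    rownames(type_props) <- rotation_components()
  }

  structure(
    list(n_subjects = as.integer(n_subjects), mode = mode,
         joint_counts = joint_counts, cluster_props = cluster_props,
         type_props = if (mode == "parametric") type_props else NULL,
         attribute_ranges = attribute_ranges, angle_ranges = angle_ranges,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

default_type_props <- function() {
  counts <- reference_joint_counts("real")
  t(vapply(counts, function(m) rowSums(m) / sum(m), numeric(3)))
}

validate_ranges <- function(attribute_ranges, angle_ranges) {
  for (nm in c("age", "weight", "height")) {
    r <- attribute_ranges[[nm]]
    if (is.null(r) || !all(dim(r) == c(3, 2)) || any(r[, 1] > r[, 2]) ||
        any(r <= 0)) {
      stop(sprintf("attribute_ranges$%s must be a 3x2 matrix of positive lo/hi bounds", nm),
           call. = FALSE)
    }
  }
  # ranges must be compatible with the rule-based classifier, otherwise the
  # requested cell can never be realised
  if (attribute_ranges$age[1, 1] <= 30) {
    stop("infeasible spec: Cluster 1 requires age > 30 years", call. = FALSE)
  }
  if (any(attribute_ranges$age[2:3, 2] > 30)) {
    stop("infeasible spec: Clusters 2-3 require age <= 30 years", call. = FALSE)
  }
  if (attribute_ranges$weight[2, 2] > 60) {
    stop("infeasible spec: Cluster 2 requires weight <= 60 kg", call. = FALSE)
  }
  if (attribute_ranges$weight[3, 1] <= 60) {
    stop("infeasible spec: Cluster 3 requires weight > 60 kg", call. = FALSE)
  }
  if (any(attribute_ranges$height > 3)) {
    stop("height ranges must be in metres (<= 3)", call. = FALSE)
  }
  if (!all(dim(angle_ranges) == c(3, 2)) || any(angle_ranges < 0) ||
      any(angle_ranges > 90)) {
    stop("angle_ranges must be a 3x2 matrix within [0, 90] degrees",
         call. = FALSE)
  }
  ok <- angle_ranges[1, 2] <= 20 && angle_ranges[2, 1] >= 20 &&
    angle_ranges[2, 2] <= 65 && angle_ranges[3, 1] >= 65
  if (!ok) {
    stop("infeasible spec: angle ranges must respect the type boundaries (20 and 65 degrees)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d subjects, %s mode, seed %d\n",
              x$n_subjects, x$mode, x$seed))
  if (x$mode == "table_exact") {
    cat("  exact tables for:", paste(names(x$joint_counts), collapse = ", "),
        "\n  cluster sizes:", paste(colSums(x$joint_counts[[1]]), collapse = "/"),
        "\n")
  } else {
    cat("  cluster proportions:",
        paste(sprintf("%.3f", x$cluster_props), collapse = "/"), "\n")
  }
  invisible(x)
}

#' Generate a synthetic subject cohort
#'
#' Draws a cohort according to a [cohort_spec()]. In table-exact mode,
#' applying [label_cohort()] to the result and tabulating with
#' [contingency_table()] reproduces every supplied joint-count table
#' exactly. Output is deterministic given the seed; row order is
#' randomised so cluster membership is not encoded in position.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer; defaults to `spec$seed`.
#' @return a subject data frame (columns `age`, `weight`, `height`,
#'   `rter`, `rtir`, `lter`, `ltir`).
#' @examples
#' spec <- cohort_spec(joint_counts = reference_joint_counts("real"),
#'                     mode = "table_exact", seed = 7)
#' cohort <- generate_cohort(spec)
#' table(classify_physical_cluster(cohort$age, cohort$weight, cohort$height))
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_subjects

  if (spec$mode == "table_exact") {
    cluster_sizes <- colSums(spec$joint_counts[[1]])
    cluster <- rep(1:3, cluster_sizes)
    types <- matrix(2L, n, 4,
                    dimnames = list(NULL, rotation_components()))
    for (nm in names(spec$joint_counts)) {
      panel <- spec$joint_counts[[nm]]
      for (cl in 1:3) {
        idx <- which(cluster == cl)
        tv <- rep(1:3, panel[, cl])
        types[idx, nm] <- sample_vec(tv)
      }
    }
  } else {
    cluster <- sample(1:3, n, replace = TRUE, prob = spec$cluster_props)
    types <- vapply(rotation_components(), function(nm) {
      sample(1:3, n, replace = TRUE, prob = spec$type_props[nm, ])
    }, integer(n))
  }

  draw_attr <- function(ranges) {
    r <- ranges[cluster, , drop = FALSE]
    stats::runif(n, r[, 1], r[, 2])
  }
  subjects <- data.frame(
    age    = draw_attr(spec$attribute_ranges$age),
    weight = draw_attr(spec$attribute_ranges$weight),
    height = draw_attr(spec$attribute_ranges$height)
  )
  for (nm in rotation_components()) {
    r <- spec$angle_ranges[types[, nm], , drop = FALSE]
    subjects[[nm]] <- stats::runif(n, r[, 1], r[, 2])
  }
  subjects <- subjects[sample_vec(seq_len(n)), , drop = FALSE]
  rownames(subjects) <- NULL
  validate_subjects(subjects)
}

# sample() with length-1 x would sample 1:x; this always permutes x itself
sample_vec <- function(x) x[sample.int(length(x))]

#' Gaussian blob fixture for clustering engines
#'
#' Generates `k` well-separated spherical Gaussian clusters with known
#' centers and labels, the standard ground-truth fixture for testing
#' center recovery. Center `j` sits at `separation * (j - 1)` in every
#' coordinate, so consecutive centers are `separation * sqrt(p)` apart.
#'
#' @param k number of clusters (>= 1).
#' @param n_per_cluster points per cluster (>= 1).
#' @param separation spacing of the center grid (> 0).
#' @param noise_sd per-coordinate Gaussian noise (>= 0).
#' @param p dimension.
#' @param seed integer RNG seed.
#' @return a list with `x` (an `n x p` matrix), `labels` (true cluster of
#'   each row, 1..k) and `centers` (`k x p` true centers).
#' @examples
#' b <- well_separated_blobs(k = 3, n_per_cluster = 20, seed = 1)
#' table(b$labels)
#' @export
well_separated_blobs <- function(k, n_per_cluster, separation = 10,
                                 noise_sd = 1, p = 2, seed = 1L) {
  stopifnot(k >= 1, n_per_cluster >= 1, separation > 0, noise_sd >= 0,
            p >= 1)
  set.seed(seed)
  centers <- matrix(separation * (seq_len(k) - 1), k, p)
  labels <- rep(seq_len(k), each = n_per_cluster)
  n <- length(labels)
  x <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  list(x = x, labels = labels, centers = centers)
}

#' Read a cohort specification from a YAML or JSON config
#'
#' The config maps directly onto [cohort_spec()] arguments; `seed` must be
#' explicit. `joint_counts` entries are given as 3x3 arrays (rows types,
#' columns clusters); `attribute_ranges`/`angle_ranges` as lo/hi pairs.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  if (is.null(cfg$seed)) {
    stop("cohort spec config must set an explicit `seed`", call. = FALSE)
  }
  as_mat <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = length(m), byrow = TRUE)
  }
  args <- list(
    n_subjects = cfg$n_subjects,
    mode = if (is.null(cfg$mode)) "parametric" else cfg$mode,
    seed = cfg$seed
  )
  if (!is.null(cfg$joint_counts)) {
    args$joint_counts <- lapply(cfg$joint_counts, as_mat)
  }
  if (!is.null(cfg$cluster_props)) args$cluster_props <- unlist(cfg$cluster_props)
  if (!is.null(cfg$type_props)) args$type_props <- as_mat(cfg$type_props)
  if (!is.null(cfg$attribute_ranges)) {
    args$attribute_ranges <- lapply(cfg$attribute_ranges, as_mat)
  }
  if (!is.null(cfg$angle_ranges)) args$angle_ranges <- as_mat(cfg$angle_ranges)
  do.call(cohort_spec, args)
}
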