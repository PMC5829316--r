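# Contingency and percentage tables over rotation type x physical
# cluster, label alignment for arbitrary cluster indices, and the study's
# min/max accuracy-rate statistic. All rounding is half-up at 2 decimals
# (base round() is round-half-even, which does not reproduce the published
# arithmetic), and accuracy is computed from the already-rounded
# percentages, matching how the published rates were derived.

#' Round half-up
#'
#' `round()` in R rounds half to even; the published percentage and
#' accuracy arithmetic is reproduced only by conventional half-up
#' rounding, so that is used throughout.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Tabulate rotation types against clusters
#'
#' Builds the 3x3 count table (rows Type 1..3, columns Cluster 1..3) from
#' per-subject labels. Grand and marginal totals are always recomputed
#' from the cells.
#'
#' @param type integer vector of rotation types (1..3).
#' @param cluster integer vector of cluster labels (1..3), same length.
#' @param rotation optional rotation component name carried as an
#'   attribute.
#' @return a `count_table`: 3x3 integer matrix.
#' @examples
#' contingency_table(type = c(2, 2, 1), cluster = c(2, 3, 2))
#' @export
contingency_table <- function(type, cluster, rotation = NULL) {
  if (length(type) != length(cluster)) {
    stop("`type` and `cluster` must have equal length", call. = FALSE)
  }
  if (length(type) == 0) stop("no subjects to tabulate", call. = FALSE)
  if (!all(type %in% 1:3) || !all(cluster %in% 1:3)) {
    stop("labels must be in 1..3", call. = FALSE)
  }
  counts <- table(factor(type, levels = 1:3),
                  factor(cluster, levels = 1:3))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(type = paste0("Type", 1:3),
                              cluster = paste0("Cluster", 1:3)))
  structure(m, rotation = rotation, class = c("count_table", class(m)))
}

#' @export
print.count_table <- function(x, ...) {
  rot <- attr(x, "rotation")
  if (!is.null(rot)) cat("Rotation component:", toupper(rot), "\n")
  m <- unclass(x)
  attr(m, "rotation") <- NULL
  out <- cbind(m, Total = rowSums(m))
  out <- rbind(out, Total = colSums(out))
  print(out)
  invisible(x)
}

#' Row-wise percentages of a count table
#'
#' Each cell becomes `100 * count / row total`, half-up rounded to 2
#' decimals, so each row sums to 100 within rounding slack. A row with
#' zero total yields `NA` across (there is nothing to express a share
#' of); a zero cell in a nonzero row is `0.00`, rendered as "-" by the
#' printed convention (see [format_percent_table()]).
#'
#' @param counts a `count_table` or any 3-column non-negative count
#'   matrix.
#' @return a `percent_table`: numeric matrix of the same shape.
#' @examples
#' row_percentages(contingency_table(c(2, 2, 1), c(2, 3, 2)))
#' @export
row_percentages <- function(counts) {
  m <- unclass(counts)
  attr(m, "rotation") <- NULL
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- rowSums(m)
  pct <- round_half_up(100 * sweep(m, 1, totals, "/"))
  pct[totals == 0, ] <- NA_real_
  structure(pct, rotation = attr(counts, "rotation"),
            class = c("percent_table", "matrix", "array"))
}

#' Render a percentage table with the published "-" convention
#'
#' @param pct a `percent_table` (or numeric matrix of percentages).
#' @param counts optional matching count matrix; when given, zero-count
#'   cells in nonzero rows also render as "-", matching the published
#'   layout.
#' @return character matrix.
#' @export
format_percent_table <- function(pct, counts = NULL) {
  m <- unclass(pct)
  out <- ifelse(is.na(m), "-", sprintf("%.2f", m))
  if (!is.null(counts)) out[unclass(counts) == 0] <- "-"
  dimnames(out) <- dimnames(m)
  out
}

#' @export
print.percent_table <- function(x, ...) {
  rot <- attr(x, "rotation")
  if (!is.null(rot)) cat("Rotation component:", toupper(rot), "\n")
  print(format_percent_table(x), quote = FALSE)
  invisible(x)
}

#' Accuracy rate between a real and a predicted percentage
#'
#' The study's agreement statistic for one type-by-cluster cell:
#' `100 * min(real, predicted) / max(real, predicted)`, half-up rounded
#' to 2 decimals — 100 exactly when the two shares agree, shrinking
#' towards 0 as they diverge. When both shares are zero the rate is
#' undefined (`NA`, printed "-"); when exactly one is zero it is 0.
#' `NA` inputs are treated as zero shares (the "-" prints in the
#' percentage tables stand for empty cells). Vectorised.
#'
#' @param real,predicted percentages in \[0, 100\].
#' @return numeric vector of rates in \[0, 100\], `NA` where undefined.
#' @examples
#' accuracy_rate(11.35, 8.51)
#' accuracy_rate(c(52.72, 44.82), c(62.18, 45.10))
#' @export
accuracy_rate <- function(real, predicted) {
  if (length(real) != length(predicted)) {
    stop("`real` and `predicted` must have equal length", call. = FALSE)
  }
  real <- ifelse(is.na(real), 0, real)
  predicted <- ifelse(is.na(predicted), 0, predicted)
  if (any(real < 0 | real > 100 | predicted < 0 | predicted > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  lo <- pmin(real, predicted)
  hi <- pmax(real, predicted)
  ifelse(hi == 0, NA_real_, round_half_up(100 * lo / hi))
}

#' Align arbitrary predicted cluster indices with reference labels
#'
#' Clustering engines emit arbitrary cluster indices; before any
#' agreement statistic they must be matched to the reference labelling.
#' Exhaustive search over all `k!` relabellings returns the permutation
#' maximising total agreement, ties broken by the lexicographically
#' smallest permutation.
#'
#' @param reference integer vector of reference labels (1..k).
#' @param predicted integer vector of predicted labels (1..k), same
#'   length.
#' @param k number of labels (default 3).
#' @return integer vector `perm` of length `k`: predicted label `j`
#'   should be read as `perm[j]`. Apply with `perm[predicted]`.
#' @examples
#' align_labels(reference = c(1, 1, 2, 3), predicted = c(2, 2, 1, 3))
#' @export
align_labels <- function(reference, predicted, k = 3) {
  if (length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must have equal length", call. = FALSE)
  }
  if (!all(reference %in% seq_len(k)) || !all(predicted %in% seq_len(k))) {
    stop(sprintf("labels must be in 1..%d", k), call. = FALSE)
  }
  perms <- permutations(k)
  agreement <- apply(perms, 1,
                     function(p) sum(p[predicted] == reference))
  # perms are generated in lexicographic order, so which.max breaks ties
  # towards the lexicographically smallest permutation
  perms[which.max(agreement), ]
}

permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Compare method percentage tables against the reference table
#'
#' Applies [accuracy_rate()] cell-wise to each supplied method table
#' against the real (rule-based) one, producing the per-method accuracy
#' tables of the study's final comparison.
#'
#' @param real `percent_table` of the rule-based labelling.
#' @param ... named `percent_table`s of predicted labellings (e.g.
#'   `ga = ..., km = ...`).
#' @return named list of `accuracy_table` matrices (3x3, `NA` where both
#'   shares are zero).
#' @examples
#' real <- row_percentages(reference_joint_counts("real", "rtir"))
#' km <- row_percentages(reference_joint_counts("km", "rtir"))
#' compare_methods(real, km = km)$km
#' @export
compare_methods <- function(real, ...) {
  methods <- list(...)
  if (length(methods) == 0 || is.null(names(methods)) ||
      any(names(methods) == "")) {
    stop("supply at least one named predicted percentage table",
         call. = FALSE)
  }
  rm <- unclass(real)
  lapply(methods, function(pred) {
    pm <- unclass(pred)
    if (!all(dim(pm) == dim(rm))) {
      stop("percentage tables must have matching shapes", call. = FALSE)
    }
    out <- matrix(accuracy_rate(as.vector(rm), as.vector(pm)),
                  nrow(rm), ncol(rm), dimnames = dimnames(rm))
    structure(out, class = c("accuracy_table", "matrix", "array"))
  })
}

#' @export
print.accuracy_table <- function(x, ...) {
  m <- unclass(x)
  print(ifelse(is.na(m), "-", sprintf("%.2f", m)), quote = FALSE)
  invisible(x)
}

#' Full evaluation of clustering engines on a labelled cohort
#'
#' End-to-end report for one rotation component: rule-based labels define
#' the reference clusters and the rotation types; each fitted model's
#' labels are aligned with the reference via [align_labels()]; counts,
#' row percentages and accuracy tables are assembled per method.
#'
#' @param subjects subject data frame.
#' @param rotation rotation component to type.
#' @param ... named `cluster_model`s (or bare integer label vectors),
#'   e.g. `km = kmeans_fit(...)`, `ga = ga_cluster_fit(...)`.
#' @return list with `rotation`, `reference` (list of `counts` and
#'   `percents`) and per-method lists of aligned `counts`, `percents`
#'   and `accuracy`.
#' @export
evaluate_methods <- function(subjects, rotation = rotation_components(),
                             ...) {
  rotation <- match.arg(rotation)
  labels <- label_cohort(subjects, rotation)
  methods <- list(...)
  if (length(methods) == 0 || is.null(names(methods)) ||
      any(names(methods) == "")) {
    stop("supply at least one named model or label vector", call. = FALSE)
  }
  ref_counts <- contingency_table(labels$type, labels$cluster,
                                  rotation = rotation)
  ref_pct <- row_percentages(ref_counts)
  out <- list(rotation = rotation,
              reference = list(counts = ref_counts, percents = ref_pct))
  out$methods <- lapply(methods, function(m) {
    pred <- if (inherits(m, "cluster_model")) m$cluster else as.integer(m)
    perm <- align_labels(labels$cluster, pred)
    aligned <- perm[pred]
    counts <- contingency_table(labels$type, aligned, rotation = rotation)
    pct <- row_percentages(counts)
    list(permutation = perm, counts = counts, percents = pct,
         accuracy = compare_methods(ref_pct, m = pct)$m)
  })
  out
}
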