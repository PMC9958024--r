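# Stratification of subjects by clinical asymmetry magnitude (menton
# deviation, mm) with 1-D k-medoids, and silhouette scoring.

#' k-medoids clustering of asymmetry magnitudes
#'
#' Partitioning Around Medoids (PAM: deterministic build phase followed by
#' swap to convergence) on scalar values with absolute-difference distance.
#' Samples are labelled by their nearest medoid; distance ties go to the
#' lower medoid value. PAM is deterministic, so `seed` does not affect the
#' result; the argument exists for interface stability.
#'
#' @param values numeric vector (mm, >= 0).
#' @param k number of clusters; must not exceed the number of distinct values.
#' @param seed unused, kept for interface stability.
#' @return A `cluster_result`: list with `labels` (1..k, ordered by ascending
#'   medoid), `medoids` (ascending data values), `cost` (sum of distances to
#'   assigned medoids) and `silhouette`.
#' @export
kmedoids <- function(values, k, seed = 0L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (k > length(unique(values))) {
    stop("k exceeds the number of distinct values", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  medoids <- if (k == length(values)) {
    sort(values)  # every point its own medoid; pam requires k < n
  } else {
    fit <- cluster::pam(matrix(values, ncol = 1), k = k, metric = "manhattan",
                        keep.diss = FALSE, keep.data = FALSE)
    sort(as.numeric(fit$medoids))
  }
  # nearest-medoid labels with ties to the lower medoid value
  d <- abs(outer(values, medoids, `-`))
  labels <- max.col(-d, ties.method = "first")
  cost <- sum(d[cbind(seq_along(values), labels)])
  sil <- if (k >= 2 && length(unique(labels)) >= 2) {
    silhouette_coefficient(values, labels)
  } else {
    NA_real_
  }
  structure(
    list(labels = labels, medoids = medoids, cost = cost, silhouette = sil),
    class = "cluster_result"
  )
}

#' Mean silhouette coefficient of a 1-D clustering
#'
#' For each sample, `a` is its mean distance to its own cluster's other
#' members and `b` the smallest mean distance to another cluster; the sample
#' silhouette is `(b - a) / max(a, b)`, zero for singleton clusters. The
#' coefficient is the mean over samples and lies in `[-1, 1]`.
#'
#' @param values numeric vector.
#' @param labels integer cluster labels, at least two distinct.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least two clusters", call. = FALSE)
  }
  n <- length(values)
  stopifnot(length(labels) == n)
  d <- abs(outer(values, values, `-`))
  sizes <- tabulate(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sizes[labels[i]] == 1) {
      s[i] <- 0
      next
    }
    a <- sum(d[i, own]) / (sizes[labels[i]] - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Name asymmetry clusters by severity
#'
#' With `k = 3`, clusters are named `mild`, `moderate` and `marked` by
#' ascending medoid value. The names follow the cluster order, not fixed
#' millimetre boundaries: published boundaries emerge from a particular
#' cohort and do not transfer.
#'
#' @param result a `cluster_result` from [kmedoids()] with 3 clusters.
#' @return The `cluster_result` with added `group_names` (per-cluster) and
#'   `groups` (per-sample factor).
#' @export
label_clusters <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (length(result$medoids) != 3) {
    stop("severity labelling requires exactly 3 clusters", call. = FALSE)
  }
  nm <- c("mild", "moderate", "marked") # medoids are stored ascending
  result$group_names <- nm
  result$groups <- factor(nm[result$labels], levels = nm)
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, medoids: %s, cost %.3f, silhouette %.3f\n",
              length(x$medoids), paste(signif(x$medoids, 4), collapse = ", "),
              x$cost, x$silhouette))
  invisible(x)
}
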