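#' Lloyd's k-means with random data-point initialization
#'
#' Initial centers are `k` distinct points drawn at random from the data;
#' iterations alternately assign every sample to its nearest center (squared
#' Euclidean distance, ties to the lowest center index) and move each center
#' to its cluster mean, until no center moves more than `tol` or `max_iter`
#' is reached. A cluster left empty is re-seeded at the point currently
#' farthest from its assigned center. Within-cluster inertia is recorded at
#' every iteration and is non-increasing.
#'
#' @param points Numeric matrix, one row per sample.
#' @param k Cluster count; must not exceed the number of distinct points.
#' @param seed Seed for the initial center draw.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the largest center displacement.
#' @return A `kmeans_result`: `centers` (k x d), `assignment` (cluster index
#'   per sample), `inertia`, `iterations`, and `inertia_history`.
#' @export
kmeans_lloyd <- function(points, k, seed = 1L, max_iter = 100L, tol = 1e-8) {
  points <- as.matrix(points)
  uniq <- unique(points)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(uniq))
    stop("k exceeds the number of distinct points", call. = FALSE)
  set.seed(seed)
  centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]

  sq_dist_to_centers <- function(ctr) {
    # n x k matrix of squared distances
    pn <- rowSums(points^2)
    cn <- rowSums(ctr^2)
    outer(pn, rep(1, nrow(ctr))) - 2 * points %*% t(ctr) +
      outer(rep(1, nrow(points)), cn)
  }

  assignment <- NULL
  inertia_history <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- pmax(sq_dist_to_centers(centers), 0)
    assignment <- max.col(-d2, ties.method = "first")
    inertia_history <- c(inertia_history,
                         sum(d2[cbind(seq_len(nrow(points)), assignment)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assignment == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        far <- which.max(d2[cbind(seq_len(nrow(points)), assignment)])
        new_centers[j, ] <- points[far, ]
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || iter >= max_iter) break
  }
  d2 <- pmax(sq_dist_to_centers(centers), 0)
  assignment <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(points)), assignment)])
  structure(list(centers = centers, assignment = assignment,
                 inertia = inertia, iterations = iter,
                 inertia_history = inertia_history),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> k = %d, %d iterations, inertia %.4g\n",
              nrow(x$centers), x$iterations, x$inertia))
  invisible(x)
}

new_projection2d <- function(x, y, sample_ids, xlab, ylab) {
  structure(data.frame(sample_id = sample_ids, x = x, y = y,
                       row.names = NULL),
            xlab = xlab, ylab = ylab, class = c("projection2d", "data.frame"))
}

#' Mean / standard-deviation 2-D projection
#'
#' Reduces each sample's feature vector to two descriptive statistics: the
#' mean (x) and the population standard deviation (divisor n, y). Used to
#' visualize high-dimensional spectra in a 2-D scatter.
#'
#' @param feature_matrix Numeric matrix, one row per sample, >= 2 columns.
#' @return A `projection2d` data frame (`sample_id`, `x`, `y`) with axis
#'   labels "Mean" and "STD" as attributes.
#' @export
mean_std_projection <- function(feature_matrix) {
  feature_matrix <- as.matrix(feature_matrix)
  if (ncol(feature_matrix) < 2L)
    stop("each sample needs >= 2 features (STD degenerate otherwise)",
         call. = FALSE)
  mu <- rowMeans(feature_matrix)
  std <- sqrt(rowMeans(feature_matrix^2) - mu^2)
  std[std < 0] <- 0  # guard tiny negative round-off
  ids <- rownames(feature_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(feature_matrix)))
  new_projection2d(mu, std, ids, "Mean", "STD")
}

#' Two-feature 2-D projection
#'
#' Selects two feature columns as scatter coordinates. When `i`/`j` are not
#' supplied, a distinct pair is drawn at random under `seed` and reported with
#' a message so the choice is reproducible.
#'
#' @param feature_matrix Numeric matrix, one row per sample.
#' @param i,j Feature column indices (`i != j`); optional.
#' @param seed Seed for the random pair draw when indices are not supplied.
#' @return A `projection2d` data frame with the feature indices as axis labels.
#' @export
feature_pair_projection <- function(feature_matrix, i = NULL, j = NULL,
                                    seed = 1L) {
  feature_matrix <- as.matrix(feature_matrix)
  p <- ncol(feature_matrix)
  if (is.null(i) || is.null(j)) {
    if (p < 2L) stop("need >= 2 features", call. = FALSE)
    set.seed(seed)
    pick <- sample.int(p, 2L)
    i <- pick[1]; j <- pick[2]
    message(sprintf("feature_pair_projection: randomly selected features %d and %d",
                    i, j))
  }
  if (i == j) stop("i and j must differ", call. = FALSE)
  if (i < 1L || i > p || j < 1L || j > p)
    stop("feature index out of range", call. = FALSE)
  ids <- rownames(feature_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(feature_matrix)))
  new_projection2d(feature_matrix[, i], feature_matrix[, j], ids,
                   sprintf("feature_%d", i), sprintf("feature_%d", j))
}

#' Cluster a 2-D projection and tabulate the result
#'
#' Runs [kmeans_lloyd()] on the projection coordinates and returns the point
#' table with cluster assignments and (optionally) true labels — the artifact
#' behind the visual cluster-analysis scatter plots.
#'
#' @param projection A `projection2d`.
#' @param k Cluster count (default 2: authentic vs non-authentic).
#' @param labels Optional true labels, one per sample.
#' @param seed Seed for center initialization.
#' @return A `data.frame` with `sample_id`, `x`, `y`, `cluster` and `label`.
#' @export
cluster_projection <- function(projection, k = 2L, labels = NULL, seed = 1L) {
  km <- kmeans_lloyd(as.matrix(projection[, c("x", "y")]), k, seed = seed)
  out <- data.frame(sample_id = projection$sample_id, x = projection$x,
                    y = projection$y, cluster = km$assignment,
                    label = if (is.null(labels)) NA_character_ else labels)
  attr(out, "kmeans") <- km
  out
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions up to relabeling.
#'
#' @param a,b Integer or character cluster assignments of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  n <- length(a)
  if (n < 2L) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
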