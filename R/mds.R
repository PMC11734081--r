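#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling: the squared distance matrix is double-centered
#' (`B = -1/2 J D^2 J`), eigendecomposed, and coordinates are formed from
#' the eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (non-Euclidean distance structure) never
#' contribute and are reported. The sign of each coordinate column is
#' fixed so that its largest-magnitude entry is positive, making
#' embeddings reproducible.
#'
#' @param d Square symmetric distance matrix (zero diagonal, non-negative
#'   entries), or a `dist` object.
#' @param k Number of dimensions requested (`k >= 1`); truncated with a
#'   warning when it exceeds the number of positive eigenvalues.
#' @return Object of class `nlr_mds`: list with `points` (n x k matrix),
#'   `eig` (all eigenvalues, descending), `k` (dimensions returned), and
#'   `gof` (sum of retained eigenvalues over the sum of positive
#'   eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  if (k < 1) stop("k must be >= 1")
  labels <- rownames(d)
  d2 <- d^2
  # double centering without forming J explicitly
  rm_ <- rowMeans(d2)
  gm <- mean(d2)
  b <- -0.5 * (sweep(sweep(d2, 1, rm_), 2, rm_) + gm)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  values <- e$values
  tol <- max(abs(values), 0) * 1e-12
  n_pos <- sum(values > tol)
  if (n_pos == 0L) {
    pts <- matrix(0, n, k, dimnames = list(labels, paste0("Dim", seq_len(k))))
    return(structure(list(points = pts, eig = values, k = k, gof = 0),
                     class = "nlr_mds"))
  }
  if (k > n_pos) {
    warning(sprintf("k = %d exceeds the %d positive eigenvalue(s); truncated",
                    k, n_pos))
    k <- n_pos
  }
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  pts <- vec %*% diag(sqrt(values[seq_len(k)]), k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(labels, paste0("Dim", seq_len(k)))
  structure(list(points = pts, eig = values, k = k,
                 gof = sum(values[seq_len(k)]) / sum(values[values > tol])),
            class = "nlr_mds")
}

#' @export
print.nlr_mds <- function(x, ...) {
  cat(sprintf("<nlr_mds> %d points in %d dimension(s); GOF = %.3f; %d negative eigenvalue(s)\n",
              nrow(x$points), x$k, x$gof, sum(x$eig < 0)))
  invisible(x)
}

#' Cluster-separation score of an embedding
#'
#' Mean silhouette width over all points, with Euclidean distances in the
#' embedding: for each point, `a` is the mean distance to its own group and
#' `b` the smallest mean distance to another group; the silhouette is
#' `(b - a) / max(a, b)` (0 for singleton groups or coincident geometry).
#' Values near 1 indicate well-separated groups, values near 0 no
#' structure.
#'
#' @param embedding `nlr_mds` object or a numeric coordinate matrix.
#' @param labels Group label per point (at least two distinct labels).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
cluster_recovery <- function(embedding, labels) {
  pts <- if (inherits(embedding, "nlr_mds")) embedding$points else as.matrix(embedding)
  labels <- as.character(labels)
  if (length(labels) != nrow(pts)) {
    stop("labels must have one entry per embedded point")
  }
  if (length(unique(labels)) < 2L) {
    stop("cluster_recovery requires at least two distinct labels")
  }
  d <- as.matrix(stats::dist(pts))
  groups <- unique(labels)
  n <- nrow(pts)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(groups, labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}
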