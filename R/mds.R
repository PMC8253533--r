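#' Classical (metric) multidimensional scaling
#'
#' Principal-coordinates embedding of a dissimilarity matrix: the
#' Gower-centred matrix \eqn{B = -\tfrac12 J (D \circ D) J} (with J the
#' centering projector \eqn{I - \mathbf{1}\mathbf{1}'/n}) is
#' eigendecomposed and coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues.  Axes are ordered by decreasing
#' eigenvalue, and each axis is given a deterministic sign: the loading of
#' largest magnitude (first such index on ties) is made positive, so runs
#' are reproducible across platforms.
#'
#' Rst matrices are generally non-Euclidean; negative eigenvalues are
#' dropped, as in standard PCoA practice, and reported as a distortion
#' diagnostic.
#'
#' @param D square symmetric dissimilarity matrix with zero diagonal and
#'   non-negative entries.
#' @param k number of coordinate axes requested (default 2).  If fewer
#'   positive eigenvalues exist, the embedding is truncated and flagged.
#' @param labels point labels; defaults to \code{rownames(D)}.
#' @return An object of class \code{ystr_mds}: \code{points} (n x k'
#'   matrix), \code{eigenvalues} (all, decreasing),
#'   \code{prop_variance} (share of each retained axis among positive
#'   eigenvalues), \code{negative_eigenvalues} and \code{truncated}.
#' @examples
#' D <- as.matrix(dist(cbind(c(0, 3, 5))))
#' classical_mds(D, k = 1)$points
#' @export
classical_mds <- function(D, k = 2L, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) stop("distance matrix must be square")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix must have zero diagonal")
  if (k < 1) stop("k must be >= 1")
  if (is.null(labels)) labels <- paste0("P", seq_len(n))

  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9 + 1e-300
  pos <- which(vals > tol)
  truncated <- k > length(pos)
  if (truncated) {
    warning(sprintf("only %d positive eigenvalue(s); embedding truncated",
                    length(pos)))
  }
  keep <- pos[seq_len(min(k, length(pos)))]
  pts <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep]), nrow = length(keep))
  # deterministic sign: make the largest-magnitude loading positive
  for (a in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, a]))
    if (pts[i, a] < 0) pts[, a] <- -pts[, a]
  }
  rownames(pts) <- labels
  if (ncol(pts) > 0) colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  structure(list(labels = labels, points = pts, eigenvalues = vals,
                 prop_variance = if (length(pos))
                   vals[keep] / sum(vals[pos]) else numeric(0),
                 negative_eigenvalues = vals[vals < -tol],
                 k_requested = as.integer(k), truncated = truncated),
            class = "ystr_mds")
}

#' @export
print.ystr_mds <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d points, %d axis/axes\n",
              length(x$labels), ncol(x$points)))
  if (length(x$prop_variance)) {
    cat(sprintf("  variance explained: %s\n",
                paste(sprintf("%.1f%%", 100 * x$prop_variance),
                      collapse = ", ")))
  }
  if (length(x$negative_eigenvalues)) {
    cat(sprintf("  %d negative eigenvalue(s) dropped (min %.3g)\n",
                length(x$negative_eigenvalues),
                min(x$negative_eigenvalues)))
  }
  print(round(x$points, 6))
  invisible(x)
}
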