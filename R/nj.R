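#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining, the agglomerative method that exactly
#' recovers any tree whose path-length matrix generated the input
#' (additive matrices).  At each step the pair minimising
#' \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)} is joined;
#' ties are broken deterministically on the lexicographically smallest
#' label pair, so identical inputs always give the identical Newick
#' string.  Limb lengths use the standard formulas
#' \eqn{l_i = d(i,j)/2 + (r_i - r_j)/(2(n-2))}, the reduction is
#' \eqn{d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2}, and the two-taxon base
#' case is a single edge split evenly between the leaves.
#'
#' The result is unrooted (final three lineages meet at one node of
#' degree three).  Negative estimated limb lengths --- possible on
#' non-additive input --- are reported; with \code{clamp = TRUE} a
#' negative limb is set to zero and the deficit moved to its sibling limb
#' so the joined pair's separation is preserved (Kuhner--Felsenstein
#' convention; at the final star, negatives are clamped to zero).
#'
#' @param D square symmetric matrix with zero diagonal (dissimilarities;
#'   clamp negative Rst entries to 0 before calling).
#' @param labels taxon labels; defaults to \code{rownames(D)}.
#' @param clamp zero out negative branch lengths (default FALSE).
#' @return An object of class \code{ystr_nj}: \code{newick} (string with
#'   full-precision branch lengths and quoted labels where needed),
#'   \code{tree} (an \pkg{ape} \code{phylo}), \code{labels} and
#'   \code{negative_branches} (count of negative limb estimates before any
#'   clamping).
#' @examples
#' D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = rep(list(c("A", "B", "C")), 2))
#' neighbor_joining(D)$newick
#' @export
neighbor_joining <- function(D, labels = rownames(D), clamp = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  if (ncol(D) != n) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix must have zero diagonal")
  if (is.null(labels)) labels <- paste0("T", seq_len(n))
  if (anyDuplicated(labels)) stop("taxon labels must be unique")
  storage.mode(D) <- "double"

  frag <- .quote_newick_label(labels)   # growing subtree strings
  lab <- labels                         # tie-break labels per active node
  neg <- 0L
  fmt <- function(x) sprintf("%.17g", x)

  while (length(lab) > 3) {
    m <- length(lab)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    minq <- min(Q)
    cand <- which(Q <= minq, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(lab[cand[, 1]], lab[cand[, 2]])
    hi <- pmax(lab[cand[, 1]], lab[cand[, 2]])
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) neg <- neg + 1L
    if (clamp) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    rest <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, rest] + D[j, rest] - D[i, j]) / 2
    D <- rbind(cbind(D[rest, rest, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[rest], newfrag)
    lab <- c(lab[rest], min(lab[c(i, j)]))
  }

  if (length(lab) == 2) {
    half <- D[1, 2] / 2
    newick <- sprintf("(%s:%s,%s:%s);", frag[1], fmt(half), frag[2], fmt(half))
  } else {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    if (any(c(l1, l2, l3) < 0)) neg <- neg + 1L
    if (clamp) { l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0) }
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  }
  tree <- ape::read.tree(text = newick)
  # ape keeps the quoting characters; restore the caller's labels
  tree$tip.label <- .unquote_newick_label(tree$tip.label)
  structure(list(newick = newick, tree = tree,
                 labels = labels, negative_branches = neg,
                 clamped = clamp),
            class = "ystr_nj")
}

.quote_newick_label <- function(x) {
  need <- grepl("[^A-Za-z0-9_.-]", x)
  x[need] <- paste0("'", gsub("'", "''", x[need]), "'")
  x
}

.unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' @export
print.ystr_nj <- function(x, ...) {
  cat(sprintf("Neighbor-joining tree: %d taxa%s\n", length(x$labels),
              if (x$negative_branches > 0)
                sprintf(" (%d negative branch estimate(s)%s)",
                        x$negative_branches,
                        if (x$clamped) ", clamped" else "") else ""))
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' Serialises a [neighbor_joining()] result (its full-precision Newick
#' string, with labels containing spaces or other special characters
#' single-quoted) or any \pkg{ape} \code{phylo} object.
#'
#' @param tree an \code{ystr_nj}, a \code{phylo}, or a Newick string.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  nwk <- if (inherits(tree, "ystr_nj")) tree$newick
         else if (inherits(tree, "phylo")) .phylo_to_newick(tree)
         else if (is.character(tree) && length(tree) == 1) tree
         else stop("unsupported tree object")
  writeLines(nwk, path)
  invisible(path)
}

# minimal phylo serializer with label quoting and full-precision lengths
.phylo_to_newick <- function(tr) {
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  len <- tr$edge.length
  rec <- function(node, edge_idx) {
    body <- if (node <= ntip) {
      .quote_newick_label(tr$tip.label[node])
    } else {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e)
        rec(tr$edge[e, 2], e), character(1)), collapse = ","), ")")
    }
    if (is.null(edge_idx) || is.null(len)) body
    else sprintf("%s:%.17g", body, len[edge_idx])
  }
  paste0(rec(root, NULL), ";")
}
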