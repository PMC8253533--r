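#' Squared repeat-score distance between two haplotypes
#'
#' The molecular distance underlying Rst: the sum over value slots of the
#' squared difference in repeat scores (Slatkin-type, as used for AMOVA on
#' microsatellites).  Multi-copy markers contribute two slots, paired
#' after ascending sort --- the pairing that minimises the squared
#' difference for two copies.  Microvariant alleles enter with their
#' numeric score (18.2 as 18.2 under the default scoring).
#'
#' @param h1,h2 named character vectors of canonical cells (as from
#'   [canonicalize_haplotype()]), or single-sample populations.
#' @param panel the [ystr_panel()] both haplotypes are typed on.
#' @param scoring microvariant scoring convention, see [allele_score()].
#' @return non-negative squared distance.
#' @export
haplotype_sq_distance <- function(h1, h2, panel,
                                  scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  s1 <- .cells_to_scores(h1, panel, scoring)
  s2 <- .cells_to_scores(h2, panel, scoring)
  sum((s1 - s2)^2)
}

.cells_to_scores <- function(h, panel, scoring) {
  if (inherits(h, "ystr_pop")) {
    stopifnot(h$n == 1)
    return(as.numeric(.pop_scores(h, scoring)))
  }
  h <- canonicalize_haplotype(as.list(h), panel)
  unlist(lapply(seq_len(nrow(panel)), function(j) {
    tk <- strsplit(h[[panel$marker[j]]], "-", fixed = TRUE)[[1]]
    sort(allele_score(tk, motif = panel$motif[j], scoring = scoring))
  }))
}

# pooled squared-distance matrix and block sizes for a list of populations
.pooled_sq_dist <- function(pops, scoring = "decimal") {
  panel <- pops[[1]]$panel
  for (p in pops) {
    if (!identical(p$panel$marker, panel$marker)) {
      stop("all populations must share one panel")
    }
  }
  X <- do.call(rbind, lapply(pops, .pop_scores, scoring = scoring))
  D2 <- as.matrix(stats::dist(X))^2
  list(D2 = D2, sizes = vapply(pops, function(p) p$n, integer(1)),
       labels = vapply(pops, function(p) p$name, character(1)))
}

# AMOVA variance components from a pooled squared-distance matrix and
# consecutive group sizes; the workhorse shared by amova_two_level() and
# the permutation machinery
.amova_from_d2 <- function(D2, sizes) {
  sizes <- unname(sizes)
  N <- sum(sizes)
  k <- length(sizes)
  ssd_total <- sum(D2) / (2 * N)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  ssd_within <- 0
  for (g in seq_len(k)) {
    idx <- starts[g]:ends[g]
    ssd_within <- ssd_within + sum(D2[idx, idx]) / (2 * sizes[g])
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- k - 1L
  df_within <- N - k
  sigma_b <- ssd_within / df_within
  n0 <- (N - sum(sizes^2) / N) / df_among
  sigma_a <- (ssd_among / df_among - sigma_b) / n0
  tot <- sigma_a + sigma_b
  degenerate <- tot <= 0
  rst <- if (degenerate) 0 else sigma_a / tot
  list(ssd_total = ssd_total, ssd_among = ssd_among,
       ssd_within = ssd_within, df_among = df_among,
       df_within = df_within, sigma_a = sigma_a, sigma_b = sigma_b,
       n0 = n0, rst = rst, degenerate = degenerate)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions the squared repeat-score distances among N individuals in k
#' populations into among- and within-population components, in the
#' classical sums-of-squares-from-distances form:
#' \deqn{SSD_{total} = \frac{1}{N}\sum_{i<j}\delta^2_{ij}, \qquad
#'       SSD_{within} = \sum_{pops}\frac{1}{n_p}\sum_{i<j \in p}\delta^2_{ij},}
#' \eqn{\sigma^2_b = SSD_{within}/(N-k)},
#' \eqn{n_0 = (N - \sum n_p^2/N)/(k-1)},
#' \eqn{\sigma^2_a = (SSD_{among}/(k-1) - \sigma^2_b)/n_0}, and
#' \eqn{R_{st} = \sigma^2_a / (\sigma^2_a + \sigma^2_b)}.
#'
#' When total variance is zero the statistic is undefined; Rst is then
#' reported as 0 with \code{degenerate = TRUE}.
#'
#' @param pops list of two or more [ystr_population()]s on one shared
#'   panel, each with \eqn{n \ge 2}.
#' @param scoring microvariant scoring convention, see [allele_score()].
#' @return An object of class \code{ystr_amova}: variance components,
#'   degrees of freedom, \code{rst} and a \code{degenerate} flag.
#' @export
amova_two_level <- function(pops, scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  if (length(pops) < 2) stop("AMOVA needs at least two populations")
  small <- vapply(pops, function(p) p$n < 2, logical(1))
  if (any(small)) {
    stop(sprintf("population(s) with n < 2: %s",
                 paste(vapply(pops[small], function(p) p$name, ""),
                       collapse = ", ")))
  }
  pd <- .pooled_sq_dist(pops, scoring)
  res <- .amova_from_d2(pd$D2, pd$sizes)
  structure(c(res, list(labels = pd$labels, sizes = pd$sizes)),
            class = "ystr_amova")
}

#' @export
print.ystr_amova <- function(x, ...) {
  cat("Two-level AMOVA\n")
  cat(sprintf("  populations: %s (n = %s)\n",
              paste(x$labels, collapse = ", "),
              paste(x$sizes, collapse = ", ")))
  cat(sprintf("  SSD among / within / total: %.6g / %.6g / %.6g\n",
              x$ssd_among, x$ssd_within, x$ssd_total))
  cat(sprintf("  sigma2 among = %.6g, within = %.6g (n0 = %.4f)\n",
              x$sigma_a, x$sigma_b, x$n0))
  cat(sprintf("  Rst = %.6f%s\n", x$rst,
              if (x$degenerate) " (degenerate: zero total variance)" else ""))
  invisible(x)
}

#' Permutation p-value for pairwise Rst
#'
#' Pools the individuals of two populations, reassigns them uniformly at
#' random to groups of the original sizes, and recomputes Rst for each
#' permutation.  The p-value uses the add-one estimator
#' \eqn{p = (b + 1)/(m + 1)} where b counts permuted Rst values greater
#' than or equal to the observed one (ties count as exceeding).
#' Deterministic given the seed.
#'
#' @param popA,popB populations on one shared panel.
#' @param n_perm number of permutations (\eqn{\ge 1}).
#' @param seed RNG seed.
#' @param scoring microvariant scoring convention.
#' @return list with \code{rst} (observed), \code{p}, \code{n_perm} and
#'   \code{seed}.
#' @export
permutation_p <- function(popA, popB, n_perm = 999L, seed = 1L,
                          scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  stopifnot(n_perm >= 1)
  pd <- .pooled_sq_dist(list(popA, popB), scoring)
  .permutation_p_d2(pd$D2, pd$sizes[1], pd$sizes[2], n_perm, seed)
}

# batched permutation test on a precomputed pooled D2 (two groups);
# within-group sums via quadratic forms z' D2 z / 2 with 0/1 indicators
.permutation_p_d2 <- function(D2, n1, n2, n_perm, seed) {
  N <- n1 + n2
  obs <- .amova_from_d2(D2, c(n1, n2))
  .with_seed(seed, {
    Z <- matrix(0, nrow = N, ncol = n_perm)
    for (b in seq_len(n_perm)) Z[sample.int(N, n1), b] <- 1
    S1 <- colSums(Z * (D2 %*% Z)) / 2
    Zc <- 1 - Z
    S2 <- colSums(Zc * (D2 %*% Zc)) / 2
    ssd_total <- sum(D2) / (2 * N)
    ssd_within <- S1 / n1 + S2 / n2
    ssd_among <- ssd_total - ssd_within
    sigma_b <- ssd_within / (N - 2)
    n0 <- (N - (n1^2 + n2^2) / N)
    sigma_a <- (ssd_among - sigma_b) / n0
    tot <- sigma_a + sigma_b
    rst_perm <- ifelse(tot <= 0, 0, sigma_a / tot)
    b_ge <- sum(rst_perm >= obs$rst - 1e-12)
    list(rst = obs$rst, p = (b_ge + 1) / (n_perm + 1),
         n_perm = n_perm, seed = seed, degenerate = obs$degenerate)
  })
}

#' Pairwise Rst matrix with permutation significance
#'
#' Computes Rst for every pair of populations by two-level AMOVA, a
#' permutation p-value per pair, and significance flags at the raw and the
#' multiplicity-corrected alpha.  Negative Rst estimates (sampling noise
#' around zero differentiation) are retained in \code{rst_raw} and clamped
#' to 0 in \code{rst} for downstream ordination and tree building, which
#' require dissimilarities.
#'
#' @param pops list of \eqn{\ge 2} populations on one shared panel.
#' @param n_perm permutations per pair.
#' @param seed base RNG seed; pair \eqn{(i, j)} uses a seed offset by its
#'   pair index so pairs are independent yet reproducible.
#' @param alpha nominal significance level.
#' @param correction \code{"bonferroni"} (alpha divided by \code{m}) or
#'   \code{"none"}.
#' @param m Bonferroni divisor; defaults to the number of pairwise
#'   comparisons.  Some studies instead divide by the sample size (e.g.
#'   0.05/431); pass that value explicitly to reproduce the convention.
#' @param scoring microvariant scoring convention.
#' @return An object of class \code{ystr_rst}: labels, \code{rst}
#'   (clamped), \code{rst_raw}, \code{p} matrix, significance matrices,
#'   \code{alpha}, \code{alpha_corrected}, \code{n_perm}, \code{seed}.
#' @export
pairwise_rst <- function(pops, n_perm = 10000L, seed = 1L, alpha = 0.05,
                         correction = c("bonferroni", "none"), m = NULL,
                         scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  correction <- match.arg(correction)
  k <- length(pops)
  if (k < 2) stop("need at least two populations")
  labels <- vapply(pops, function(p) p$name, character(1))
  n_pairs <- k * (k - 1) / 2
  if (is.null(m)) m <- n_pairs
  alpha_c <- if (correction == "bonferroni") bonferroni(alpha, m) else alpha
  rst_raw <- matrix(0, k, k, dimnames = list(labels, labels))
  pmat <- matrix(1, k, k, dimnames = list(labels, labels))
  pair_idx <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pair_idx <- pair_idx + 1L
      res <- permutation_p(pops[[i]], pops[[j]], n_perm = n_perm,
                           seed = seed + pair_idx, scoring = scoring)
      rst_raw[i, j] <- rst_raw[j, i] <- res$rst
      pmat[i, j] <- pmat[j, i] <- res$p
    }
  }
  rst <- pmax(rst_raw, 0)
  diag(rst) <- diag(rst_raw) <- 0
  structure(list(labels = labels, rst = rst, rst_raw = rst_raw, p = pmat,
                 significant = pmat <= alpha & row(pmat) != col(pmat),
                 significant_corrected =
                   pmat <= alpha_c & row(pmat) != col(pmat),
                 alpha = alpha, alpha_corrected = alpha_c, m = m,
                 n_perm = n_perm, seed = seed),
            class = "ystr_rst")
}

#' @export
print.ystr_rst <- function(x, ...) {
  cat(sprintf(
    "Pairwise Rst (%d populations, %d permutations, alpha = %g, corrected = %g)\n",
    length(x$labels), x$n_perm, x$alpha, x$alpha_corrected))
  cat("Rst (lower triangle) / p (upper triangle):\n")
  show <- x$rst
  show[upper.tri(show)] <- x$p[upper.tri(x$p)]
  print(round(show, 4))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' \code{alpha / m}.  The divisor is conventionally the number of
#' comparisons; some forensic population reports divide by the sample size
#' instead (e.g. 0.05/431, which rounds to 0.0001).
#'
#' @param alpha nominal level in (0, 1).
#' @param m positive integer divisor.
#' @return corrected level.
#' @examples
#' round(bonferroni(0.05, 431), 4)  # 0.0001
#' @export
bonferroni <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  alpha / m
}
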