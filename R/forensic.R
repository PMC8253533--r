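#' Direct-counting allele frequencies at one marker
#'
#' Counts allele units at a marker over the whole sample.  At single-copy
#' markers the unit is the allele; at multi-copy markers (DYS385a/b,
#' DYF387S1a/b) it is the canonical sorted pair configuration (e.g.
#' \code{"13-17"}), counted per male with denominator \code{n} --- the
#' convention under which DYS385a/b yields several dozen distinct units in
#' a large Han sample and behaves as a single highly diverse locus.
#'
#' @param pop an [ystr_population()] (complete haplotypes).
#' @param marker marker name present in the population's panel.
#' @return An object of class \code{ystr_freqs}: data frame with columns
#'   \code{marker}, \code{allele}, \code{count}, \code{frequency}, ordered
#'   by ascending allele score, with attributes \code{n} and \code{marker}.
#' @export
allele_frequencies <- function(pop, marker) {
  stopifnot(inherits(pop, "ystr_pop"))
  if (!marker %in% pop$panel$marker) {
    stop(sprintf("marker %s not in panel '%s'", marker,
                 attr(pop$panel, "panel_name")))
  }
  cell <- pop$calls[, marker]
  if (any(is.na(cell))) stop("missing calls; frequencies need complete data")
  tab <- table(cell)
  units <- names(tab)
  first <- vapply(strsplit(units, "-", fixed = TRUE), `[`, character(1), 1)
  ord <- order(allele_score(first), units)
  out <- data.frame(marker = marker, allele = units[ord],
                    count = as.integer(tab)[ord],
                    frequency = as.integer(tab)[ord] / pop$n,
                    stringsAsFactors = FALSE)
  structure(out, n = pop$n, marker = marker,
            class = c("ystr_freqs", "data.frame"))
}

#' Gene diversity of a frequency table
#'
#' Nei's unbiased gene diversity \eqn{GD = \frac{n}{n-1}(1 - \sum_i p_i^2)},
#' where \eqn{p_i} are the allele-unit frequencies and \eqn{n} the number
#' of sampled males.  Zero iff the marker is monomorphic.
#'
#' @param freqs an [allele_frequencies()] table.
#' @return GD in \eqn{[0, 1]}.
#' @export
gene_diversity <- function(freqs) {
  n <- attr(freqs, "n")
  if (is.null(n) || n < 2) stop("gene diversity undefined for n < 2")
  n / (n - 1) * (1 - sum(freqs$frequency^2))
}

#' Haplotype multiplicity spectrum
#'
#' The census at the heart of the haplotype-level statistics: how many
#' distinct haplotypes occur once (singletons), twice, three times, and so
#' on.  All of HD, DC, RMP and the proportion of unique haplotypes derive
#' from this spectrum.
#'
#' @param pop an [ystr_population()]; samples with incomplete haplotypes
#'   are rejected (strict statistics contract).
#' @param panel optional sub-panel to project onto first.
#' @return An object of class \code{ystr_spectrum}.
#' @seealso [as_spectrum()] to build a spectrum directly from published
#'   multiplicity counts.
#' @export
haplotype_spectrum <- function(pop, panel = NULL) {
  stopifnot(inherits(pop, "ystr_pop"))
  if (!is.null(panel)) pop <- project_population(pop, panel)
  if (!all(.complete_mask(pop))) {
    stop("incomplete haplotypes present; spectrum requires complete data")
  }
  mult <- table(table(.haplotype_keys(pop)))
  as_spectrum(setNames(as.integer(mult), names(mult)))
}

#' Build a multiplicity spectrum from counts
#'
#' @param counts named integer vector mapping multiplicity to the number
#'   of distinct haplotypes with that multiplicity, e.g.
#'   \code{c("1" = 405, "2" = 10, "3" = 2)} for 405 singletons, 10
#'   doubletons and 2 tripletons.
#' @return An object of class \code{ystr_spectrum}: list with fields
#'   \code{spectrum}, \code{n} (total samples) and \code{k} (distinct
#'   haplotypes).
#' @export
as_spectrum <- function(counts) {
  if (inherits(counts, "ystr_spectrum")) return(counts)
  mult <- as.integer(names(counts))
  cnt <- as.integer(counts)
  if (any(is.na(mult)) || any(mult < 1) || any(cnt < 0)) {
    stop("spectrum must map positive multiplicities to non-negative counts")
  }
  keep <- cnt > 0
  mult <- mult[keep]; cnt <- cnt[keep]
  ord <- order(mult)
  structure(list(spectrum = setNames(cnt[ord], mult[ord]),
                 n = sum(mult * cnt), k = sum(cnt)),
            class = "ystr_spectrum")
}

#' @export
print.ystr_spectrum <- function(x, ...) {
  cat(sprintf("Haplotype spectrum: n = %d samples, k = %d distinct\n",
              x$n, x$k))
  print(x$spectrum)
  invisible(x)
}

# sum of squared haplotype frequencies from a spectrum
.sum_p2 <- function(spec) {
  mult <- as.integer(names(spec$spectrum))
  sum(spec$spectrum * mult^2) / spec$n^2
}

#' Haplotype diversity
#'
#' \eqn{HD = \frac{n}{n-1}(1 - \sum_i p_i^2)} over whole-haplotype
#' frequencies --- the same estimator as [gene_diversity()] applied to
#' haplotypes.  Exactly 1 when every haplotype is unique.
#'
#' @param spec an \code{ystr_spectrum} (or a population, coerced via
#'   [haplotype_spectrum()]).
#' @return HD in \eqn{[0, 1]}.
#' @export
haplotype_diversity <- function(spec) {
  spec <- .as_spec(spec)
  if (spec$n < 2) stop("haplotype diversity undefined for n < 2")
  spec$n / (spec$n - 1) * (1 - .sum_p2(spec))
}

#' Discrimination capacity
#'
#' \eqn{DC = k / n}: the number of distinct haplotypes over the sample
#' size.
#'
#' @inheritParams haplotype_diversity
#' @return DC in \eqn{(0, 1]}.
#' @export
discrimination_capacity <- function(spec) {
  spec <- .as_spec(spec)
  spec$k / spec$n
}

#' Random match probability
#'
#' \eqn{RMP = \sum_i p_i^2} over haplotype frequencies: the chance that
#' two males drawn at random share a haplotype.  Algebraically
#' \eqn{RMP = 1 - HD \cdot (n-1)/n}.
#'
#' @inheritParams haplotype_diversity
#' @return RMP in \eqn{(0, 1]}.
#' @export
random_match_probability <- function(spec) {
  .sum_p2(.as_spec(spec))
}

#' Proportion of unique haplotypes
#'
#' Singleton haplotypes divided by the number of distinct haplotypes
#' \eqn{k}.
#'
#' @inheritParams haplotype_diversity
#' @return proportion in \eqn{[0, 1]}.
#' @export
proportion_unique <- function(spec) {
  spec <- .as_spec(spec)
  singles <- spec$spectrum[names(spec$spectrum) == "1"]
  if (length(singles) == 0) singles <- 0L
  as.numeric(singles) / spec$k
}

.as_spec <- function(x) {
  if (inherits(x, "ystr_spectrum")) x
  else if (inherits(x, "ystr_pop")) haplotype_spectrum(x)
  else as_spectrum(x)
}

#' Forensic summary report for both panels
#'
#' Computes, from one population typed on the 27-slot Yfiler Plus panel,
#' the standard forensic summary for both the 17-slot Yfiler projection
#' and the full panel: per-locus gene diversity, the haplotype spectrum,
#' the number of distinct haplotypes k, HD, DC, RMP and the proportion of
#' unique haplotypes.  Because the 17-slot panel is a projection of the
#' 27-slot one, k, HD and DC on 27 loci are always at least their 17-locus
#' values.
#'
#' @param pop population on the \code{"yfiler_plus"} panel.
#' @return An object of class \code{ystr_forensic_report}: list with one
#'   element per panel, each holding \code{per_locus_gd} (data frame),
#'   \code{spectrum}, \code{n}, \code{k}, \code{hd}, \code{dc}, \code{rmp}
#'   and \code{proportion_unique}.
#' @export
forensic_report <- function(pop) {
  stopifnot(inherits(pop, "ystr_pop"))
  if (attr(pop$panel, "panel_name") != "yfiler_plus") {
    stop("forensic_report() needs a population typed on the yfiler_plus panel")
  }
  panels <- list(yfiler = ystr_panel("yfiler"),
                 yfiler_plus = ystr_panel("yfiler_plus"))
  out <- lapply(names(panels), function(pn) {
    p <- project_population(pop, panels[[pn]])
    gd <- data.frame(
      marker = p$panel$marker,
      n_alleles = NA_integer_, gd = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(gd))) {
      fr <- allele_frequencies(p, gd$marker[i])
      gd$n_alleles[i] <- nrow(fr)
      gd$gd[i] <- gene_diversity(fr)
    }
    spec <- haplotype_spectrum(p)
    list(panel = pn, per_locus_gd = gd, spectrum = spec,
         n = spec$n, k = spec$k,
         hd = haplotype_diversity(spec),
         dc = discrimination_capacity(spec),
         rmp = random_match_probability(spec),
         proportion_unique = proportion_unique(spec))
  })
  names(out) <- names(panels)
  structure(out, population = pop$name, class = "ystr_forensic_report")
}

#' @export
print.ystr_forensic_report <- function(x, ...) {
  cat(sprintf("Forensic report for '%s'\n", attr(x, "population")))
  cat(sprintf("%-24s %10s %10s\n", "", "Yfiler(17)", "YfilerPlus(27)"))
  row <- function(lab, f) {
    cat(sprintf("%-24s %10s %10s\n", lab,
                f(x$yfiler), f(x$yfiler_plus)))
  }
  row("Sample size", function(r) r$n)
  row("Distinct haplotypes (k)", function(r) r$k)
  row("Proportion unique", function(r) sprintf("%.4f", r$proportion_unique))
  row("HD", function(r) sprintf("%.4f", r$hd))
  row("DC", function(r) sprintf("%.4f", r$dc))
  row("RMP", function(r) sprintf("%.4f", r$rmp))
  invisible(x)
}
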