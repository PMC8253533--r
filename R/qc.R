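#' Quality-control screen of a Y-STR population
#'
#' Reports the three anomaly classes routinely checked before submitting
#' haplotype data to reference databases:
#' \describe{
#'   \item{null alleles}{markers with no call for a sample (dropout);}
#'   \item{copy-number variants}{samples with more or fewer alleles at a
#'     marker than its nominal copy number (e.g. a duplicated allele at a
#'     normally single-copy locus);}
#'   \item{microvariants}{a census of off-ladder / intermediate alleles
#'     (partial-repeat designations such as 18.2), with occurrence counts
#'     per marker.}
#' }
#' Microvariants are ordinary, reportable alleles; they are counted, not
#' flagged as errors.  The screen never fails: it always returns a report.
#'
#' @param pop an [ystr_population()], typically parsed in lenient mode.
#' @return An object of class \code{ystr_qc}: list of data frames
#'   \code{null_alleles} (sample_id, marker), \code{cnv} (sample_id,
#'   marker, observed_alleles) and \code{microvariants} (marker, allele,
#'   count).
#' @examples
#' pop <- maoming_like_fixture(seed = 1)
#' qc <- qc_screen(pop)
#' sum(qc$microvariants$count)  # 9 off-ladder occurrences
#' @export
qc_screen <- function(pop) {
  stopifnot(inherits(pop, "ystr_pop"))
  nulls <- list(); cnvs <- list(); micro <- list()
  for (j in seq_len(nrow(pop$panel))) {
    m <- pop$panel$marker[j]
    copies <- pop$panel$copies[j]
    cell <- pop$calls[, j]
    miss <- which(is.na(cell))
    if (length(miss) > 0) {
      nulls[[m]] <- data.frame(sample_id = pop$sample_id[miss], marker = m,
                               stringsAsFactors = FALSE)
    }
    idx <- which(!is.na(cell))
    if (length(idx) > 0) {
      toks <- strsplit(cell[idx], "-", fixed = TRUE)
      nall <- lengths(toks)
      bad <- which(nall != copies)
      if (length(bad) > 0) {
        cnvs[[m]] <- data.frame(sample_id = pop$sample_id[idx[bad]],
                                marker = m, observed_alleles = nall[bad],
                                stringsAsFactors = FALSE)
      }
      flat <- unlist(toks)
      flat <- flat[.valid_tokens(flat)]
      mv <- flat[grepl("\\.", flat)]
      if (length(mv) > 0) {
        tab <- table(mv)
        micro[[m]] <- data.frame(marker = m, allele = names(tab),
                                 count = as.integer(tab),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    d[0, , drop = FALSE]
  }
  res <- list(
    null_alleles = if (length(nulls)) do.call(rbind, unname(nulls))
                   else empty(sample_id = "", marker = ""),
    cnv = if (length(cnvs)) do.call(rbind, unname(cnvs))
          else empty(sample_id = "", marker = "", observed_alleles = 0L),
    microvariants = if (length(micro)) do.call(rbind, unname(micro))
                    else empty(marker = "", allele = "", count = 0L),
    population = pop$name, n = pop$n
  )
  rownames(res$null_alleles) <- rownames(res$cnv) <-
    rownames(res$microvariants) <- NULL
  structure(res, class = "ystr_qc")
}

#' @export
print.ystr_qc <- function(x, ...) {
  cat(sprintf("QC report for '%s' (n = %d):\n", x$population, x$n))
  cat(sprintf("  null alleles:        %d\n", nrow(x$null_alleles)))
  cat(sprintf("  copy-number events:  %d\n", nrow(x$cnv)))
  cat(sprintf("  microvariant occurrences: %d at %d marker(s)\n",
              sum(x$microvariants$count),
              length(unique(x$microvariants$marker))))
  if (nrow(x$microvariants) > 0) {
    print.data.frame(x$microvariants, row.names = FALSE)
  }
  invisible(x)
}
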