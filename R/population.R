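#' Construct a population of Y-STR haplotypes
#'
#' The central container of the package: a named collection of male
#' haplotypes typed on one panel.  Internally each sample is a row of a
#' character matrix with one column per marker; multi-copy markers
#' (DYS385a/b, DYF387S1a/b) hold both alleles in a single cell joined by
#' \code{"-"} and canonically sorted ascending by repeat score, so two
#' samples differing only in the input order of a multi-copy pair compare
#' equal.
#'
#' In \code{"strict"} mode every cell must hold exactly the panel's copy
#' number of valid allele tokens; violations are errors.  In
#' \code{"lenient"} mode missing calls (\code{NA}, \code{""}) and wrong
#' allele counts are retained so that [qc_screen()] can report them;
#' samples with anomalies are excluded from diversity statistics.
#'
#' @param df data frame with a sample-id column and one column per panel
#'   marker (combined multi-copy cells such as \code{"13-17"}).
#' @param panel an [ystr_panel()].
#' @param name population label.
#' @param id_column name of the sample-id column.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return An object of class \code{ystr_pop}: list with fields
#'   \code{name}, \code{panel}, \code{sample_id}, \code{calls} (canonical
#'   character matrix) and \code{n}.
#' @export
ystr_population <- function(df, panel, name = "population",
                            id_column = "sample_id",
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ystr_panel"))
  if (!id_column %in% names(df)) {
    stop(sprintf("sample-id column '%s' not found", id_column))
  }
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  missing_markers <- setdiff(panel$marker, names(df))
  if (length(missing_markers) > 0) {
    stop(sprintf("incomplete haplotype table: missing marker column(s) %s",
                 paste(missing_markers, collapse = ", ")))
  }
  calls <- as.matrix(df[, panel$marker, drop = FALSE])
  storage.mode(calls) <- "character"
  calls <- .canonicalize_calls(calls, panel, mode)
  rownames(calls) <- NULL
  structure(list(name = name, panel = panel, sample_id = ids,
                 calls = calls, n = length(ids)),
            class = "ystr_pop")
}

# canonicalize every cell; strict mode errors on the first anomaly
.canonicalize_calls <- function(calls, panel, mode) {
  for (j in seq_len(nrow(panel))) {
    m <- panel$marker[j]
    copies <- panel$copies[j]
    cell <- calls[, j]
    blank <- is.na(cell) | trimws(cell) == "" | toupper(trimws(cell)) == "NA"
    cell[blank] <- NA_character_
    idx <- which(!is.na(cell))
    if (length(idx) > 0) {
      toks <- strsplit(trimws(cell[idx]), "-", fixed = TRUE)
      canon <- vapply(seq_along(idx), function(k) {
        tk <- trimws(toks[[k]])
        if (!all(.valid_tokens(tk))) {
          if (mode == "strict") {
            stop(sprintf("malformed allele %s at marker %s (sample row %d)",
                         sQuote(cell[idx[k]]), m, idx[k]))
          }
          return(cell[idx[k]])  # kept verbatim for QC
        }
        if (length(tk) != copies && mode == "strict") {
          stop(sprintf(
            "copy-number mismatch at marker %s (sample row %d): %d allele(s), expected %d",
            m, idx[k], length(tk), copies))
        }
        paste(tk[order(allele_score(tk))], collapse = "-")
      }, character(1))
      cell[idx] <- canon
    } else if (mode == "strict") {
      stop(sprintf("missing calls at marker %s", m))
    }
    if (mode == "strict" && any(is.na(cell))) {
      stop(sprintf("missing call at marker %s (sample row %d)",
                   m, which(is.na(cell))[1]))
    }
    calls[, j] <- cell
  }
  calls
}

#' Canonicalize a single haplotype
#'
#' Sorts multi-copy allele pairs ascending by repeat score and validates
#' copy numbers against the panel, yielding the canonical cell vector under
#' which haplotype equality is defined.
#'
#' @param raw named list mapping marker names to character vectors of
#'   allele tokens (one token for single-copy markers, two for multi-copy).
#' @param panel an [ystr_panel()].
#' @return named character vector of canonical cells, one per marker.
#' @examples
#' p <- ystr_panel("yfiler")
#' raw <- as.list(setNames(rep("12", nrow(p)), p$marker))
#' raw$DYS385 <- c("17", "13")
#' canonicalize_haplotype(raw, p)[["DYS385"]]  # "13-17"
#' @export
canonicalize_haplotype <- function(raw, panel) {
  missing_markers <- setdiff(panel$marker, names(raw))
  if (length(missing_markers) > 0) {
    stop(sprintf("incomplete haplotype: missing marker(s) %s",
                 paste(missing_markers, collapse = ", ")))
  }
  out <- vapply(seq_len(nrow(panel)), function(j) {
    tk <- as.character(raw[[panel$marker[j]]])
    tk <- unlist(strsplit(tk, "-", fixed = TRUE))
    if (length(tk) != panel$copies[j]) {
      stop(sprintf("copy-number error at %s: %d allele(s), expected %d",
                   panel$marker[j], length(tk), panel$copies[j]))
    }
    allele_score(tk)  # validates
    paste(tk[order(allele_score(tk))], collapse = "-")
  }, character(1))
  names(out) <- panel$marker
  out
}

#' @export
print.ystr_pop <- function(x, ...) {
  cat(sprintf("Y-STR population '%s': n = %d samples, panel '%s' (%d slots)\n",
              x$name, x$n, attr(x$panel, "panel_name"),
              attr(x$panel, "n_slots")))
  invisible(x)
}

#' Project a population onto a sub-panel
#'
#' Restricts haplotypes to the markers of a smaller panel, e.g. the
#' 17-slot Yfiler subset of a 27-slot Yfiler Plus population.  Projection
#' can only merge haplotypes, never split them, so the number of distinct
#' haplotypes never increases.
#'
#' @param pop an [ystr_population()].
#' @param panel target [ystr_panel()]; its markers must be a subset of the
#'   population's panel.
#' @return projected \code{ystr_pop}.
#' @export
project_population <- function(pop, panel) {
  stopifnot(inherits(pop, "ystr_pop"), inherits(panel, "ystr_panel"))
  missing_markers <- setdiff(panel$marker, pop$panel$marker)
  if (length(missing_markers) > 0) {
    stop(sprintf("target panel markers not typed: %s",
                 paste(missing_markers, collapse = ", ")))
  }
  pop$calls <- pop$calls[, panel$marker, drop = FALSE]
  pop$panel <- panel
  pop
}

# logical mask: rows with a full set of valid calls at the panel's copy
# numbers (the rows usable for diversity statistics)
.complete_mask <- function(pop) {
  ok <- rep(TRUE, pop$n)
  for (j in seq_len(nrow(pop$panel))) {
    cell <- pop$calls[, j]
    ok <- ok & !is.na(cell)
    idx <- which(!is.na(cell))
    toks <- strsplit(cell[idx], "-", fixed = TRUE)
    good <- vapply(toks, function(tk) {
      length(tk) == pop$panel$copies[j] && all(.valid_tokens(tk))
    }, logical(1))
    ok[idx] <- ok[idx] & good
  }
  ok
}

# numeric slot-score matrix (n x n_slots); multi-copy cells expand to two
# columns already sorted ascending by the canonical form
.pop_scores <- function(pop, scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  if (!all(.complete_mask(pop))) {
    stop("population contains incomplete or anomalous haplotypes; ",
         "run qc_screen() and use complete samples only")
  }
  cols <- vector("list", nrow(pop$panel))
  nms <- character(0)
  for (j in seq_len(nrow(pop$panel))) {
    toks <- strsplit(pop$calls[, j], "-", fixed = TRUE)
    copies <- pop$panel$copies[j]
    tk <- matrix(unlist(toks), ncol = copies, byrow = TRUE)
    sc <- matrix(allele_score(tk, motif = pop$panel$motif[j],
                              scoring = scoring),
                 ncol = copies)
    cols[[j]] <- sc
    nms <- c(nms, if (copies == 1) pop$panel$marker[j]
             else paste0(pop$panel$marker[j], c("a", "b")))
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  rownames(out) <- pop$sample_id
  out
}

# canonical haplotype keys; equality of keys == haplotype equality
.haplotype_keys <- function(pop) {
  apply(pop$calls, 1, paste, collapse = "|")
}
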