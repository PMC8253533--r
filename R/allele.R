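#' Parse a Y-STR allele designation
#'
#' Y-STR alleles are named by the number of full repeat units, with
#' microvariant (off-ladder / intermediate) alleles carrying a decimal
#' suffix giving the extra nucleotides beyond the last full repeat:
#' \code{"18"} is 18 full repeats, \code{"18.2"} is 18 repeats plus 2 nt.
#' The partial-repeat part is restricted to 1--3 nucleotides, consistent
#' with repeat units of up to four (and more) bases in standard
#' nomenclature.
#'
#' @param token a single allele designation such as \code{"12"} or
#'   \code{"18.2"}.
#' @return An object of class \code{ystr_allele}: a list with integer
#'   fields \code{full} and \code{partial}.
#' @examples
#' a <- parse_allele("18.2")
#' a$full     # 18
#' a$partial  # 2
#' render_allele(a)  # "18.2"
#' @export
parse_allele <- function(token) {
  if (length(token) != 1L) stop("parse_allele() takes a single token")
  p <- .parse_tokens(token)
  structure(list(full = p$full, partial = p$partial), class = "ystr_allele")
}

#' Render an allele back to its designation string
#'
#' Inverse of [parse_allele()]: \code{render_allele(parse_allele(x)) == x}
#' for every valid token.
#'
#' @param a a \code{ystr_allele}, or an integer full-repeat count.
#' @param partial extra nucleotides (0--3) when \code{a} is given as an
#'   integer.
#' @return canonical designation string.
#' @export
render_allele <- function(a, partial = 0L) {
  if (inherits(a, "ystr_allele")) {
    full <- a$full
    partial <- a$partial
  } else {
    full <- as.integer(a)
  }
  if (partial == 0L) as.character(full) else paste0(full, ".", partial)
}

#' @export
print.ystr_allele <- function(x, ...) {
  cat("Y-STR allele", render_allele(x), "\n")
  invisible(x)
}

#' Numeric repeat score of allele designations
#'
#' Converts designation strings to the numeric scale used for molecular
#' (squared-difference) distances.  Two conventions are supported:
#' \describe{
#'   \item{\code{"decimal"}}{the printed name read as a number
#'     (\code{18.2} scores 18.2); the default, transparent against
#'     published tables.}
#'   \item{\code{"motif"}}{partial nucleotides expressed as a fraction of
#'     the repeat-unit length (\code{18.2} at a tetranucleotide locus
#'     scores 18.5), the biologically proportional alternative.}
#' }
#'
#' @param tokens character vector of allele designations.
#' @param motif repeat-unit length(s) in nucleotides; recycled; only used
#'   for \code{scoring = "motif"}.
#' @param scoring \code{"decimal"} (default) or \code{"motif"}.
#' @return numeric vector of scores, strictly increasing in
#'   (full, partial) lexicographic order.
#' @export
allele_score <- function(tokens, motif = 4L, scoring = c("decimal", "motif")) {
  scoring <- match.arg(scoring)
  p <- .parse_tokens(tokens)
  if (scoring == "decimal") p$full + p$partial / 10 else p$full + p$partial / motif
}

# vectorized strict parser; errors name the offending token
.parse_tokens <- function(tokens) {
  tokens <- as.character(tokens)
  ok <- grepl("^[0-9]+(\\.[0-9])?$", tokens)
  if (!all(ok)) {
    stop(sprintf("malformed allele token(s): %s",
                 paste(sQuote(unique(tokens[!ok])), collapse = ", ")))
  }
  full <- as.integer(sub("\\..*$", "", tokens))
  partial <- ifelse(grepl("\\.", tokens),
                    as.integer(sub("^[0-9]+\\.", "", tokens)), 0L)
  bad <- partial > 3L
  if (any(bad)) {
    stop(sprintf("partial repeat out of range (1-3 nt) in token(s): %s",
                 paste(sQuote(unique(tokens[bad])), collapse = ", ")))
  }
  list(full = full, partial = as.integer(partial))
}

# TRUE where token is a valid allele designation (no error)
.valid_tokens <- function(tokens) {
  tokens <- as.character(tokens)
  ok <- grepl("^[0-9]+(\\.[0-9])?$", tokens)
  ok[ok] <- {
    part <- ifelse(grepl("\\.", tokens[ok]),
                   as.integer(sub("^[0-9]+\\.", "", tokens[ok])), 0L)
    part <= 3L
  }
  ok
}
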