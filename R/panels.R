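#' Y-STR marker panels
#'
#' Definitions of the two commercial Y-STR panels handled by the package:
#' \code{"yfiler"} (17 value slots: 15 single-copy markers plus the two-copy
#' DYS385a/b) and \code{"yfiler_plus"} (27 value slots: the Yfiler markers
#' plus DYS449, DYS460, DYS481, DYS518, DYS533, DYS570, DYS576, DYS627 and
#' the two-copy DYF387S1a/b).  A panel is a data frame with one row per
#' marker and columns \code{marker}, \code{copies} (value slots contributed,
#' 1 or 2), \code{motif} (repeat-unit length in nucleotides, used by the
#' optional motif-proportional microvariant scoring), and plausible
#' \code{min_allele}/\code{max_allele} repeat counts used by the simulator.
#'
#' The allele ranges are synthetic plausibility bounds taken from common
#' commercial allelic ladders; they parameterise the data generators and are
#' not frequency estimates for any real population.
#'
#' @param name \code{"yfiler"} or \code{"yfiler_plus"}.
#' @return An object of class \code{ystr_panel}: the marker data frame with
#'   attributes \code{panel_name} and \code{n_slots}.
#' @examples
#' p <- ystr_panel("yfiler_plus")
#' sum(p$copies)  # 27 value slots
#' @export
ystr_panel <- function(name = c("yfiler_plus", "yfiler")) {
  name <- match.arg(name)
  def <- .panel_marker_table()
  if (name == "yfiler") def <- def[def$in_yfiler, ]
  def$in_yfiler <- NULL
  rownames(def) <- NULL
  structure(def,
            panel_name = name,
            n_slots = sum(def$copies),
            class = c("ystr_panel", "data.frame"))
}

# marker, copies, motif length, plausible ladder range, Yfiler membership
.panel_marker_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
marker    copies motif min_allele max_allele in_yfiler
DYS19     1      4     12         17         TRUE
DYS385    2      4     10         20         TRUE
DYS389I   1      4     11         15         TRUE
DYS389II  1      4     26         33         TRUE
DYS390    1      4     20         26         TRUE
DYS391    1      4     8          13         TRUE
DYS392    1      3     10         16         TRUE
DYS393    1      4     11         16         TRUE
DYS437    1      4     13         17         TRUE
DYS438    1      5     8          13         TRUE
DYS439    1      4     10         14         TRUE
DYS448    1      6     17         22         TRUE
DYS456    1      4     13         18         TRUE
DYS458    1      4     14         20         TRUE
DYS635    1      4     19         25         TRUE
YGATAH4   1      4     10         14         TRUE
DYS449    1      4     26         36         FALSE
DYS460    1      4     9          13         FALSE
DYS481    1      3     20         28         FALSE
DYS518    1      4     35         44         FALSE
DYS533    1      4     10         14         FALSE
DYS570    1      4     14         21         FALSE
DYS576    1      4     14         21         FALSE
DYS627    1      4     16         24         FALSE
DYF387S1  2      4     33         41         FALSE
")
  tab
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat(sprintf("Y-STR panel '%s': %d markers, %d value slots\n",
              attr(x, "panel_name"), nrow(x), attr(x, "n_slots")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Normalize marker-name dialects
#'
#' Maps spelling variants seen in haplotype tables onto the package's
#' internal marker names: case, spaces, hyphens, underscores and slashes are
#' ignored, so \code{"Y GATA H4"}, \code{"Y-GATA-H4"} and \code{"YGATAH4"}
#' all resolve to \code{YGATAH4}, and \code{"DYS385a/b"} resolves to
#' \code{DYS385}.  Copy suffixes on multi-copy markers (\code{DYS385a},
#' \code{DYS385b}) are preserved as attribute \code{copy} so split-column
#' tables can be reassembled.
#'
#' @param x character vector of raw column names.
#' @return character vector of normalized base names with attribute
#'   \code{copy} (integer vector: 1, 2 or NA when no suffix).
#' @export
normalize_marker_name <- function(x) {
  up <- toupper(gsub("[ _/-]", "", x))
  up <- sub("^YGATAH4$|^GATAH4$", "YGATAH4", up)
  copy <- rep(NA_integer_, length(up))
  multi <- c("DYS385", "DYF387S1")
  for (m in multi) {
    hit_ab <- up == paste0(m, "AB")
    up[hit_ab] <- m
    for (k in 1:2) {
      hit <- up == paste0(m, c("A", "B")[k])
      up[hit] <- m
      copy[hit] <- k
    }
  }
  structure(up, copy = copy)
}
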