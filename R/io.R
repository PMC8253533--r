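#' Haplotype-table dialect
#'
#' Describes how a haplotype table is laid out on disk: field delimiter,
#' whether multi-copy markers occupy one combined column (\code{"13-17"})
#' or two split columns (\code{DYS385a}, \code{DYS385b}), and the name of
#' the sample-id column.  A table written in any dialect re-reads to an
#' identical population.
#'
#' @param delimiter \code{"tab"} or \code{"comma"}.
#' @param multicopy \code{"combined"} or \code{"split"}.
#' @param id_column sample-id column name.
#' @return An object of class \code{ystr_dialect}.
#' @export
haplotype_dialect <- function(delimiter = c("tab", "comma"),
                              multicopy = c("combined", "split"),
                              id_column = "sample_id") {
  structure(list(delimiter = match.arg(delimiter),
                 multicopy = match.arg(multicopy),
                 id_column = id_column),
            class = "ystr_dialect")
}

.delim_char <- function(dialect) if (dialect$delimiter == "tab") "\t" else ","

#' Read a haplotype table
#'
#' Reads a delimited table with one row per male and one column per
#' marker, in the style used for haplotype-database submissions.  Header
#' names are normalised across dialects ("Y GATA H4", "YGATAH4" and
#' "Y-GATA-H4" all resolve; "DYS385a/b" may be one combined or two split
#' columns).  Missing tokens (\code{""}, \code{"NA"}) are retained in
#' lenient mode and surface in [qc_screen()].
#'
#' @param path input file.
#' @param panel panel name or [ystr_panel()].
#' @param dialect an [haplotype_dialect()].
#' @param name population label (default: file name without extension).
#' @param mode \code{"strict"} (default; anomalies are errors) or
#'   \code{"lenient"} (anomalies retained for QC).
#' @return an [ystr_population()].
#' @export
read_haplotype_table <- function(path, panel = "yfiler_plus",
                                 dialect = haplotype_dialect(),
                                 name = NULL,
                                 mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.character(panel)) panel <- ystr_panel(panel)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = .delim_char(dialect),
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  nm <- normalize_marker_name(names(raw))
  copy <- attr(nm, "copy")
  id_norm <- normalize_marker_name(dialect$id_column)
  is_id <- nm == as.character(id_norm) | names(raw) == dialect$id_column
  if (!any(is_id)) {
    stop(sprintf("sample-id column '%s' not found", dialect$id_column))
  }
  df <- data.frame(sample_id = raw[[which(is_id)[1]]],
                   stringsAsFactors = FALSE)
  for (j in seq_len(nrow(panel))) {
    m <- panel$marker[j]
    hit <- which(nm == m)
    if (length(hit) == 0) {
      stop(sprintf("missing marker column: %s", m))
    }
    if (panel$copies[j] == 2 && length(hit) == 2) {
      ord <- order(copy[hit])  # a before b
      df[[m]] <- paste(trimws(raw[[hit[ord[1]]]]),
                       trimws(raw[[hit[ord[2]]]]), sep = "-")
    } else if (length(hit) == 1) {
      df[[m]] <- trimws(raw[[hit]])
    } else {
      stop(sprintf("marker %s appears in %d columns", m, length(hit)))
    }
  }
  extra <- setdiff(nm[!is_id], c(panel$marker, as.character(id_norm)))
  if (length(extra) > 0) {
    stop(sprintf("unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  ystr_population(df, panel, name = name, mode = mode)
}

#' Write a haplotype table
#'
#' Inverse of [read_haplotype_table()]: deterministic column order
#' (sample id, then panel markers), byte-identical across runs for the
#' same population and dialect.
#'
#' @param pop an [ystr_population()].
#' @param path output file.
#' @param dialect an [haplotype_dialect()].
#' @return \code{path}, invisibly.
#' @export
write_haplotype_table <- function(pop, path,
                                  dialect = haplotype_dialect()) {
  stopifnot(inherits(pop, "ystr_pop"))
  df <- data.frame(pop$sample_id, stringsAsFactors = FALSE)
  names(df) <- dialect$id_column
  for (j in seq_len(nrow(pop$panel))) {
    m <- pop$panel$marker[j]
    if (pop$panel$copies[j] == 2 && dialect$multicopy == "split") {
      parts <- strsplit(pop$calls[, m], "-", fixed = TRUE)
      df[[paste0(m, "a")]] <- vapply(parts, `[`, character(1), 1)
      df[[paste0(m, "b")]] <- vapply(parts, `[`, character(1), 2)
    } else {
      df[[m]] <- pop$calls[, m]
    }
  }
  utils::write.table(df, path, sep = .delim_char(dialect),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write allele-frequency tables
#'
#' Emits a deterministic CSV with columns \code{marker}, \code{allele},
#' \code{count}, \code{frequency} (rounded to \code{digits} decimals, the
#' conventional reporting precision) and \code{frequency_full} (full
#' precision, machine-readable).  Counts round-trip exactly through
#' [read_frequency_table()].
#'
#' @param freqs one [allele_frequencies()] table or a list of them.
#' @param path output file.
#' @param digits rounding for the report column (default 4).
#' @return \code{path}, invisibly.
#' @export
write_frequency_table <- function(freqs, path, digits = 4) {
  if (inherits(freqs, "ystr_freqs")) freqs <- list(freqs)
  for (f in freqs) {
    if (abs(sum(f$frequency) - 1) > 1e-9) {
      stop(sprintf("frequencies at %s do not sum to 1", attr(f, "marker")))
    }
  }
  tab <- do.call(rbind, lapply(freqs, function(f) {
    data.frame(marker = f$marker, allele = f$allele, count = f$count,
               frequency = sprintf(paste0("%.", digits, "f"),
                                   round(f$frequency, digits)),
               frequency_full = .fmt_full(f$frequency),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a frequency table written by [write_frequency_table()]
#'
#' @param path input file.
#' @return data frame with columns marker, allele, count, frequency
#'   (full precision).
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           colClasses = c("character", "character",
                                          "integer", "character",
                                          "numeric"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(marker = tab$marker, allele = tab$allele, count = tab$count,
             frequency = tab$frequency_full, stringsAsFactors = FALSE)
}

#' Write a distance matrix
#'
#' Supported formats: labelled CSV (header row and label column) and
#' square PHYLIP (taxon count on the first line; spaces in labels become
#' underscores).  Entries are written at full precision; a written matrix
#' re-reads equal to within 1e-12.
#'
#' @param D square symmetric numeric matrix with zero diagonal.
#' @param path output file.
#' @param labels row/column labels; defaults to \code{rownames(D)}.
#' @param format \code{"csv"} or \code{"phylip"}.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(D, path, labels = rownames(D),
                                  format = c("csv", "phylip")) {
  format <- match.arg(format)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("diagonal must be zero")
  if (is.null(labels)) labels <- paste0("P", seq_len(nrow(D)))
  if (format == "csv") {
    lines <- c(paste(c("label", labels), collapse = ","),
               vapply(seq_len(nrow(D)), function(i) {
                 paste(c(labels[i], .fmt_full(D[i, ])), collapse = ",")
               }, character(1)))
  } else {
    lab <- gsub("[[:space:]]", "_", labels)
    lines <- c(sprintf("%5d", nrow(D)),
               vapply(seq_len(nrow(D)), function(i) {
                 paste(c(lab[i], .fmt_full(D[i, ])), collapse = "  ")
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path input file.
#' @param format \code{"csv"} or \code{"phylip"}.
#' @return labelled numeric matrix.
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.table(path, header = TRUE, sep = ",",
                             check.names = FALSE, row.names = 1,
                             stringsAsFactors = FALSE)
    D <- as.matrix(tab)
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
    lab <- vapply(parts, `[`, character(1), 1)
    D <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(D) <- list(lab, lab)
  }
  D
}

#' Read an analysis configuration file
#'
#' A single YAML key-value file selecting inputs and analysis settings;
#' see [run_pipeline()] for the recognised keys.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
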