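#' Run the full Y-STR population analysis pipeline
#'
#' End-to-end orchestration of the package's workflow, in the order a
#' forensic population report is assembled: per-population quality
#' control, forensic parameters on both the 17- and 27-slot panels, then
#' --- when two or more populations are supplied --- pairwise Rst with
#' permutation p-values and Bonferroni correction, a 2-D classical MDS of
#' the Rst matrix, and a neighbor-joining tree.  Single-population runs
#' skip the comparative stages with a logged notice.  Stages fail fast:
#' an error aborts the run naming the failing stage.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with keys:
#' \describe{
#'   \item{populations}{named character vector/list of haplotype-table
#'     paths, or a list of [ystr_population()] objects.}
#'   \item{panel}{\code{"yfiler_plus"} (default) or \code{"yfiler"}.}
#'   \item{dialect}{optional list with \code{delimiter},
#'     \code{multicopy}, \code{id_column}.}
#'   \item{n_perm, seed, alpha}{permutation-test settings (defaults
#'     10000, 1, 0.05).}
#'   \item{bonferroni_m}{\code{"pairs"} (default: number of pairwise
#'     comparisons) or an explicit integer divisor, e.g. a study's
#'     sample-size convention such as 431.}
#'   \item{out_dir}{output directory (created if needed).}
#' }
#'
#' All numeric report files carry both 4-decimal and full-precision
#' columns; every random stage records its seed in the manifest, and
#' re-running an unchanged configuration reproduces all outputs
#' byte-identically.
#'
#' @param config named list or YAML path.
#' @param out_dir overrides \code{config$out_dir}.
#' @return An object of class \code{ystr_manifest} (invisibly): the
#'   configuration snapshot, seeds, input and output file digests.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel_name <- config$panel %||% "yfiler_plus"
  panel <- ystr_panel(panel_name)
  dia <- do.call(haplotype_dialect, config$dialect %||% list())
  n_perm <- as.integer(config$n_perm %||% 10000L)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- as.numeric(config$alpha %||% 0.05)

  stage <- function(name, expr) {
    message(sprintf("[ystrkit] stage %s", name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  # ---- load ----
  input_files <- character(0)
  pops <- stage("load", {
    src <- config$populations
    if (is.list(src) && length(src) > 0 && inherits(src[[1]], "ystr_pop")) {
      src
    } else {
      paths <- unlist(src)
      input_files <- normalizePath(paths)
      ps <- lapply(seq_along(paths), function(i) {
        read_haplotype_table(paths[[i]], panel = panel, dialect = dia,
                             name = names(paths)[i] %||% NULL,
                             mode = "lenient")
      })
      ps
    }
  })
  if (length(pops) == 0) stop("config names no population tables")

  # ---- qc ----
  qcs <- stage("qc", {
    qcs <- lapply(pops, qc_screen)
    bindqc <- function(field) {
      do.call(rbind, lapply(qcs, function(q) {
        d <- q[[field]]
        if (nrow(d) == 0) return(NULL)
        cbind(population = q$population, d)
      }))
    }
    for (field in c("null_alleles", "cnv", "microvariants")) {
      d <- bindqc(field)
      if (is.null(d)) d <- data.frame(population = character(0))
      utils::write.table(d, emit(file.path(out_dir,
                                           paste0("qc_", field, ".csv"))),
                         sep = ",", quote = FALSE, row.names = FALSE)
    }
    qcs
  })

  # statistics use complete haplotypes only (QC holds the anomalies)
  pops_ok <- lapply(pops, .complete_subset)

  # ---- forensic parameters ----
  stage("forensic", {
    for (p in pops_ok) {
      if (attr(p$panel, "panel_name") == "yfiler_plus") {
        rep_ <- forensic_report(p)
        tab <- do.call(rbind, lapply(rep_, function(r) {
          data.frame(population = p$name, panel = r$panel, n = r$n,
                     k = r$k,
                     proportion_unique = .round4(r$proportion_unique),
                     hd = .round4(r$hd), dc = .round4(r$dc),
                     rmp = .round4(r$rmp),
                     hd_full = .fmt_full(r$hd), dc_full = .fmt_full(r$dc),
                     rmp_full = .fmt_full(r$rmp),
                     stringsAsFactors = FALSE)
        }))
        utils::write.table(tab,
          emit(file.path(out_dir, sprintf("forensic_%s.csv", p$name))),
          sep = ",", quote = FALSE, row.names = FALSE)
        gd <- rep_$yfiler_plus$per_locus_gd
        gd$gd_full <- .fmt_full(gd$gd)
        gd$gd <- .round4(gd$gd)
        utils::write.table(gd,
          emit(file.path(out_dir, sprintf("per_locus_gd_%s.csv", p$name))),
          sep = ",", quote = FALSE, row.names = FALSE)
      }
      freqs <- lapply(p$panel$marker, function(m) allele_frequencies(p, m))
      write_frequency_table(freqs,
        emit(file.path(out_dir, sprintf("frequencies_%s.csv", p$name))))
    }
  })

  # ---- comparative stages ----
  rst <- NULL
  if (length(pops_ok) >= 2) {
    m_conf <- config$bonferroni_m %||% "pairs"
    m <- if (identical(m_conf, "pairs")) NULL else as.integer(m_conf)
    rst <- stage("rst", {
      r <- pairwise_rst(pops_ok, n_perm = n_perm, seed = seed,
                        alpha = alpha, m = m)
      write_distance_matrix(r$rst, emit(file.path(out_dir, "rst.csv")))
      write_distance_matrix(r$rst_raw,
                            emit(file.path(out_dir, "rst_raw.csv")))
      pm <- r$p; diag(pm) <- 0  # writer wants zero diagonal
      write_distance_matrix(pm, emit(file.path(out_dir, "rst_p.csv")))
      writeLines(utils::capture.output(print(r)),
                 emit(file.path(out_dir, "amova_log.txt")))
      r
    })
    stage("mds", {
      if (length(pops_ok) >= 3) {
        emb <- classical_mds(rst$rst, k = 2)
        tab <- data.frame(label = emb$labels, emb$points,
                          stringsAsFactors = FALSE)
        utils::write.table(tab, emit(file.path(out_dir, "mds.csv")),
                           sep = ",", quote = FALSE, row.names = FALSE)
      } else {
        message("[ystrkit]   fewer than 3 populations; MDS skipped")
      }
    })
    stage("njtree", {
      tr <- neighbor_joining(rst$rst)
      write_newick(tr, emit(file.path(out_dir, "tree.nwk")))
    })
  } else {
    message("[ystrkit] single population: Rst/MDS/NJ stages skipped")
  }

  # ---- manifest ----
  manifest <- list(
    package = "ystrkit",
    version = as.character(utils::packageVersion("ystrkit")),
    config = list(panel = panel_name, n_perm = n_perm, seed = seed,
                  alpha = alpha,
                  bonferroni_m = config$bonferroni_m %||% "pairs",
                  populations = vapply(pops, function(p) p$name,
                                       character(1))),
    input_digests = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    outputs = as.list(setNames(unname(tools::md5sum(normalizePath(outputs))),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(manifest, class = "ystr_manifest"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop rows with missing or anomalous calls (they remain visible via QC)
.complete_subset <- function(pop) {
  keep <- .complete_mask(pop)
  pop$sample_id <- pop$sample_id[keep]
  pop$calls <- pop$calls[keep, , drop = FALSE]
  pop$n <- sum(keep)
  pop
}
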