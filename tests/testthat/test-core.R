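test_that("panels expose the documented slot structure", {
  p17 <- ystr_panel("yfiler")
  p27 <- ystr_panel("yfiler_plus")
  expect_equal(attr(p17, "n_slots"), 17L)
  expect_equal(attr(p27, "n_slots"), 27L)
  expect_equal(sum(p17$copies == 2), 1L)                 # DYS385 only
  expect_setequal(p27$marker[p27$copies == 2], c("DYS385", "DYF387S1"))
  expect_true(all(p17$marker %in% p27$marker))           # projection defined
})

test_that("marker-name dialects resolve to one internal name", {
  nm <- normalize_marker_name(c("Y GATA H4", "YGATAH4", "Y-GATA-H4",
                                "DYS385a/b", "dys385a", "DYS385b",
                                "DYF387S1a"))
  expect_equal(as.character(nm),
               c("YGATAH4", "YGATAH4", "YGATAH4", "DYS385", "DYS385",
                 "DYS385", "DYF387S1"))
  expect_equal(attr(nm, "copy"), c(NA, NA, NA, NA, 1L, 2L, 1L))
})

test_that("multi-copy pairs canonicalize to ascending order under every input ordering", {
  p <- ystr_panel("yfiler")
  raw <- as.list(setNames(rep("12", nrow(p)), p$marker))
  raw$DYS385 <- c("17", "13")
  h1 <- canonicalize_haplotype(raw, p)
  expect_equal(h1[["DYS385"]], "13-17")
  raw$DYS385 <- c("13", "17")
  expect_identical(canonicalize_haplotype(raw, p), h1)   # order-free equality
  raw$DYS385 <- c("13", "13")
  expect_equal(canonicalize_haplotype(raw, p)[["DYS385"]], "13-13")
  # microvariant sorts by score, not string
  raw$DYS385 <- c("13.2", "13")
  expect_equal(canonicalize_haplotype(raw, p)[["DYS385"]], "13-13.2")
  raw$DYS385 <- "17"
  expect_error(canonicalize_haplotype(raw, p), "copy-number")
  expect_error(canonicalize_haplotype(raw[-1], p), "incomplete")
})

test_that("populations enforce unique ids and complete strict calls", {
  pop <- single_locus_pop(c(14, 15, 15), "X")
  expect_equal(pop$n, 3L)
  df <- data.frame(sample_id = c("a", "a"), stringsAsFactors = FALSE)
  p <- ystr_panel("yfiler")
  for (j in seq_len(nrow(p))) {
    df[[p$marker[j]]] <- if (p$copies[j] == 2) "13-17" else "12"
  }
  expect_error(ystr_population(df, p), "duplicate sample_id")
  df$sample_id <- c("a", "b")
  df$DYS19 <- c("14", NA)
  expect_error(ystr_population(df, p), "missing call")
  expect_silent(ystr_population(df, p, mode = "lenient"))
})

test_that("projection never increases the number of distinct haplotypes", {
  p17 <- ystr_panel("yfiler")
  for (seed in 1:25) {
    spec <- withr::with_seed(seed, random_spectrum(40))
    pop <- from_spectrum(spec, "yfiler_plus", seed = seed)
    k27 <- haplotype_spectrum(pop)$k
    k17 <- haplotype_spectrum(project_population(pop, p17))$k
    expect_lte(k17, k27)
  }
})

test_that("qc_screen reports exactly the injected anomalies", {
  pop <- single_locus_pop(c(14, 15, 15, 16), "Q")
  clean <- qc_screen(pop)
  expect_equal(nrow(clean$null_alleles), 0L)
  expect_equal(nrow(clean$cnv), 0L)
  expect_equal(nrow(clean$microvariants), 0L)

  # inject: one null, one extra allele at single-copy DYS19, microvariants
  pop$calls[1, "DYS392"] <- NA
  pop$calls[2, "DYS19"] <- "14-15"
  pop$calls[1, "DYS448"] <- "18.2"
  pop$calls[2, "DYS448"] <- "18.2"
  pop$calls[3, "DYS448"] <- "19.2"
  pop$calls[4, "DYS458"] <- "18.2"
  qc <- qc_screen(pop)
  expect_equal(nrow(qc$null_alleles), 1L)
  expect_equal(qc$null_alleles$marker, "DYS392")
  expect_equal(nrow(qc$cnv), 1L)
  expect_equal(qc$cnv$observed_alleles, 2L)
  expect_equal(qc$cnv$marker, "DYS19")
  expect_equal(sum(qc$microvariants$count), 4L)
  expect_setequal(unique(qc$microvariants$marker), c("DYS448", "DYS458"))
  expect_equal(qc$microvariants$count[qc$microvariants$allele == "18.2" &
                                      qc$microvariants$marker == "DYS448"], 2L)
})

test_that("anomalous samples are excluded from statistics but kept in QC", {
  pop <- single_locus_pop(c(14, 15, 16), "L")
  pop$calls[2, "DYS390"] <- NA
  expect_error(haplotype_spectrum(pop), "incomplete")
  ok <- ystrkit:::.complete_subset(pop)
  expect_equal(ok$n, 2L)
  expect_equal(haplotype_spectrum(ok)$k, 2L)
})
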