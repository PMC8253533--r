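test_that("allele frequencies are direct counts", {
  pop <- single_locus_pop(c(10, 10, 10, 11), "F")
  fr <- allele_frequencies(pop, "DYS19")
  expect_equal(fr$allele, c("10", "11"))
  expect_equal(fr$frequency, c(0.75, 0.25))
  expect_equal(sum(fr$count), 4L)
  expect_error(allele_frequencies(pop, "DYS999"), "not in panel")
})

test_that("multi-copy frequencies count sorted pair configurations per male", {
  p <- ystr_panel("yfiler")
  df <- data.frame(sample_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  for (j in seq_len(nrow(p))) {
    df[[p$marker[j]]] <- if (p$copies[j] == 2) "13-17" else "12"
  }
  df$DYS385 <- c("13-17", "17-13", "14-18")   # order-free pairing
  pop <- ystr_population(df, p)
  fr <- allele_frequencies(pop, "DYS385")
  expect_equal(fr$allele, c("13-17", "14-18"))
  expect_equal(fr$frequency, c(2 / 3, 1 / 3))
  expect_equal(attr(fr, "n"), 3L)             # denominator is n, not 2n
})

test_that("gene diversity follows the unbiased n/(n-1) estimator", {
  mono <- allele_frequencies(single_locus_pop(rep(14, 6), "M"), "DYS19")
  expect_equal(gene_diversity(mono), 0)
  two <- allele_frequencies(single_locus_pop(c(14, 15), "T"), "DYS19")
  expect_equal(gene_diversity(two), 1)
  counts211 <- allele_frequencies(single_locus_pop(c(14, 14, 15, 16), "H"),
                                  "DYS19")
  expect_equal(gene_diversity(counts211), (4 / 3) * (1 - 0.375))
  attr(counts211, "n") <- 1L
  expect_error(gene_diversity(counts211), "n < 2")
})

test_that("the haplotype spectrum is an exact multiset census", {
  pop <- single_locus_pop(c(10, 10, 11, 12, 13), "S")   # {A,A,B,C,D}
  spec <- haplotype_spectrum(pop)
  expect_equal(spec$spectrum, c("1" = 3L, "2" = 1L))
  expect_equal(spec$k, 4L)
  expect_equal(spec$n, 5L)
  expect_error(as_spectrum(c("0" = 3)), "positive multiplicities")
})

test_that("HD, DC, RMP and proportion unique match hand arithmetic", {
  s <- as_spectrum(c("1" = 3, "2" = 1))                 # n = 5
  expect_equal(haplotype_diversity(s), 0.9)
  expect_equal(random_match_probability(s), 0.28)
  expect_equal(discrimination_capacity(s), 4 / 5)

  all_unique <- as_spectrum(c("1" = 37))
  expect_equal(haplotype_diversity(all_unique), 1)
  expect_equal(proportion_unique(all_unique), 1)
  expect_equal(discrimination_capacity(all_unique), 1)

  shared <- as_spectrum(c("4" = 1))                     # one haplotype, n = 4
  expect_equal(random_match_probability(shared), 1)
  expect_equal(haplotype_diversity(shared), 0)
  expect_equal(proportion_unique(shared), 0)
})

test_that("published-style spectra give the documented 4-decimal statistics", {
  s17 <- as_spectrum(c("1" = 328, "2" = 33, "3" = 6, "4" = 1, "5" = 3))
  s27 <- as_spectrum(c("1" = 405, "2" = 10, "3" = 2))
  expect_equal(s17$n, 431L)
  expect_equal(s17$k, 371L)
  expect_equal(s27$k, 417L)
  expect_equal(round(discrimination_capacity(s17), 4), 0.8608)
  expect_equal(round(discrimination_capacity(s27), 4), 0.9675)
  expect_equal(round(proportion_unique(s17), 4), 0.8841)
  expect_equal(round(proportion_unique(s27), 4), 0.9712)
  expect_equal(random_match_probability(s17), 605 / 431^2)
  expect_equal(round(random_match_probability(s17), 4), 0.0033)
  expect_equal(random_match_probability(s27), 463 / 431^2)
})

test_that("RMP and HD satisfy their algebraic identity on random spectra", {
  for (seed in 1:30) {
    s <- withr::with_seed(seed, random_spectrum(sample(5:200, 1)))
    if (s$n < 2) next
    expect_equal(random_match_probability(s) +
                   haplotype_diversity(s) * (s$n - 1) / s$n,
                 1, tolerance = 1e-12)
  }
})

test_that("naive pairwise-identity counting reproduces sum(p^2)", {
  sizes <- c(50, 200, 1000)
  for (i in seq_along(sizes)) {
    spec <- withr::with_seed(i, random_spectrum(sizes[i]))
    pop <- from_spectrum(spec, "yfiler", seed = i)
    expect_equal(random_match_probability(haplotype_spectrum(pop)),
                 brute_force_sum_p2(pop), tolerance = 1e-12)
  }
})

test_that("forensic_report is monotone in loci and matches recomputation", {
  pop <- from_spectrum(c("1" = 60, "2" = 10, "3" = 4), "yfiler_plus",
                       seed = 11)
  rep_ <- forensic_report(pop)
  expect_gte(rep_$yfiler_plus$k, rep_$yfiler$k)
  expect_gte(rep_$yfiler_plus$hd, rep_$yfiler$hd)
  expect_gte(rep_$yfiler_plus$dc, rep_$yfiler$dc)
  # brute-force recomputation of the 27-locus cells
  expect_equal(rep_$yfiler_plus$rmp, brute_force_sum_p2(pop))
  expect_equal(rep_$yfiler_plus$dc,
               length(unique(apply(pop$calls, 1, paste, collapse = "|"))) /
                 pop$n)
  # per-locus GD recomputed for one marker
  fr <- allele_frequencies(pop, "DYS391")
  gd_row <- rep_$yfiler_plus$per_locus_gd
  expect_equal(gd_row$gd[gd_row$marker == "DYS391"], gene_diversity(fr))
})

test_that("an identical-haplotype population has HD 0 and DC 1/n", {
  pop <- single_locus_pop(rep(14, 8), "C")
  spec <- haplotype_spectrum(pop)
  expect_equal(haplotype_diversity(spec), 0)
  expect_equal(discrimination_capacity(spec), 1 / 8)
  expect_equal(random_match_probability(spec), 1)
})
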