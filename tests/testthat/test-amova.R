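test_that("squared repeat-score distance sums over slots with sorted pairing", {
  p <- ystr_panel("yfiler")
  base <- as.list(setNames(rep("12", nrow(p)), p$marker))
  base$DYS385 <- c("13", "17")
  h1 <- canonicalize_haplotype(base, p)
  expect_equal(haplotype_sq_distance(h1, h1, p), 0)

  h2 <- base; h2$DYS19 <- "15"; base$DYS19 <- "13"
  expect_equal(haplotype_sq_distance(canonicalize_haplotype(base, p),
                                     canonicalize_haplotype(h2, p), p), 4)

  h3 <- base; h3$DYS385 <- c("14", "18")
  expect_equal(haplotype_sq_distance(canonicalize_haplotype(base, p),
                                     canonicalize_haplotype(h3, p), p), 2)
})

test_that("ascending sort minimises the multi-copy pairing (exhaustive check)", {
  for (seed in 1:50) {
    pair <- withr::with_seed(seed, list(a = sample(10:20, 2, TRUE),
                                        b = sample(10:20, 2, TRUE)))
    a <- sort(pair$a); b <- sort(pair$b)
    sorted_cost <- sum((a - b)^2)
    all_costs <- c(sum((pair$a - pair$b)^2),
                   sum((pair$a - rev(pair$b))^2))
    expect_equal(sorted_cost, min(all_costs))
  }
})

test_that("AMOVA matches hand-computed toys at the Rst = 0 and Rst = 1 limits", {
  a <- single_locus_pop(c(10, 10), "A")
  b <- single_locus_pop(c(10, 12), "B")
  res <- amova_two_level(list(a, b))
  expect_equal(res$ssd_total, 3)
  expect_equal(res$ssd_within, 2)
  expect_equal(res$ssd_among, 1)
  expect_equal(res$sigma_b, 1)
  expect_equal(res$n0, 2)
  expect_equal(res$sigma_a, 0)
  expect_equal(res$rst, 0)

  b_fixed <- single_locus_pop(c(12, 12), "B")
  res1 <- amova_two_level(list(a, b_fixed))
  expect_equal(res1$sigma_b, 0)
  expect_equal(res1$rst, 1)

  same <- amova_two_level(list(a, single_locus_pop(c(10, 10), "B")))
  expect_true(same$degenerate)
  expect_equal(same$rst, 0)

  expect_error(amova_two_level(list(a, single_locus_pop(10, "C"))), "n < 2")
  expect_error(amova_two_level(list(a)), "two populations")
})

test_that("optimized variance components equal the naive double-sum oracle", {
  cfg <- sim_config(c(P1 = 50, P2 = 80, P3 = 70), t = c(0, 60, 150),
                    mu = 0.003, seed = 42)
  pops <- simulate_populations(cfg)     # N = 200
  fast <- amova_two_level(pops)
  slow <- naive_amova(pops)
  for (f in c("ssd_total", "ssd_among", "ssd_within", "sigma_a",
              "sigma_b", "rst")) {
    expect_equal(fast[[f]], slow[[f]], tolerance = 1e-9, info = f)
  }
  expect_equal(fast$ssd_among + fast$ssd_within, fast$ssd_total,
               tolerance = 1e-9)
  expect_lte(fast$rst, 1)
})

test_that("results are invariant under within-population sample reordering", {
  cfg <- sim_config(c(A = 15, B = 15), t = 40, seed = 9)
  pops <- simulate_populations(cfg)
  shuffled <- lapply(pops, function(p) {
    ord <- rev(seq_len(p$n))
    p$sample_id <- p$sample_id[ord]
    p$calls <- p$calls[ord, , drop = FALSE]
    p
  })
  expect_equal(amova_two_level(shuffled)$rst, amova_two_level(pops)$rst,
               tolerance = 1e-12)
})

test_that("permutation p is deterministic and follows the add-one count", {
  a <- single_locus_pop(rep(10, 20), "A")
  b <- single_locus_pop(rep(14, 20), "B")
  res <- permutation_p(a, b, n_perm = 999, seed = 3)
  expect_equal(res$rst, 1)
  # recreating the fully differentiated split by chance is ~1.5e-11,
  # so no permutation ties the observed Rst and p = 1/(B+1)
  expect_equal(res$p, 1 / 1000)
  res2 <- permutation_p(a, b, n_perm = 999, seed = 3)
  expect_identical(res, res2)
  res3 <- permutation_p(a, b, n_perm = 999, seed = 4)
  expect_equal(res3$p, res$p)           # same count, different stream
})

test_that("pairwise_rst returns symmetric matrices with unit-free diagonals", {
  cfg <- sim_config(c(A = 12, B = 12, C = 12), t = c(0, 0, 400), seed = 5)
  pops <- simulate_populations(cfg)
  r <- pairwise_rst(pops, n_perm = 199, seed = 7, m = 431)
  expect_equal(diag(r$rst), c(A = 0, B = 0, C = 0))
  expect_equal(diag(r$p), c(A = 1, B = 1, C = 1))
  expect_equal(r$rst, t(r$rst))
  expect_equal(r$p, t(r$p))
  expect_true(all(r$rst >= 0))
  expect_true(all(r$p > 0 & r$p <= 1))
  expect_equal(round(r$alpha_corrected, 4), 0.0001)     # 0.05/431
  # the diverged population is farther from both source-split groups
  expect_gt(r$rst["A", "C"], r$rst["A", "B"])
  expect_gt(r$rst["B", "C"], r$rst["A", "B"])
})

test_that("bonferroni divides alpha by the comparison count", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 11), 0.05 / 11)
  expect_equal(round(bonferroni(0.05, 11), 6), 0.004545)
  expect_equal(round(bonferroni(0.05, 431), 4), 0.0001)
  expect_error(bonferroni(1.2, 5), "alpha")
  expect_error(bonferroni(0.05, 0), "positive integer")
})

test_that("mean pairwise Rst rises along a divergence-time ladder", {
  ladder <- c(0, 200, 1000, 5000)
  mean_rst <- vapply(seq_along(ladder), function(i) {
    reps <- vapply(1:4, function(r) {
      cfg <- sim_config(c(A = 30, B = 30), t = ladder[i], mu = 0.002,
                        seed = 100 * i + r)
      amova_two_level(simulate_populations(cfg))$rst
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_gt(cor(ladder, mean_rst, method = "spearman"), 0.9)
  expect_lt(mean_rst[1], 0.05)
  expect_gt(mean_rst[4], 0.5)
})
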