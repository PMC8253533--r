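nj_labels <- function(n) LETTERS[seq_len(n)]

named_matrix <- function(x, labels) {
  dimnames(x) <- list(labels, labels)
  x
}

test_that("two- and three-taxon base cases use the documented conventions", {
  D2 <- named_matrix(matrix(c(0, 0.5, 0.5, 0), 2), c("A", "B"))
  expect_equal(neighbor_joining(D2)$newick, "(A:0.25,B:0.25);")

  D3 <- named_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), nj_labels(3))
  tr <- neighbor_joining(D3)
  limbs <- setNames(tr$tree$edge.length[order(tr$tree$edge[, 2])][1:3],
                    tr$tree$tip.label[order(order(tr$tree$edge[, 2])[1:3])])
  co <- ape::cophenetic.phylo(tr$tree)[nj_labels(3), nj_labels(3)]
  expect_equal(co, D3, tolerance = 1e-12)
  # closed-form limb lengths (1, 2, 3)
  tip_edges <- match(seq_len(3), tr$tree$edge[, 2])
  expect_equal(sort(tr$tree$edge.length[tip_edges]), c(1, 2, 3))
})

test_that("a known 4-taxon additive matrix is recovered exactly", {
  # unrooted tree: limbs A=1, B=2, C=3, D=1, internal edge 1
  lab <- nj_labels(4)
  D <- named_matrix(matrix(c(0, 3, 5, 3,
                             3, 0, 6, 4,
                             5, 6, 0, 4,
                             3, 4, 4, 0), 4), lab)
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr$tree)[lab, lab], D,
               tolerance = 1e-9)
  # AB|CD split present
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr$tree), ref)), 0)
})

test_that("NJ recovers random additive trees exactly", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(4:12, 1))
    true <- withr::with_seed(seed + 500, ape::unroot(ape::rtree(n)))
    D <- ape::cophenetic.phylo(true)
    lab <- rownames(D)
    tr <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr$tree)[lab, lab], D[lab, lab],
                 tolerance = 1e-9)
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr$tree), true)),
                 0)
  }
})

test_that("NJ agrees with the reference implementation on additive input", {
  true <- withr::with_seed(77, ape::unroot(ape::rtree(8)))
  D <- ape::cophenetic.phylo(true)
  lab <- rownames(D)
  mine <- neighbor_joining(D)
  ref <- ape::nj(D)
  expect_equal(ape::cophenetic.phylo(mine$tree)[lab, lab],
               ape::cophenetic.phylo(ref)[lab, lab], tolerance = 1e-9)
})

test_that("identical input gives the identical Newick string", {
  D <- withr::with_seed(3, {
    X <- matrix(rnorm(12), 6, 2)
    named_matrix(as.matrix(dist(X)), paste0("P", 1:6))
  })
  expect_identical(neighbor_joining(D)$newick, neighbor_joining(D)$newick)
})

test_that("labels with spaces are quoted and survive a round trip", {
  lab <- c("Meizhou Kejia", "Maoming", "Guangdong Han")
  D <- named_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), lab)
  tr <- neighbor_joining(D)
  expect_match(tr$newick, "'Meizhou Kejia'", fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  back$tip.label <- gsub("^'|'$", "", back$tip.label)  # ape keeps quotes
  expect_setequal(back$tip.label, lab)
  expect_equal(ape::cophenetic.phylo(back)[lab, lab], D, tolerance = 1e-9)
})

test_that("negative branch estimates are reported and clampable", {
  # triangle-inequality violation: limb for A = (1 + 5 - 10)/2 = -2
  D <- named_matrix(matrix(c(0, 1, 5,
                             1, 0, 10,
                             5, 10, 0), 3), nj_labels(3))
  tr <- neighbor_joining(D)
  expect_gt(tr$negative_branches, 0)
  clamped <- neighbor_joining(D, clamp = TRUE)
  expect_true(all(clamped$tree$edge.length >= 0))
})

test_that("invalid matrices are rejected", {
  expect_error(neighbor_joining(matrix(0, 1, 1)), "two taxa")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad, labels = c("A", "B")), "symmetric")
  dup <- named_matrix(matrix(c(0, 1, 1, 0), 2), c("A", "A"))
  expect_error(neighbor_joining(dup), "unique")
})
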