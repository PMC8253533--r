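# Shared fixtures and independent oracles for the test suite.

# a population varying only at DYS19 (all other markers constant), handy
# for hand-checkable AMOVA arithmetic
single_locus_pop <- function(vals, name, panel = ystr_panel("yfiler")) {
  df <- data.frame(sample_id = paste0(name, seq_along(vals)),
                   stringsAsFactors = FALSE)
  for (j in seq_len(nrow(panel))) {
    df[[panel$marker[j]]] <- if (panel$copies[j] == 2) "13-17" else "12"
  }
  df$DYS19 <- as.character(vals)
  ystr_population(df, panel, name = name)
}

# independent per-individual slot scores: split cells and read tokens as
# plain numbers (decimal convention), no package scoring code involved
oracle_scores <- function(pop) {
  t(vapply(seq_len(pop$n), function(i) {
    unlist(lapply(seq_len(nrow(pop$panel)), function(j) {
      sort(as.numeric(strsplit(pop$calls[i, j], "-", fixed = TRUE)[[1]]))
    }))
  }, numeric(attr(pop$panel, "n_slots"))))
}

# naive double-sum AMOVA: the defining formulas computed with explicit
# loops over individual pairs
naive_amova <- function(pops) {
  X <- do.call(rbind, lapply(pops, oracle_scores))
  sizes <- unname(vapply(pops, function(p) p$n, integer(1)))
  N <- sum(sizes)
  k <- length(sizes)
  group <- rep(seq_len(k), sizes)
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  ssd_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ssd_total <- ssd_total + d2(i, j)
  }
  ssd_total <- ssd_total / N
  ssd_within <- 0
  for (g in seq_len(k)) {
    idx <- which(group == g)
    s <- 0
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) s <- s + d2(idx[a], idx[b])
    }
    ssd_within <- ssd_within + s / sizes[g]
  }
  ssd_among <- ssd_total - ssd_within
  sigma_b <- ssd_within / (N - k)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  sigma_a <- (ssd_among / (k - 1) - sigma_b) / n0
  list(ssd_total = ssd_total, ssd_among = ssd_among,
       ssd_within = ssd_within, sigma_a = sigma_a, sigma_b = sigma_b,
       rst = if (sigma_a + sigma_b <= 0) 0 else sigma_a / (sigma_a + sigma_b))
}

# brute-force sum of squared haplotype frequencies: count identical
# ordered pairs (including self-pairs) over raw call rows
brute_force_sum_p2 <- function(pop) {
  keys <- apply(pop$calls, 1, paste, collapse = "|")
  hits <- 0L
  for (i in seq_len(pop$n)) {
    hits <- hits + sum(keys == keys[i])
  }
  hits / pop$n^2
}

# random multiplicity spectrum with total n, biased toward singletons
random_spectrum <- function(n) {
  left <- n
  mult <- integer(0)
  while (left > 0) {
    m <- sample(1:min(4, left), 1, prob = (4:1)[1:min(4, left)])
    mult <- c(mult, m)
    left <- left - m
  }
  tab <- table(mult)
  as_spectrum(setNames(as.integer(tab), names(tab)))
}
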