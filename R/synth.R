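#' Simulation configuration for diverging Y-STR populations
#'
#' Parameters of the stepwise-mutation-model (SMM) generator in
#' [simulate_populations()].  A shared founder haplotype is drawn per
#' locus from the panel's plausible allele ranges; each population's
#' ancestor then drifts from the founder for its divergence time
#' \code{t} generations (population-level differentiation), after which
#' its \code{n} sampled lineages radiate star-like from the ancestor for
#' \code{within_generations} generations (standing within-population
#' diversity).  Per lineage, per value slot and per generation a mutation
#' occurs with probability \code{mu}, changing the repeat count by one
#' full unit up or down with equal probability (single-step SMM).
#' Expected pairwise Rst between two populations is approximately
#' \eqn{t / (t + within\_generations)}, so divergence is tuned directly
#' by \code{t}.
#'
#' @param populations named integer vector of sample sizes, e.g.
#'   \code{c(PopA = 50, PopB = 50)}; every n must be \eqn{\ge 2}.
#' @param panel panel name or [ystr_panel()] (default Yfiler Plus).
#' @param t divergence generations per population (scalar recycled or one
#'   value per population).
#' @param mu per-locus per-generation mutation probability, in
#'   \eqn{[0, 0.05]}.
#' @param within_generations star-radiation depth within each population.
#' @param microvariant_rate probability that a sampled allele carries a
#'   partial repeat (1--3 nt) injected after mutation.
#' @param seed RNG seed, recorded in the output metadata.
#' @return An object of class \code{ystr_sim_config}.
#' @export
sim_config <- function(populations, panel = "yfiler_plus", t = 0,
                       mu = 0.002, within_generations = 400L,
                       microvariant_rate = 0, seed = 1L) {
  if (is.character(panel)) panel <- ystr_panel(panel)
  stopifnot(inherits(panel, "ystr_panel"))
  if (is.null(names(populations)) || any(!nzchar(names(populations)))) {
    stop("populations must be a named vector of sample sizes")
  }
  if (any(populations < 2)) stop("every population needs n >= 2")
  if (mu < 0 || mu > 0.05) stop("mu must lie in [0, 0.05]")
  if (microvariant_rate < 0 || microvariant_rate > 1) {
    stop("microvariant_rate must lie in [0, 1]")
  }
  t <- rep_len(as.integer(round(t)), length(populations))
  if (any(t < 0)) stop("divergence generations must be >= 0")
  structure(list(populations = populations, panel = panel, t = t,
                 mu = mu, within_generations = as.integer(within_generations),
                 microvariant_rate = microvariant_rate,
                 seed = as.integer(seed)),
            class = "ystr_sim_config")
}

# net displacement of a single-step SMM walk over t generations:
# mutation count ~ Binomial(t, mu), each step +-1 with prob 1/2
.smm_net <- function(len, t, mu) {
  k <- stats::rbinom(len, t, mu)
  2L * stats::rbinom(len, k, 0.5) - k
}

#' Simulate diverging Y-STR populations under the stepwise mutation model
#'
#' See [sim_config()] for the generative model.  Fully reproducible: the
#' output is a pure function of the configuration (including its seed).
#'
#' @param cfg an [sim_config()].
#' @return list of [ystr_population()]s, one per configured population,
#'   with the configuration attached as attribute \code{config}.
#' @examples
#' cfg <- sim_config(c(A = 20, B = 20), t = 50, seed = 7)
#' pops <- simulate_populations(cfg)
#' amova_two_level(pops)$rst
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "ystr_sim_config"))
  panel <- cfg$panel
  slots <- rep(seq_len(nrow(panel)), panel$copies)
  n_slots <- length(slots)
  .with_seed(cfg$seed, {
    founder <- panel$min_allele[slots] +
      floor(stats::runif(n_slots) * (panel$max_allele[slots] -
                                     panel$min_allele[slots] + 1))
    pops <- vector("list", length(cfg$populations))
    for (g in seq_along(cfg$populations)) {
      n <- cfg$populations[[g]]
      ancestor <- founder + .smm_net(n_slots, cfg$t[g], cfg$mu)
      full <- matrix(rep(ancestor, each = n), nrow = n) +
        matrix(.smm_net(n * n_slots, cfg$within_generations, cfg$mu),
               nrow = n)
      full <- pmax(full, 2L)
      partial <- matrix(0L, n, n_slots)
      if (cfg$microvariant_rate > 0) {
        hit <- stats::runif(n * n_slots) < cfg$microvariant_rate
        partial[hit] <- sample(1:3, sum(hit), replace = TRUE)
      }
      tokens <- matrix(ifelse(partial == 0L, as.character(full),
                              paste0(full, ".", partial)), n, n_slots)
      cells <- matrix(NA_character_, n, nrow(panel),
                      dimnames = list(NULL, panel$marker))
      for (j in seq_len(nrow(panel))) {
        cols <- which(slots == j)
        if (length(cols) == 1) {
          cells[, j] <- tokens[, cols]
        } else {
          cells[, j] <- apply(tokens[, cols, drop = FALSE], 1,
                              paste, collapse = "-")
        }
      }
      df <- data.frame(sample_id = sprintf("%s_%04d",
                                           names(cfg$populations)[g],
                                           seq_len(n)),
                       cells, stringsAsFactors = FALSE,
                       check.names = FALSE)
      pops[[g]] <- ystr_population(df, panel,
                                   name = names(cfg$populations)[g])
    }
    names(pops) <- names(cfg$populations)
    attr(pops, "config") <- cfg
    pops
  })
}

#' Construct a population realising an exact haplotype spectrum
#'
#' Generates \code{k} pairwise-distinct random haplotypes on the panel
#' (alleles uniform over each marker's plausible range) and replicates
#' each to its requested multiplicity, so that [haplotype_spectrum()] on
#' the result returns the input spectrum exactly.  Useful for turning a
#' published multiplicity table into working data.
#'
#' @param spectrum an [as_spectrum()] (or named multiplicity counts).
#' @param panel panel name or [ystr_panel()].
#' @param seed RNG seed.
#' @param name population label.
#' @return an [ystr_population()] with \code{n} samples.
#' @examples
#' pop <- from_spectrum(c("1" = 5, "2" = 2), "yfiler", seed = 3)
#' haplotype_spectrum(pop)$spectrum
#' @export
from_spectrum <- function(spectrum, panel = "yfiler_plus", seed = 1L,
                          name = "synthetic") {
  spec <- as_spectrum(spectrum)
  if (is.character(panel)) panel <- ystr_panel(panel)
  .with_seed(seed, {
    cells <- .random_distinct_haplotypes(spec$k, panel)
    mult <- rep(as.integer(names(spec$spectrum)), spec$spectrum)
    mult <- sort(mult, decreasing = TRUE)     # shared haplotypes first
    rows <- rep(seq_len(spec$k), mult)
    df <- data.frame(sample_id = sprintf("S%04d", seq_len(spec$n)),
                     cells[rows, , drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    ystr_population(df, panel, name = name)
  })
}

# k pairwise-distinct random haplotype rows (character cell matrix)
.random_distinct_haplotypes <- function(k, panel) {
  draw <- function(m) {
    out <- matrix(NA_character_, m, nrow(panel),
                  dimnames = list(NULL, panel$marker))
    for (j in seq_len(nrow(panel))) {
      rng <- panel$min_allele[j]:panel$max_allele[j]
      if (panel$copies[j] == 1) {
        out[, j] <- as.character(sample(rng, m, replace = TRUE))
      } else {
        a <- sample(rng, m, replace = TRUE)
        b <- sample(rng, m, replace = TRUE)
        out[, j] <- paste(pmin(a, b), pmax(a, b), sep = "-")
      }
    }
    out
  }
  cells <- draw(k)
  for (it in 1:100) {
    keys <- apply(cells, 1, paste, collapse = "|")
    dup <- which(duplicated(keys))
    if (length(dup) == 0) return(cells)
    cells[dup, ] <- draw(length(dup))
  }
  stop("could not generate distinct haplotypes; spectrum too large for panel")
}

#' A 431-male fixture shaped like a large single-city Han panel
#'
#' A synthetic 27-locus population of 431 samples with the haplotype
#' multiplicity spectrum 405 singletons, 10 doubletons and 2 tripletons
#' (417 distinct haplotypes) and exactly nine microvariant allele
#' occurrences at six markers: DYS448 18.2 (twice) and 19.2, DYS458 18.2,
#' DYS449 34.2, DYS518 37.2, DYF387S1 37.2, and DYS627 17.2 and 18.2.
#' No null alleles or copy-number variants.  All haplotypes are random
#' draws --- the fixture reproduces summary structure, not any real
#' population's allele frequencies.
#'
#' @param seed RNG seed.
#' @return an [ystr_population()] named \code{"MaomingLike"}.
#' @export
maoming_like_fixture <- function(seed = 1L) {
  spots <- list(c("DYS448", "18.2"), c("DYS448", "18.2"),
                c("DYS448", "19.2"), c("DYS458", "18.2"),
                c("DYS449", "34.2"), c("DYS518", "37.2"),
                c("DYF387S1", "37.2"), c("DYS627", "17.2"),
                c("DYS627", "18.2"))
  target <- as_spectrum(c("1" = 405, "2" = 10, "3" = 2))
  panel <- ystr_panel("yfiler_plus")
  for (attempt in 0:9) {
    pop <- from_spectrum(target, panel, seed = seed + 1000L * attempt,
                         name = "MaomingLike")
    pop$sample_id <- sprintf("MM%04d", seq_len(pop$n))
    # samples 1..26 carry the shared haplotypes; inject into singletons
    rows <- 26L + seq_along(spots)
    for (s in seq_along(spots)) {
      mk <- spots[[s]][1]; al <- spots[[s]][2]
      cell <- pop$calls[rows[s], mk]
      toks <- strsplit(cell, "-", fixed = TRUE)[[1]]
      toks[length(toks)] <- al
      pop$calls[rows[s], mk] <- paste(toks[order(allele_score(toks))],
                                      collapse = "-")
    }
    got <- haplotype_spectrum(pop)
    if (identical(got$spectrum, target$spectrum)) return(pop)
  }
  stop("failed to build fixture with the exact spectrum")  # nocov
}
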