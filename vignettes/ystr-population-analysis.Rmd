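---
title: "Forensic Y-STR population analysis with ystrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic Y-STR population analysis with ystrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are paternally inherited
without recombination, so a panel of markers typed in one male forms a
single haplotype. Forensic laboratories characterise a population sample
of such haplotypes in two directions: *within* the population, how well
does the panel discriminate unrelated males (allele and haplotype
frequencies, gene diversity, haplotype diversity, discrimination
capacity, random match probability); and *between* populations, how
differentiated is this sample from reference populations (pairwise Rst
by AMOVA, permutation significance, ordination and tree summaries).
`ystrkit` implements this full workflow for the 17-slot Yfiler and
27-slot Yfiler Plus panels, together with a stepwise-mutation-model
simulator that generates data with known structure for calibration.

## Data model and quality control

An allele is a repeat designation: a full repeat count plus an optional
partial-repeat suffix of 1–3 nucleotides (`18.2` = 18 repeats + 2 nt, a
*microvariant*). Multi-copy markers (DYS385a/b, DYF387S1a/b) contribute
two alleles per male, reported as an unordered pair; `ystrkit` stores
the pair sorted ascending by repeat score, because electropherograms
cannot assign copies to chromosomal positions, so two samples differing
only in input order are the same haplotype.

Parsing is strict by default (any missing call, malformed token or
copy-number anomaly is an error, the right contract for statistics) and
lenient for QC runs, where anomalies are retained and routed to
`qc_screen()`: null alleles (dropouts), copy-number variants (extra
alleles at nominally single-copy loci) and a census of microvariant
occurrences per marker. Samples with any incomplete slot are excluded
from spectrum and diversity computations and remain visible in the QC
report.

DYS389II values are used exactly as reported (the database submission
convention, which includes the DYS389I stretch); no subtraction is
applied.

## Forensic statistics

All estimators use direct counting. With $p_i$ the frequency of the
$i$-th allele unit at a marker and $n$ males,

$$GD = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

and haplotype diversity (HD) is the same estimator over whole-haplotype
frequencies. Discrimination capacity is $DC = k/n$ with $k$ the number
of distinct haplotypes, and the random match probability is
$RMP = \sum_i p_i^2$ over haplotype frequencies, linked to HD by
$RMP = 1 - HD\,(n-1)/n$ — an identity the test suite checks to 1e-12.

At multi-copy markers the allele unit is the sorted pair configuration
(`"13-17"`) with denominator $n$. This treats DYS385a/b as one highly
diverse locus, the convention under which it shows several dozen
distinct units in a large Han sample; the alternative (counting single
copies with denominator $2n$) is deliberately not offered, to keep one
unambiguous unit definition throughout.

```{r}
s27 <- as_spectrum(c("1" = 405, "2" = 10, "3" = 2))  # 431 males
round(c(dc = discrimination_capacity(s27),
        hd = haplotype_diversity(s27),
        rmp = random_match_probability(s27),
        unique = proportion_unique(s27)), 4)
```

Report files render statistics at 4 decimals (rounded half-even, the
conventional reporting precision) alongside full-precision columns.

## Microvariant scoring

The molecular distance needs a numeric score per allele. The default
reads the designation as a decimal number (`18.2` scores 18.2), which
is transparent against published tables. A motif-proportional
alternative (`18.2` at a tetranucleotide locus scores 18.5) is available
via `scoring = "motif"` in the distance and AMOVA functions; it changes
distances only for microvariant carriers, which are rare (nine
occurrences in 431 × 27 calls in the data structure this package
targets), so the default favours transparency over biological
proportionality.

## AMOVA, Rst and permutation significance

The squared molecular distance between two haplotypes is the sum over
value slots of squared repeat-score differences, with multi-copy slots
paired after ascending sort (the pairing that minimises the sum for two
copies — verified exhaustively in tests). Two-level AMOVA partitions
these distances as

$$SSD_{total} = \frac{1}{N}\sum_{i<j}\delta^2_{ij},\qquad
  SSD_{within} = \sum_{pops}\frac{1}{n_p}\sum_{i<j\in p}\delta^2_{ij},$$

with $\sigma^2_b = SSD_{within}/(N-k)$,
$n_0 = (N-\sum n_p^2/N)/(k-1)$,
$\sigma^2_a = (SSD_{among}/(k-1)-\sigma^2_b)/n_0$ and
$R_{st} = \sigma^2_a/(\sigma^2_a+\sigma^2_b)$ — the classical
sums-of-squares-from-distances algebra for a Slatkin-type
microsatellite Rst. A population pair with zero total variance has no
defined Rst; it is reported as 0 with a `degenerate` flag rather than
NaN.

Significance is assessed by pooling the two samples and reassigning
individuals to the original group sizes uniformly at random; the
p-value is the add-one estimator $(b+1)/(m+1)$, with ties (permuted
statistic equal to the observed one) counted as exceeding. The default
is 10,000 permutations; every run is a pure function of its seed. The
implementation batches all permutations into two matrix products per
pair (within-group sums are quadratic forms in 0/1 indicator vectors),
which is what makes the 500-replicate size-calibration test affordable.
That calibration — one simulated source of 50 males split randomly into
25 + 25, 999 permutations, rejection at $\alpha = 0.05$ — must land in
[0.03, 0.07], the binomial band around the nominal size.

Negative Rst estimates (sampling noise around zero differentiation) are
kept in `rst_raw` and clamped to 0 in the matrix passed to ordination
and tree building, which require dissimilarities.

Bonferroni correction defaults to dividing $\alpha$ by the number of
pairwise comparisons. Some forensic population reports instead divide
by the sample size (0.05/431 ≈ 0.0001); passing `m = 431` reproduces
that convention, and the pipeline exposes it as `bonferroni_m`.

## Ordination and trees

`classical_mds()` is metric (Torgerson) principal coordinates: Gower
double-centering, eigendecomposition, coordinates scaled by square
roots of positive eigenvalues. Metric MDS was chosen over non-metric
stress minimisation because it is deterministic — no starting
configuration or convergence tolerance — and exactly recovers
Euclidean-embeddable inputs, which makes it testable against a
distance-recovery oracle. Rst matrices are generally non-Euclidean;
negative eigenvalues are dropped (standard PCoA practice) and reported
as a distortion diagnostic. Axis signs follow a fixed convention
(largest-magnitude loading positive) so coordinates are reproducible
across platforms.

`neighbor_joining()` implements Saitou–Nei NJ with a deterministic
tie-break on Q-minima (lexicographically smallest label pair). On
additive matrices it recovers topology and branch lengths exactly (the
suite checks 200 random trees of 4–12 taxa to 1e-9). The output is
unrooted; the two-taxon base case splits the distance evenly. Negative
branch estimates are reported, and `clamp = TRUE` zeroes a negative
limb while moving the deficit to its sibling so the joined pair's
separation is preserved; at the final three-limb star, negatives are
simply clamped. Newick output quotes labels containing spaces.

## The synthetic-data generators

`from_spectrum()` turns a published multiplicity spectrum (so many
singletons, doubletons, …) into a working dataset: `k` pairwise
distinct random haplotypes, each replicated to its multiplicity, so the
recomputed spectrum equals the input exactly. `maoming_like_fixture()`
uses it to build a 431-male, 27-locus panel with 417 distinct
haplotypes (405/10/2 spectrum) and exactly nine microvariant
occurrences at six loci — the QC structure of a large single-city Han
panel — by injecting the microvariants into singleton haplotypes so the
spectrum is preserved.

`simulate_populations()` is a single-step stepwise mutation model
(each mutation ±1 full repeat with equal probability; multi-step
variants were deliberately left out as the single-step model is the one
underlying Rst's assumptions). The genealogy is two-stage: a shared
founder haplotype is drawn per locus from plausible allelic-ladder
ranges (hard-coded synthetic bounds, not estimates of any real
population); each population's ancestor drifts from the founder for its
divergence time `t`; then the sampled lineages radiate independently
(star genealogy) from the ancestor for `within_generations` (default
400) generations. The population-ancestor stage is essential: with a
pure star genealogy around one founder, lineages are exchangeable
across populations and expected Rst is 0 at any `t`. Under the
two-stage model the expected Rst is approximately
$t/(t + within\_generations)$, so divergence ladders from ~0.001 to
~0.9 are directly tunable, covering the range of pairwise values
(roughly 0.0007–0.16) seen between regional Han and other Chinese
populations. With `t = 0` the two populations are i.i.d. around the
founder — the exchangeable null used for the permutation-test
calibration.

What the simulator does *not* emulate: coalescent correlation within
populations (star genealogies understate haplotype sharing), locus-
specific mutation rates, directional mutation bias, and real allele
frequency spectra. Passing tests therefore validate the estimators'
algebra and calibration under a known truth, not any claim about a real
population's values.

Default scale choices used by the test suite and kept small on purpose:
50-male sources for the 500-replicate null calibration, N = 200 for the
AMOVA oracle equivalence check, 100 random populations for the
locus-addition monotonicity property, and 200 random trees for NJ
recovery.

## Numerical and degenerate-input conventions

* Diversity statistics require $n \ge 2$; they error rather than return
  NaN.
* Monomorphic markers give GD exactly 0; a single shared haplotype
  gives HD 0 and RMP 1.
* Distance matrices must be symmetric to 1e-12 with zero diagonal;
  asymmetric input is an error, not silently symmetrised.
* MDS drops eigenvalues below `max|eig| * 1e-9` as numerically zero.
* Results are invariant under sample reordering to 1e-12 (floating-
  point summation order is not bit-stable, so bit-identity is not
  promised across *reorderings*; reruns of identical inputs are
  byte-identical).
* The permutation tie comparison uses a 1e-12 tolerance so that
  floating-point noise cannot turn a tie into a miss.

## Known limitations

* Haplotype-frequency confidence estimators (kappa, Brenner) are out of
  scope; frequencies are direct counts.
* Published reference-population comparisons depend on each study's
  marker subset and microvariant handling; this package provides the
  machinery, not curated reference data.
* The pipeline's MDS stage needs at least three populations; with two,
  the single Rst value is the complete geometry.
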