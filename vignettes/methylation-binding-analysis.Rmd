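---
title: "Calling and characterizing methyl-CpG-dependent TF binding with methBind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing methyl-CpG-dependent TF binding with methBind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methBind)
```

`methBind` implements a pipeline for discovering transcription factors
(TFs) that preferentially bind methylated CpG (mCpG) DNA, from
protein-microarray competition screens through in vivo confirmation
against ChIP-seq and methylome data, kinetic affinity measurement, and
ChIP-bisulfite validation. This vignette is the package's account of the
underlying models, the parameters that matter, the numerical choices
made where the procedure was genuinely open, and what the synthetic-data
tests do and do not demonstrate about real data.

## The microarray model

A competition assay probes one Cy5-labeled methylated motif (in the
presence of excess unlabeled, unmethylated competitor) against an array
of purified proteins, each printed in duplicate, on two replicate
arrays. Scanner output gives per-spot foreground and background medians
F and B (arbitrary fluorescence units), from which:

1. **Raw intensity** R = F/B. The ratio cancels any global scan gain, so
   Z-scores are invariant to rescaling F and B together (a tested
   invariant).
2. **Local normalization** R' = R / median(window), with a 9 × 9 window
   centered on the spot. This removes smooth spatial artifacts (washing
   gradients, print-tip effects). A handful of true binders cannot bias
   a median over 81 spots.
3. **Mirrored-shadow noise.** Binding only raises R', so intensities
   below 1 are noise. The shadow set N1 = {R' < 1} is reflected around 1
   into N2 = 2 − N1, and N = N1 ∪ N2 is the noise model: mean(N) = 1 by
   construction, and sd(N) estimates the background spread without ever
   looking at the (possibly binder-contaminated) right tail.
4. **Z-scores** Z = (R' − mean(N))/sd(N), and the **all-four-spots
   rule**: a protein is a hit only if both duplicate spots on both
   replicate arrays reach Z ≥ 3 (inclusive). Requiring four concordant
   spots is what keeps the false-positive rate near zero even with
   ~3,000 spots per array.

Key parameters: `window` (9; odd, ≥3), `cutoff` (Z = 3), `minShadow`
(10; below this the array is declared uninterpretable rather than
silently standardized against a noise estimate built from a handful of
values).

### Decisions where the procedure was open

* The window median **includes the center spot**, and windows are
  **truncated at grid borders** rather than padded; both are the
  simplest defensible readings, and both are pinned by brute-force
  window oracles in the tests.
* Values exactly 1 are excluded from the shadow set; x = 1 is a fixed
  point of the mirroring either way.
* sd(N) is the **population** SD (divide by |N|): N is a constructed
  distribution, not a sample whose mean was estimated.
* The noise mean is recomputed rather than fixed at 1; it equals 1 up to
  floating point, and reporting the computed value keeps the Z formula
  self-contained.
* Excluded (flagged) spots are masked everywhere — window medians, noise
  estimation, hit calling — and a protein with any masked spot can never
  be a hit, the conservative completion of the all-four-spots rule.
* Replicates are paired by identical (row, column) layout; mismatched
  layouts are an error, never auto-aligned.

## PDI integration and summaries

`classifyPDIs()` merges the methylated screen with a prior unmethylated
screen over the same protein and motif universes; each (protein, motif)
pair with at least one hit becomes a PDI classified METH_ONLY /
UNMETH_ONLY / BOTH. Percentages are reported rounded to integer percent,
the convention of the printed summaries. `annotationEnrichment()` is the
strictly-upper hypergeometric tail P(X ≥ k) — enrichment claims are
one-sided — with the arrayed proteins as the default universe.
`saturationCurve()` subsamples motifs to estimate how many distinct
mCpG-binding proteins would be found with fewer (or more) motifs; the
closed form E[unique] = Σ_p (1 − C(M−m_p, n)/C(M, n)) is used as the
test oracle.

## Consensus motifs from mCpG-centered k-mers

Because the methylated CpG is the conserved, binding-critical position,
bound motifs are aligned on it: each motif contributes one 6-mer per
annotated CpG with the CpG at the central two positions
(`extractCenteredKmers()`). Clustering (`clusterKmers()`) is
agglomerative average linkage on the **flank mismatch fraction** — the
central CG is constant by construction and carries no discriminative
information — stopping when the next merge would join groups with
average similarity below `minSimilarity`.

* `minSimilarity = 0.75` (≥3 of 4 flanks for k = 6) is the default
  cutoff; it is a parameter because no canonical value exists.
* With only five possible distances between 6-mers (0, ¼, ½, ¾, 1),
  ties are the rule, not the exception. The implementation is therefore
  deterministic by construction: k-mers are sorted lexicographically and
  tied merges are resolved by the smallest group representatives. A
  generic dendrogram cut cannot express this tie policy, which is why
  the clustering is implemented directly (and checked against an
  independent brute-force oracle).
* The consensus of a group is its base-frequency PWM plus an IUPAC
  string taking, per position, the smallest degenerate code covering
  every base at frequency ≥ 0.25 (the standard logo-style degeneracy
  threshold; configurable). A singleton group's consensus is the k-mer
  itself. The reported consensus is that of the largest group.
* Reverse complements are **not** collapsed for array motifs: probes are
  defined double-stranded with a stated written strand.

## In vivo k-mer enrichment

Peaks (BED, 0-based half-open; summits as name-column offsets) are
filtered to below the 95th length percentile — wide peaks dilute the
summit signal — then each summit gets a methylation level M pooled over
the CpGs within ±60 bp: M = Σn_meth / Σn_total. Pooling by coverage is
robust to low-coverage CpGs; an unweighted per-CpG mean is available via
`pooled = FALSE`. Summits with no covered CpG are excluded rather than
imputed. M ≥ 0.8 is "high" (boundary counted high), M < 0.2 "low".

The foreground is the ±60 bp window around each **highly methylated**
summit; the background is every filtered peak extended ±50 bp, which
contains the foreground (fg ⊂ bg) and controls for the local sequence
composition of bound regions; an exclusive-background mode is available
through `fgSubset = FALSE`. All 4^(k−2) central-CpG k-mers (256 for
k = 6) are counted and tested with the hypergeometric upper tail;
Bonferroni multiplies by the full a priori family of 256, not just the
observed words.

**Counting unit.** A central-CpG k-mer's reverse complement is itself a
central-CpG k-mer, so each double-stranded site has two strand readings
of the same event. `countCentralCpgKmers()` counts each site **once**
under the lexicographically smaller of the two readings. Counting strand
readings separately would double every entry of the contingency table
and inflate the hypergeometric z-score by √2 — enough to produce
spurious Bonferroni hits under a null genome. Single-strand counting
(no canonicalization) remains available via `collapseRC = FALSE`.

## Kinetics

The 1:1 Langmuir model: during association at analyte concentration C,
S(t) = S_eq (1 − e^(−k_obs t)) with k_obs = k_on C + k_off and
S_eq = S_max C/(C + K_D); after the wash, S(t) = S₀ e^(−k_off t);
K_D = k_off/k_on. The model choice is recorded explicitly — the
label-free readout follows standard surface-binding analysis but no
equations travel with the data.

Fitting is **two-stage for identifiability**: k_off first from the
dissociation phase alone (initialized by log-linear regression of the
decay), then the association phase with k_off fixed, parameterized as
(A, k_obs) with k_obs bounded below by k_off — so k_on = (k_obs −
k_off)/C is positive whenever the fit is meaningful. Initialization is
deterministic (plateau mean and 63%-rise time); no random restarts.
Residuals are weighted by 1/signal² (floored at 5% of the phase maximum)
because reflectivity noise scales with the signal; ordinary least
squares is available via `weighting = "none"`, and a joint two-phase
refinement behind `joint = TRUE`. A flat or non-rising signal returns a
structured fit failure ("no binding"), mirroring how non-binders are
reported, never a silent number. The reported affinity is the
**arithmetic mean** of the K_D estimates at two concentrations (a global
fit is the alternative reading; the per-concentration fits plus their
discordance ratio, flagged above 3×, keep both in view).

## ChIP-bisulfite comparison

Per-read call matrices (M/U/missing per read × CpG) give per-site
levels k/n with missing calls dropped from that site only. The test at
each shared site is the exact binomial upper tail
P(X ≥ chip_k | n = chip_n, p₀ = input level): "is ChIP'ed DNA more
methylated than input?" is a directional claim, so the default is
one-sided (two-sided and decrease modes exist). The null p₀ is the
input sample's observed level (plug-in). Degenerate p₀ ∈ {0, 1} yields
the forced tail (p = 0 or 1) and a flag. Consensus and non-consensus
sites are both reported so the expected contrast — consensus CpGs gain
methylation after ChIP, neighbors stay flat — is computable.

Because the binomial is discrete, P(p < α) ≤ α at any finite read
count: the test is **valid but conservative**, and at realistic
cloned-read coverage (~20 reads/site) the realized type-I rate sits
near 0.02–0.03 at α = 0.05, approaching α only as coverage grows. The
test suite asserts validity; exact uniformity of discrete p-values is
not attainable and not claimed.

## What the synthetic generators emulate — and what they do not

Each generator reproduces the statistical structure one stage assumes,
with defaults set to the study's conditions:

* `genMicroarray()`: 1,536 proteins × 2 spots on a 48 × 64 grid, two
  replicate arrays, log-normal multiplicative background (σ = 0.1,
  symmetric in log space around R' = 1 — the regime in which the
  mirrored-shadow model is estimable), 10 planted binders elevated by
  6 noise-SD on all four spots.
* `genPeaksMethylome()`: 400 peaks of 152–370 bp (the post-filter
  range) on a random genome, summit strata high/mid/low with
  probabilities 0.48/0.14/0.38 (the observed bimodal split), binomial
  methylome reads at coverage 30, and `CCCGCC` planted in high-M
  foreground windows at 5× the background rate (fold = 1 plants
  nothing, giving the matched null).
* `genSensorgram()`: 10-s sampling; phase durations of six
  characteristic times (bounded to 300–6,000 s), matching recording
  until saturation/stabilization; multiplicative Gaussian noise.
* `genBisulfite()`: Bernoulli calls at stated per-site levels, coverage
  20 — typical of cloned bisulfite PCR products.

They deliberately omit spatial artifact structure beyond smooth noise,
print-tip/batch effects, sequence composition bias (CpG islands,
repeats), bisulfite conversion failure, and mass-transport-limited
kinetics. Passing the recovery tests therefore shows the **inference
machinery** is correct and calibrated under its assumed model, not that
those assumptions hold on any particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's scale:
20 seeds of full 1,536-protein duplicate arrays, 10 + 10 seeds of
400-summit genomes (planted and null), a 3 × 3 noiseless rate grid plus
20 noisy sensorgrams, and 10,000-site null calibration — a few minutes
in total. Exhaustive oracles (brute-force window medians, average-linkage
enumeration, hypergeometric and binomial tail sums via log-binomial
coefficients) back every probabilistic claim at small n. Degenerate
inputs are handled explicitly throughout: all-missing windows stay
missing, empty shadow sets and empty peak lists raise informative
errors or warnings, an empty significant k-mer set yields "no
consensus" rather than an error, and fit failures carry diagnostics.

## Known limitations

* Array spot positions are taken from the scan table; no image-level
  spot finding or inter-array quantile normalization is attempted.
* The enrichment background includes the foreground by default; with
  very few peaks the hypergeometric sampling model is approximate
  (overlapping windows clump).
* The kinetic model is strict 1:1 binding; bivalent or
  transport-limited sensorgrams will fit poorly (visible in the
  residual RMS) rather than being detected as such.
* The bisulfite test treats reads as independent Bernoulli trials;
  clonal PCR duplicates would violate this.
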