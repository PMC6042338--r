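---
title: "Free energy of single-stranded DNA structure and Pol II pausing: models and methods"
author: "pausefold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy of single-stranded DNA structure and Pol II pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausefold)
library(GenomicRanges)
```

# The scientific question

When RNA polymerase II transcribes, the DNA duplex is transiently unwound and
the non-template (coding) strand is exposed as single-stranded DNA. That
strand can fold back on itself into hairpins and G-quadruplexes. `pausefold`
quantifies the *propensity* of genomic sequence to do so — as the minimum
Gibbs free energy ΔG (kcal/mol) of secondary-structure formation, more
negative meaning more stable — and connects that propensity to
promoter-proximal pausing of Pol II: the stereotyped stalling of engaged
polymerase within ~100 nt of the transcription start site (TSS).

The package implements the full analysis chain: windowed ΔG landscapes,
calling of highly stable structure sites, permutation enrichment against
Pol II ChIP-seq features, traveling-ratio classification of genes into
paused (PAU), non-paused (NPA) and unbound (NP2), an annotation-free
pause-site caller driven by GRO-seq/NET-seq/mNET-seq signals with a
power-law coverage null, anchored profile matrices that localize ΔG minima
relative to pause positions, and cumulative ΔΔG analysis of mutant panels.
A synthetic-data generator with a truth manifest exercises everything end
to end.

# The folding engine

## Energy model

`mfe_fold()` minimizes a nearest-neighbor free energy over all non-crossing
sets of Watson–Crick pairs (GU is never allowed in DNA):

* **Stacks.** Each adjacent pair of base pairs contributes a tabulated
  ΔG = ΔH − T·ΔS from unified DNA nearest-neighbor parameters. Monovalent
  salt corrects the stack entropies (ΔS + 0.368·ln[Na⁺] cal/(mol·K) per
  stack); divalent cations enter as an equivalent monovalent concentration,
  Na_eq = [Na⁺] + 3.795·√[Mg²⁺] (molar).
* **Loops.** Hairpin, bulge and internal loops pay tabulated penalties
  (interpolated between published anchor sizes, held fixed at their 37 °C
  values across temperatures — a documented simplification; only stack terms
  carry the temperature dependence). Loops beyond 30 nt extrapolate
  logarithmically with 1.75·R·T·ln(s/30) (Jacobson–Stockmayer).
* **Multibranch loops** use an affine cost: 3.4 kcal/mol to open plus
  0.4 kcal/mol per branch (closing pair included), unpaired multiloop bases
  free. This keeps the dynamic program O(n³).
* **Lonely pairs are disallowed by default**: every helix must stack at
  least two pairs. The recursion enumerates helices explicitly, so the
  constraint is exact, not heuristic.
* **Clamp at zero.** If no structure is negative, the unfolded state
  (ΔG = 0, all dots) is reported; ΔG is never positive.

Two deliberate defaults mirror the analysis conditions: genome-wide scans
use 1.0 M Na⁺, 0 Mg²⁺, 37 °C (`fold_params()`); sequences examined under
nuclear-extract transcription conditions use 60 mM KCl, 7 mM MgCl₂, 30 °C
(`preset_in_vitro()`).

The engine is validated against `enumerate_structures_oracle()`, which
exhaustively enumerates every admissible structure of sequences up to 18 nt
and scores each with the same energy function by an independent loop
decomposition; the dynamic-programming minimum must (and does, in the test
suite, over hundreds of random sequences) coincide exactly with the
enumeration minimum. Absolute ΔG values from this table-driven model differ
from any particular external folding program by up to a few kcal/mol; every
downstream analysis consumes rankings, thresholds, and differences, which
are robust to that offset.

## G-quadruplexes

`g4_scan()` finds the canonical motif — four runs of ≥3 guanines separated
by 1–7 nt loops, total span ≤45 nt — and assigns a simplified stability
bonus, −2.0 kcal/mol per tetrad plus +0.3 kcal/mol per loop nucleotide
(clamped at ≤0; both parameters configurable). With `allow_g4 = TRUE`,
`mfe_fold()` may include one non-overlapping motif: the motif region is
masked from pairing, the remainder refolded, and the bonus added; the result
is kept only if it lowers ΔG, so G4 inclusion never destabilizes. G-tract
positions are marked `+` in the dot-bracket string. This motif-plus-bonus
layer is intentionally coarse — G4 inclusion shifts window minima by a few
tenths of a kcal/mol without moving them, which is the only property the
analyses rely on.

# Scan geometry and coordinates

In memory every interval is a `GRanges` (1-based, closed) — the native
convention of the Bioconductor containers the package is built on; BED-family
files keep their 0-based half-open convention on disk via `rtracklayer`.
Sequence-local G4 motif coordinates are reported 0-based half-open.

* **Genome-wide scan** (`scan_genome()`): 300-nt windows, 150-nt step, plus
  strand, one ΔG per complete window; incomplete trailing windows are
  dropped, windows containing N are missing (`NA`). A chromosome of L nt
  yields ⌊(L−300)/150⌋+1 windows.
* **TSS-proximal scan** (`scan_tss_highres()`): 30-nt windows, 1-nt step,
  over the closed span TSS ± flank on the **non-template strand**, each
  window's ΔG assigned to its middle (15th) nucleotide. With the 15th-nt
  rule an exactly symmetric assigned-offset span is impossible; the package
  fixes the convention as 2·flank−28 windows at offsets −(flank−14) …
  +(flank−15) — 3972 windows at −1986…+1985 for flank 2000 — verified by
  hand count on a toy flank in the tests.
* **Stable sites** (`call_stable_sites()`): runs of ≥7 consecutive windows
  with ΔG at or below the genome-wide lowest-5% threshold
  (`genome_quantile_threshold()`, lower empirical type-1 quantile, ties on
  the stable side). A site spans first window start to last window end:
  minimum 1200 nt at 300/150 geometry, (k−1)·150+300 nt for k windows.
  Missing windows break runs — assembly gaps never bridge a site.
* **Annotation** (`annotate_sites()`): precedence TSS (±250 nt) > TTS
  (±250 nt) > promoter (−1000…−251 nt, transcription-oriented) > gene body >
  intergenic, applied both to site classification and to the territory
  partition used for per-Mb densities, so the five territories tile the
  genome and densities are mutually comparable.

# Permutation enrichment

`shuffle_intervals()` redraws an interval set with the same multiset of
lengths uniformly over all admissible genome-wide placements (chromosomes
weighted by the number of admissible starts), optionally rejecting overlaps
with an exclusion set (e.g. assembly gaps). `peak_overlap_enrichment()`
reports observed / mean-null overlapping-site counts over 10,000 shuffles
(1,000 for the read-coverage variant, `coverage_enrichment()`); the
empirical p-value uses the add-one estimator (1 + #{null ≥ obs}) /
(1 + n_shuffles) and can never be zero. Shuffling is genome-wide rather than
chromosome-preserving, matching the procedure the analysis describes; the
two differ only when interval density varies strongly between chromosomes.

# Traveling ratio and pausing states

Genes (one transcript per gene: the longest, ties by leftmost start then
transcript id; transcripts <660 nt and genes with N within TSS ± 2 knt
removed by `select_transcripts()`) are first stratified by Pol II peak
overlap: unbound genes are NP2. For bound genes the traveling ratio is

TR = density(TSS −30…+300 nt) / density(rest of the gene),

with densities as per-base coverage sums divided by region length. The TSS
window is anchored on the TSS — it extends upstream of the transcript rather
than being clipped. TR > 2 defines PAU; TR ≤ 2 NPA. Decisions the source
procedure leaves open, fixed here: zero body density with TSS signal gives
TR = +∞, which sorts above all finite TRs and is paused; a bound gene with
no coverage at all is NPA (binding is its only evidence).
`concordance()` compares samples by Spearman correlation of TR over
jointly-bound genes and counts PAU↔NPA switches.

# Annotation-free pause sites

1. **Candidates**: GRO-seq peaks whose best single overlap with a Pol II
   ChIP peak exceeds 50% of the GRO peak length (strictly greater;
   `overlap_filter()`). Candidates inherit the GRO peak strand.
2. **Noise null**: the histogram of per-base mNET-seq coverage is modeled
   as N_x = a·x^(−b), fitted by least squares on log N vs log x over
   coverage 3–100 (`fit_powerlaw_null()`). The histogram is fitted as given;
   for p-values the law is renormalized over the discrete support x ≥ 3 and
   extended analytically beyond 100, and the upper-tail **sum** is the
   default p-value (a continuous integral differs negligibly at these
   exponents). Coverage below the fit range gets p = 1.
3. **FDR**: Benjamini–Hochberg at 5% on the per-locus p-values of the
   maximum single-base mNET coverage (`mnet_fdr_filter()`).
4. **Ranking**: per-assay signal = total coverage in the locus (Pol II
   ChIP, GRO, NET, mNET); descending ranks with average ties; loci ordered
   by the rank sum, ties by mNET rank then position (`rank_loci()`). Ranks
   are computed on the post-filter set.
5. **Spikes**: the pause coordinate is the position of maximal single-base
   mNET coverage on the locus strand, ties to the 5′-most position in
   transcription orientation; the second spike (next-highest position ≥1 nt
   away) and their signed distance probe backtracking
   (`strongest_spike()`).
6. **Genic class**: a locus is intragenic when its midpoint falls inside a
   transcript; TSS/TTS distances are signed in the nearest gene's
   orientation (`classify_genic()`).

# Profiles

`anchored_matrix()` (coverage) and `anchored_dg_matrix()` (ΔG or GC with the
identical 30-nt/15th-nt geometry, so the two are comparable) build
loci × offset matrices around anchors, orientation-flipping minus-strand
rows so negative offsets are always upstream; edges pad with `NA`, and
`average_profile()` takes missing-aware column means with per-offset counts
(missing values are excluded, never zero-filled). `locate_min()` reports the
contiguous offset interval within ε (default 0.25 kcal/mol — our documented
choice; the width of the reported interval depends on it, the argmin does
not) of the profile minimum. `extreme_density()` tracks where globally
extreme (lowest/highest 2%) windows concentrate, and `strand_bias()`
contrasts non-template against template ΔG over TSS −30…+300 with a paired
t-test.

# Mutant ΔΔG analysis

"All secondary structures affected by a mutation" is operationalized as
every complete 30-nt sliding window containing a mutated position
(`affected_windows()`; an interior point touches 30 windows, clipped at
edges). `cumulative_ddg()` sums ΔG(mutant) − ΔG(reference) over that union
under the in vitro preset; negative totals mean the mutant folds more
stably, and the statistic is additive for mutations >29 nt apart.
`robust_fit()` regresses measured paused fractions on cumulative ΔΔG by
Huber IRLS with MAD scale (via `MASS::rlm`; tuning constant 1.345). This is
a deliberate simplification of full MM-estimation with an S-initialization:
only the slope's sign and rough magnitude are consumed downstream, and
points with final weight <0.5 are flagged as outliers. On exactly collinear
input the robust scale degenerates, so the fit short-circuits to OLS with
unit weights — the IRLS fixed point.

# The synthetic-data generator

`simulate_dataset()` draws the study conditions used throughout the tests:

* 1-Mb single chromosome, i.i.d. bases at 50% GC; 100 non-overlapping genes
  of 2–4 kb on random strands, placed in slots with guard gaps so TSS ± 2 knt
  regions never overlap; 60% PAU, 15% NP2, the rest NPA.
* Each PAU gene pauses at TSS+75 on its coding strand; a hairpin with a
  12-bp GC-only stem and 6-nt T loop (ΔG ≈ −20 kcal/mol, far below the
  background 1st percentile of ≈ −3) is written on the non-template strand
  centered 30 nt upstream of the pause; 20% of PAU genes also get a
  canonical G4 motif further upstream. Minus-strand genes receive the
  reverse complement on the reference.
* Tracks: Gaussian Pol II ChIP coverage (height 30, sd 60 nt) over each
  pause on a unit gene-body baseline, with ±150 nt peak calls; NPA genes get
  uniform body coverage (height 5) and a body-wide peak — bound but not
  paused by construction (TR ≈ 1 versus ≫ 2 for the Gaussian geometry);
  NP2 genes get nothing. GRO/NET cover the TSS→pause region on the coding
  strand; GRO peaks are emitted for PAU genes only (promoter-proximal GRO
  peaks are the pausing hallmark being modeled). mNET carries a 200-read
  single-base spike at the pause plus an 80-read second spike 3 nt
  downstream.
* mNET noise: 2% of positions per strand draw an integer from the discrete
  law ∝ x^(−2.443) on 3…100 — so the in-range histogram reproduces
  N_x = 0.965·x^(−2.443) — with the sub-range mass (coverage 1–2) completed
  by the same x^(−b) shape. The spike height (200) exceeds the noise ceiling
  (100) by construction, so planted argmaxes are unambiguous.

What the generator does **not** emulate: mappability and GC bias, read-level
noise in ChIP/GRO/NET tracks, overlapping or nested genes, expression-level
variation, and any coupling between sequence and coverage beyond the planted
structures. Green tests therefore demonstrate that the machinery is correct
and calibrated on data satisfying its assumptions — not that real nascent
transcription data meet those assumptions.

# Problem sizes and numerical choices

The test suite runs on a 200-kb/20-gene simulation for module tests and the
1-Mb/100-gene default for the end-to-end recovery check; anchored ΔG
matrices use ±100–200 nt flanks (a few tens of thousands of 30-mer folds).
These sizes were chosen to exercise every code path at full fidelity while
keeping the suite fast; whole-genome scans (~20 M windows for a human
genome) are an overnight batch run of the same functions, not a test path.
Printed genome-scale figures from real human data (window means, 5%
thresholds, site counts, per-cell-line paused fractions, 15–100× enrichment
ranges) require the original genome builds, ENCODE/GEO tracks, and the
external folding programs, and are reproducible only as that kind of
integration run.

Other fixed numerical choices: energy comparisons in the traceback use an
absolute tolerance of 1e-7 kcal/mol; the interior-loop search is capped at
30 unpaired nt total (standard practice; the enumeration oracle never
reaches the cap at its ≤18-nt sizes, so oracle-equivalence is exact);
quantile conventions are empirical type-1 throughout; and all random
procedures (shuffles, simulations) expose explicit seeds.
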