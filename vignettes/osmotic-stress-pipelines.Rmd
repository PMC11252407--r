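---
title: "Methods: quantitative pipelines for osmotic-stress screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative pipelines for osmotic-stress screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoscreen)
```

osmoscreen implements the quantitative backbone of a multi-omics study of
osmotic stress in *Chlamydomonas reinhardtii*: gene-level hit calling for a
pooled barcoded insertional-mutant fitness screen, Z-score scoring of
secondary 96-well plate screens, reciprocal ¹⁴N/¹⁵N label-swap
phosphopeptide filtering, reciprocal-best-BLAST-hit (RBH) orthology with
overlap and enrichment statistics, and the microscopy quantification
operators used for actin organisation, calcium spiking and plasmolysis.
This vignette is the package's account of each method, its assumptions,
the tunable parameters, and the design choices made where the procedure
left room.

## Pooled screen hit calling

### Model

Each insertional mutant carries a unique barcode; a pool of mutants is
grown competitively under a treatment (NaCl, mannitol, PEG, hypoosmotic
shock) and under a control condition, and barcodes are counted by
sequencing. The per-allele phenotype ratio is

$$\Phi = \frac{\text{relative abundance under treatment}}
             {\text{relative abundance under control}},$$

where relative abundance is the barcode's share of its library
(`normalize_abundance()`; depth differences between libraries make raw
counts incomparable). $\Phi < 1$ indicates a growth defect under stress.
A phenotype is only calculated when the allele has at least `min_reads =
50` reads; the minimum is applied to the **control** sample by default,
because a sparse control denominator makes $\Phi$ unstable while
treatment dropout — zero treatment reads, $\Phi = 0$ — is precisely the
signal and must remain observable. `min_reads_on` switches to
sum-of-pair or both-samples rules for sensitivity analysis.

Qualified alleles are counted into eight fixed half-open bins
(`phi_bin_edges()`): $\Phi < 0.0625$, $[0.0625, 0.125)$, $[0.125,
0.25)$, $[0.25, 0.5)$, $[0.5, 2)$, $[2, 4)$, $[4, 8)$, $[8, 16)$. The
printed bin list ends at 16, leaving $\Phi \ge 16$ formally unassigned;
such alleles are clipped into the top bin rather than dropped, so the
binning is a total monotone step function on $[0, \infty)$.

### The gene-level test

A gene with $n$ qualified alleles yields an 8-bin count vector, compared
with the bin vector of *all* qualified insertions in the screen. The
test (`fisher_gene_p()`) conditions on both margins of the 2×8 table
(gene row versus background-minus-gene row): under the null that the
gene's alleles are an exchangeable draw from the screen, the gene row
follows a multivariate hypergeometric distribution, and the two-sided
p-value is the total probability of all gene-row outcomes no more
probable than the observed one — the standard exact-test convention for
r×c tables. Outcomes tied with the observed probability are included,
with a $10^{-12}$ relative tolerance so that floating-point noise cannot
split exact ties.

Two numerical paths:

* **Exact enumeration** for $n \le$ `exact_cap` (default 12): all
  compositions of $n$ into 8 bins (at most $\binom{19}{7} = 50{,}388$)
  are enumerated and their log-probabilities computed from `lchoose`.
* **Monte Carlo** above the cap: at least $10^5$ seeded draws of the
  gene row by sequential conditional hypergeometric sampling; the
  result is flagged with its standard error.

Whether the focal gene's alleles are included in or excluded from the
background table turns out not to matter for the test itself: either
way the comparison row is background-minus-gene and the margins are the
full screen, so the conditional distribution is identical. The flag on
`gene_contingency()` only changes the reported background vector.

Genes with more than two alleles enter a Benjamini–Hochberg correction
(`bh_fdr()`, the step-up $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$,
delegated to `stats::p.adjust`); a gene is a hit when $q < 0.3$
(strictly). The permissive 0.3 level reflects the screening context:
hits are candidates for secondary confirmation, not final claims.
BH is applied separately within each (condition, replicate) screen, so
per-replicate hit patterns can be compared; run `run_screen_pipeline()`
over a design table of control/treatment pairs to get one hit table per
screen.

### What the screen simulator emulates

`simulate_screen()` models competitive growth in discrete doublings with
per-allele relative fitness $1 - s$: after $g$ doublings the expected
phenotype ratio of an allele with selection coefficient $s$ is exactly
$2^{-g s}$. There is no death term and no interaction between alleles —
the simplest model consistent with comparing abundances after growth.
Reads are multinomial at fixed depth (a Dirichlet-multinomial
overdispersion knob exists, default off, since PCR jackpot noise is
real but unquantified here); initial pool abundances are log-normal
(sdlog 0.5) to mimic the uneven representation of real libraries.

One subtlety is deliberate: with fixed sequencing depth, relative
abundances are compositional, so depleting the hit alleles would
slightly inflate every other allele's share and bias all $\Phi$ upward.
Real pools contain unmapped/unbarcoded material; the simulator includes
such a component (`unmapped_frac`, default 0.1) as an extra count row
absent from the annotation, and lets it take up the share vacated by
depleted mutants. Mapped alleles therefore have expected $\Phi$ exactly
$2^{-gs}$ (neutral alleles exactly 1), which the deterministic
(`sampling = FALSE`) path reproduces to machine precision — the
property the test suite checks against the closed form.

The generator does **not** emulate barcode sequencing errors, read-level
FASTQ structure, allele-frequency-dependent selection, or batch effects
between replicate cultures. Passing recovery tests on these simulations
therefore demonstrates the statistical machinery (binning, exact test,
FDR) under the stated growth model, not robustness to library-prep
artifacts.

The default study-scale simulation — 1,000 genes × 5 alleles, 20 planted
hit genes with $s = 0.5$ over $g = 4$ doublings (expected $\Phi =
0.25$), $10^7$ reads per sample — is the problem size used by the test
suite and the acceptance script; the number of doublings in a real
screen is a free parameter, not something the procedure fixes.

## Secondary plate screens

Plate scans are 8-bit RGB; `quantify_wells()` converts to grayscale with
Rec. 601 luminance weights (0.299, 0.587, 0.114 — the default of common
imaging software; configurable) and averages pixel intensity over the
full circular sampling area of each well. Wells flagged for bubbles or
irregular clamping are excluded before quantification. Growth is scored
per plate as

$$Z = \frac{\bar{x}_\text{genotype} - \bar{x}_\text{wt}}{s_\text{wt}},$$

with the sample standard deviation ($n-1$) of the wild-type wells on the
*same* plate — wild-type colonies are placed on every plate precisely to
absorb positional and plate effects, so no cross-plate pooling is done.
The two replicate wells of a mutant are averaged before scoring
(`per_well = TRUE` scores them separately). Z is invariant to any
affine gain/offset applied to a whole plate, since numerator and
denominator scale together. Whether the denominator should be the
wild-type sd or the all-well sd is not dictated by the procedure;
wild-type sd is used because the all-well sd would be inflated by the
very mutant effects being measured. A plate whose wild-type wells are
identical (sd 0) gets an explicit `sd_zero` flag: Z is 0 where the mean
difference is exactly zero and NaN otherwise.

## Reciprocal label-swap phosphoproteomics filtering

Each replicate is a pair of cultures with opposite metabolic labels:
in a *forward* pair the treated sample grows in light (¹⁴N) medium, so
the raw light/heavy peak-area ratio is treated/control; in a *reverse*
pair the labels are swapped and the raw ratio is control/treated.
`orient_ratio()` maps every measurement to the treated/control scale
(forward: unchanged; reverse: reciprocal). True phosphorylation changes
flip the raw ratio direction between orientations, label artifacts do
not — which is the point of the swap design.

`call_differential()` implements the selection rule: a peptide is called
when at least 2 of the 3 replicates show an oriented change of 2-fold or
greater *in the same direction* ($|\log_2 r| \ge \log_2 2$ with
consistent sign; passing replicates of opposite sign cancel the call).
The relaxed 1.5-fold variant (`call_differential_relaxed()`) is used for
cross-species comparison of phosphorylated proteins, and is provably a
superset of the strict calls. Three interpretation choices were open:

* "Reciprocal" is implemented as correct orientation handling before
  thresholding; an optional `strict_reciprocal` mode additionally
  requires a passing replicate from each label orientation.
* Peptides observed in fewer replicates than `min_reps` cannot be
  called, but a peptide seen in only 2 of 3 replicates can still pass —
  missingness is pervasive in MS data and the rule counts passing
  replicates.
* Protein roll-up (`summarize_directions()`): a protein is called when
  any peptide is called, with majority direction and exact ties flagged
  ambiguous; the counting structure mirrors reported
  up/down-phosphorylated protein tallies.

Upstream spectrum identification, peptide-level FDR filtering, and peak
area extraction are the province of the search and quantification tools
that produce the ratio table, and are out of scope here.

## Orthology and cross-list statistics

`parse_blast_tab()` reads standard 12-column tabular BLAST output.
`best_hits()` keeps, per query, the subject with the lowest e-value
among hits with e-value ≤ 1e-10; the e-value criterion is the
procedure's, while the tie-break (higher bitscore, then lexicographic
subject id) is the package's own, chosen to make the result exactly
invariant to input row order. `rbh()` retains pairs that are best hits
in both directions — a partial bijection, mirrored under direction
exchange. Isoform handling is not dictated; ids are used verbatim, with
an optional regex collapsing step (`collapse_pattern`) to reduce
isoforms to genes before best-hit selection.

`overlap_stats()` intersects a query set with a reference set (after
ortholog translation when the sets live in different species) and
reports the overlap as a percentage of the explicitly stated reference
set, rounded to two decimals for display — e.g. 5 shared genes against a
1,456-gene differentially-expressed reference is 0.34%.
`fisher_enrichment()` tests a 2×2 list-by-category table over a declared
universe with the two-sided Fisher exact test (`stats::fisher.test`)
and reports the sample odds ratio $ad/bc$; the test suite checks its
agreement with the package's own conditional test on the collapsed
two-bin table.

## Image quantification

### Actin skewness

`intensity_skewness()` computes $g_1 = m_3 / m_2^{3/2}$ with population
(biased) central moments over all pixels of a cell crop — no background
subtraction and no thresholding, because maximum-intensity projections
are analysed unprocessed; a sample-adjusted (G1) variant is available
behind a flag. Crops are kept at a constant physical size (10 × 10 µm)
across a comparison set so that histogram shape, not crop extent,
drives the statistic. Bundling concentrates a fixed amount of
fluorescence into fewer, brighter cables, right-skewing the histogram;
on the synthetic bundling series the statistic rises strictly
monotonically, which is the package's recovery check. Whether skewness
should be computed on all pixels or only on suprathreshold filament
pixels is a genuine fork; all pixels are used, consistent with
analysing unprocessed projections.

### Filament angle

`dominant_angle()` estimates the dominant orientation from the summed
gradient structure tensor (central differences, intensity-gradient
weighting); the filament axis is perpendicular to the dominant gradient
direction. Angles are reported in image coordinates (positive from +x
toward +y, the renderer's convention), folded to $[0, 90]$ degrees
relative to a declared reference axis — longitudinal (the cell long
axis, horizontal after alignment) or radial (transverse) — since both
conventions appear in practice. Crops whose tensor coherence
$(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$ falls below 0.1 are
flagged low-confidence rather than assigned a meaningless angle. On
synthetic scenes the estimator carries a small systematic bias (≈1.5°
at oblique orientations, from finite-difference anisotropy on the pixel
grid), within the ±2° envelope the tests enforce.

### Calcium spikes

`detect_spikes()` applies a maximum-entropy threshold
(`kapur_threshold()`: the threshold maximising the summed Shannon
entropies of the normalized sub-histograms below and above the cut,
lowest value on ties, exhaustively over the 8-bit range) computed once
from the whole stack, then scans 8 ROIs of 24 × 24 µm placed across a
150 µm span (`roi_grid()`). Per frame and ROI, suprathreshold connected
components smaller than 6 pixels are discarded as sporadic signals;
qualifying components overlapping spatially in consecutive frames merge
into one spike event with a duration, and counts convert to
spikes·hour⁻¹ as events divided by imaged hours.

One guard is the package's own: the maximum-entropy criterion, applied
to a stack containing *no* signal, happily splits the unimodal noise
histogram near its middle, flooding the mask and producing large
spurious components. `detect_spikes()` therefore requires the
foreground class to be distinguishable from background — at least 4
background standard deviations and 8 gray levels above it — before any
event is accepted; a pure-noise stack yields zero events everywhere.
The guard thresholds are deliberately far below any real indicator
signal (planted spikes in the simulator sit ≈130 gray levels above
background) and far above what noise alone can produce.

The movie simulator plants compact blobs of exactly the scheduled pixel
area and duration over Gaussian noise, and returns the schedule as
ground truth, replacing manual spike confirmation for testing purposes.
It does not emulate photobleaching, drift (input stacks are assumed
registered), or indicator kinetics.

### Plasmolysis

`shrinkage_percent()` is the arithmetic $100 (1 - A_\text{protoplast} /
A_\text{total})$ on areas supplied from masks or manual tracing;
segmentation itself is out of scope, matching how the areas are
produced in practice (membrane-marker signal for the protoplast,
bright-field for the cell wall).

## Numerical and testing notes

* All generators take a single integer seed per call and restore the
  caller's RNG state; identical seeds give bit-identical outputs.
* The exact test's tie handling uses a $10^{-12}$ relative tolerance on
  outcome probabilities; the enumeration path is checked against a
  brute-force labelled-assignment oracle to $10^{-12}$, and the
  Monte-Carlo path against the exact path within 3 standard errors.
* Super-uniformity of the gene test ($\Pr(p \le \alpha) \le \alpha$
  conditionally) is verified exhaustively for $n \le 4$ alleles over
  backgrounds with up to 3 occupied bins at $\alpha \in \{0.01, 0.05,
  0.3\}$.
* Problem sizes in the test suite (a 5,000-barcode screen at $10^7$
  reads, 20 neutral screens for the false-discovery check, 1,000 random
  histograms for the threshold oracle) were chosen as the smallest
  scales at which the corresponding properties are non-trivial.

## Known limitations

* The screen model treats alleles independently; genuine competition
  effects (frequency-dependent selection, shared-niche saturation) are
  not represented, and the unmapped-sink closure device, while exact,
  is a modelling idealisation.
* `fisher_gene_p()`'s Monte-Carlo path gives a simulation-consistent,
  not exact, p-value; it is flagged so downstream consumers can treat
  it accordingly.
* The phospho filter is a thresholding rule, not an error-rate-
  controlling test; it inherits the replicate structure it is given and
  makes no claim about peptide-level FDR.
* The angle estimator assumes an approximately unidirectional filament
  population per crop; crossed arrays yield a coherence-weighted
  compromise angle and a low coherence value rather than two angles.
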