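---
title: "Cumulative contact frequency: model, methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative contact frequency: model, methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiccf)
```

## The quantity under study

Iterative correction and related Hi-C balancing methods force every genomic
bin to the same total number of contacts. The quantity they remove — the
**cumulative contact frequency** (CCF), the per-bin sum of raw contact
frequencies — mixes technical visibility (mappability, GC, accessibility to
the restriction enzyme) with biology: open, transcriptionally active
chromatin genuinely participates in more ligation events. `hiccf` treats CCF
as a first-class signal and provides the tools needed to characterize it:
compute it under the standard filters, call the genome's A/B compartments
and TADs for context, quantify chromatin-state content per bin, and test the
CCF–activity association against the obvious confounders.

For a bin $i$, with $C$ the raw (non-normalized) contact matrix,

$$\mathrm{CCF}_i \;=\; \sum_{j \in \mathcal{J}(i)} C_{ij},$$

where $\mathcal{J}(i)$ excludes $j=i$ (the main diagonal carries artifacts
of single-sided and mirror reads) and, in the `total` scope, every
intra-chromosomal pair separated by up to `min_separation` (default 5 Mb,
*inclusive*: at 1 Mb bins, $|i-j|\le 5$ is removed — the dense near-diagonal
would otherwise dominate the sum). The `inter_chromosomal` scope keeps only
pairs on different chromosomes, which makes the statistic independent of
intra-chromosomal structure entirely. CCF is reported both raw and as a
percentage of the map's genome-wide maximum over unmasked bins, which makes
profiles comparable across maps of different sequencing depth. Bins whose
matrix row is entirely empty are masked, kept in the grid for index
stability, and excluded from every computation.

## Compartments and TADs

**Compartments.** The matrix is normalized by the expected contact frequency
at each genomic separation (pooled across chromosomes; inter-chromosomal
entries are divided by the single genome-wide inter mean). The Pearson
correlation matrix of the O/E rows carries the familiar checkerboard, and
the first principal component of that matrix is the compartment coordinate.
Our PCA convention: missing entries of the correlation matrix (zero-variance
rows) are mean-imputed and re-masked on output; the matrix is column-centered
and decomposed with `stats::prcomp`; scores of PC1 are reported along with
the proportion of variance explained, $\mathrm{PVE} =
\sigma_1^2/\sum_k\sigma_k^2$. The PC sign is not identified, so it is
oriented by positive correlation with a user-chosen reference track —
GC content by default, active-state fraction works equally — and the
reference used is recorded in the output. Bins with oriented PC1 $> 0$ are
labeled A, $< 0$ B. A genome-wide PCA is the default (matching the use of
the whole-genome matrix); a per-chromosome mode is exposed because that is
the conventional workflow elsewhere. PVE doubles as a sanity check: a map
with real compartments shows PVE far above a distance-decay-only map, and
the package's tests assert exactly this directional property on simulated
maps.

**TADs.** Each chromosome is tiled into segments maximizing total clamped
modularity. A segment $[a,b]$ scores

$$Q(a,b) = \sum_{a \le i < j \le b}\Big(A_{ij} -
\gamma\,\frac{k_i k_j}{2m}\Big),$$

with $A$ the intra-chromosomal matrix (diagonal removed), $k_i$ its row
sums, $2m = \sum_i k_i$, and $\gamma = 1$ by default. The optimal tiling is
found by dynamic programming, `best[e] = max_s best[s-1] + max(Q(s,e), 0)`;
clamping at zero lets low-scoring stretches remain background. Ties are
broken toward the later split point, which deterministically decomposes
non-positive stretches into single-bin segments. Labels follow two rules:
a segment is a TAD only if it spans at least 3 bins (shorter segments are
interTAD by definition) *and* has positive score; everything else is
interTAD. Masked bins split a chromosome into independently segmented runs.
The dynamic program is verified against exhaustive enumeration of all
$2^{n-1}$ tilings for every test instance with $n \le 12$.

## Chromatin states and correlation analyses

State segmentations (non-overlapping labeled intervals, e.g. a 15-state
human, 7-state mouse or 9-color fly catalog) are converted to per-bin
coverage fractions; an interval spanning a bin boundary contributes to both
bins proportionally to the overlap, so each state's annotated bp total is
conserved exactly. Bins without any annotation are flagged and excluded from
correlation analyses. Built-in groupings collect states into *active* and
*inactive* classes; states in neither class (insulator, Polycomb) map to
*other* and are still reported individually.

Correlations are Pearson coefficients with pairwise deletion of missing
bins; every report records the per-cell bin count, and the genome,
per-chromosome, TAD and interTAD scopes restrict the bin set before
computing. Two resampling controls accompany the plain coefficients:

* **Windowed correlation.** The genome is tiled into fixed windows (10 Mb
  default), a coefficient is computed per window, and the mean observed
  coefficient is compared to a null built by cyclic shifts of one track
  along the concatenated genome (offsets uniform on $1..n-1$). Cyclic
  shifting preserves each track's autocorrelation, which a value permutation
  would destroy; shifts crossing chromosome boundaries slightly blur the
  null's autocorrelation structure, a deliberate simplification. The
  empirical p-value $(1 + \#\{|\bar r_{\mathrm{null}}| \ge
  |\bar r_{\mathrm{obs}}|\})/(1 + n_{\mathrm{perm}})$ is conservative and
  bounded below by $1/(1+n_{\mathrm{perm}})$.

* **Downsampling control.** To ask whether a small-chromosome coefficient is
  an artifact of its smaller bin count, `downsample_control()` subsamples
  `target_n` bins without replacement from a caller-chosen source set and
  re-computes the coefficient per replicate; `control_quantile()` locates an
  observed value in that distribution. For the calibration question "is the
  small-chromosome set unusual *for its size*?", the statistically correct
  source set is the whole genome: under homogeneity the small set is then
  exchangeable with the replicates and the observed value falls inside the
  central 95% about 95% of the time. Subsampling a disjoint set (only the
  large chromosomes) remains available and mirrors the classical usage, but
  is intrinsically slightly undercovered, because the replicate distribution
  is then centered on the disjoint set's own realized coefficient and
  narrowed by the finite-population correction.

Confounder controls for the CCF–activity association come in three forms:
division by chromosome length, division by GC content, and OLS regression of
CCF on GC (residuals are exactly mean-zero and GC-orthogonal); the combined
control applies length normalization then GC regression. Division by a
confounder is a crude control (it changes the variance structure), while the
regression is the sharper instrument; both are provided because both are in
common use. Note that dividing per-bin CCF by chromosome length injects a
several-fold between-chromosome factor on any genome whose chromosome
lengths span a similar range, which dilutes genome-wide coefficients even
when the within-chromosome pattern is intact — the sign pattern, not the
magnitude, is the meaningful survivor of that control.

## Synteny projection

A synteny map is an ordered table of block pairs (A-side and B-side
coordinates plus strand, minimum block size 2 Mb). Tracks are projected by
distributing each A-bin's value over the B-side bins its mapped fragments
land in, proportionally to fragment lengths — ambiguously mapped bins are
split proportionally — so projected mass is conserved. For CCF comparison,
each block is cut into 1-Mb homology units on the A grid; a unit pairs its
A-side CCF percent with the overlap-weighted mean CCF percent at its B-side
location (percent CCF is used because it is depth-free and therefore
comparable between species). Units are classed by the chromosome size class
(large = chromosomes 1–9, small = 14–22 under the numeric rule, or an
explicit mapping) on each side, giving the four large/small class pairs,
including the translocated ones.

## The synthetic study design

`sim_spec()` defines the simulated genome all validation runs on: six
chromosomes of 200/180/150/60/50/40 Mb (three large, three small) at 1 Mb
bins, roughly 680 bins. Structure planted in the maps, and what each piece
lets the pipeline demonstrate:

* **Distance decay** $s^{-\alpha}$, $\alpha = 1$ — the expected-matrix
  module must recover the exponent from a decay-only map.
* **Compartments**: alternating A/B blocks (geometric lengths, mean 10 Mb);
  activity per bin is Beta(8,2) in A and Beta(2,8) in B; same-compartment
  contacts are multiplied by 2.0. PCA must recover the labels (>90%) and
  show a PVE far above the decay-only map.
* **Visibility bias** $b_i = \exp(0.8\,\mathrm{activity}_i +
  0.2\,\varepsilon_i)$, normalized to mean 1 — this is what makes CCF
  biologically informative in the simulation: contacts scale with
  $b_i b_j$, so CCF couples to activity.
* **GC confound**: $\mathrm{gc}_i = 0.38 + 0.1\,\mathrm{activity}_i +
  \mathcal{N}(0, 0.04)$. The noise level makes GC a *partial* proxy of
  activity (correlation ≈ 0.6, a realistic magnitude for 1-Mb GC versus
  active-chromatin coverage). This matters: were GC a near-perfect proxy,
  regressing it out would necessarily erase the activity signal and no
  pipeline could demonstrate survival of the association.
* **Inter-chromosomal preference**: a ×1.5 boost on small–small chromosome
  pairs. Per-bin inter CCF is higher on small chromosomes partly for a
  composition reason too (a small-chromosome bin simply has more
  inter-chromosomal partner bins), so the boost is validated with a per-pair
  statistic — mean count over small–small versus large–large pairs, with the
  known bias and compartment modifiers divided out — which is 1.5 with the
  boost and 1.0 without it.
* **Chromatin states**: each bin is split into an active-state run and an
  inactive-state run at its activity fraction (human 15-state names), so
  binned active-group coverage reproduces activity to rounding. Because only
  the two groups are planted, active and inactive coverage sum to 1 and
  their CCF correlations are exact mirror images — real segmentations have
  "other" states and weaker symmetry.
* **Synteny pairs**: genome A's chromosomes are partitioned into blocks
  (≥ 2 Mb, geometric lengths, mean ~8 Mb), shuffled across six new
  chromosomes (30% strand flips, at least 20% of blocks changing size
  class), carrying activity, compartment and bias along; genome B's Hi-C
  map is sampled independently. CCF agreement across the map therefore
  reflects shared block-intrinsic structure, never shared noise.

Counts are Poisson (depth scale 30, baseline inter rate
$\mu_{\mathrm{inter}} = 0.01\cdot$depth, giving raw maps with roughly
balanced intra/inter mass as at 1 Mb): Poisson keeps the generative
identity O/E $\approx$ 1 exact in expectation; overdispersion is deliberately
out of scope. All randomness flows from one seed through named substreams
(genome layout, states, matrix, synteny), so each stage is independently
reproducible.

What the simulation does **not** emulate: unmappable/repeat-rich regions
(masking is exercised synthetically, not emergently), translocation
breakpoint effects inside blocks, copy-number variation, overdispersed
counts, restriction-fragment density, and the fine-scale (sub-Mb)
compartment structure that makes 1-Mb compartment calling fail in fly.
Passing tests demonstrate correctness of the computations and
recoverability of planted structure at realistic signal levels — not that
real maps contain that structure.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; BED input is native.
* The 5-Mb cut is implemented in bin units as $|i-j| \le
  \lceil \mathrm{min\_sep}/\mathrm{bin\_size}\rceil$ (inclusive).
* An all-zero CCF vector yields an all-zero percent track with a warning,
  not an error.
* O/E entries with missing or zero expected value are missing; zero-variance
  rows of the O/E matrix make their correlations missing with a warning and
  are mean-imputed only inside the PCA.
* A chromosome with no intra-chromosomal contacts has modularity 0 for all
  segments (warning).
* Dense in-memory matrices are the contract; a 3,000-bin genome at 1 Mb
  costs ~70 MB, which is cheap, and fine grids are handled by `rebin()`
  aggregation from a finer dense grid.
* Problem sizes in the test-suite and acceptance runs: ~680-bin genomes,
  5 recovery seeds, 100-replicate downsampling controls (100 calibration
  runs), 100-permutation windowed nulls (200 calibration runs), 200 random
  TAD instances at $n \le 12$ — chosen so each validation stage finishes in
  seconds to a few minutes on one CPU while leaving Monte-Carlo noise well
  below every asserted margin.

## Worked example

```{r example}
spec <- sim_spec(seed = 1)
g <- generate_genome(spec)
hic <- generate_hic(g)

ccf <- compute_ccf(hic)                       # total CCF, 5 Mb filter
comp <- compartment_pipeline(hic, genomic_track(g$bins, g$bins$gc, "gc"))
grp <- group_fractions(bin_state_coverage(g$states, g$bins),
                       state_grouping("human15"))

c(pve = comp$pve,
  agreement = mean(comp$label == g$truth$compartment, na.rm = TRUE),
  ccf_active = pearson(ccf_track(ccf, "percent"), grp$active))
```

The same pipeline is exposed on files through `run_simulate()`, `run_ccf()`,
`run_compartments()`, `run_tads()`, `run_states()`, `run_correlate()` and
`run_synteny()`, each of which writes bedGraph/BED/TSV outputs, a JSON
report and its resolved YAML config; `inst/cli/hiccf.R` wraps them for shell
use.

## Known limitations

* The expected-matrix inter-chromosomal constant is one number genome-wide;
  chromosome-pair-specific inter preferences therefore surface in the O/E
  and can contribute to PC1 — intended here, but different from pipelines
  that exclude inter entries (a per-chromosome PCA mode is provided).
* Balancing/iterative correction is intentionally absent: the object of
  study is the raw-map signal that balancing removes.
* The modularity TAD caller is a single-scale segmentation; no consensus
  across $\gamma$ values.
* `.hic` (Juicer) and HDF5 cooler binaries are not parsed; dense text
  matrices, cooler-style text tables (chroms/bins/pixels) and BED/bedGraph
  are the interchange formats.
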