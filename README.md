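# hiccf — cumulative contact frequency analysis of Hi-C maps

Hi-C normalization procedures such as iterative correction equalize the
total number of contacts of every genomic bin. The signal they remove — the
**cumulative contact frequency** (CCF), a bin's summed raw contact
frequency — is usually dismissed as technical visibility bias, yet open,
transcriptionally active chromatin genuinely accumulates more contacts.
`hiccf` is an R package for studying CCF as a biological signal. It is
written for computational genomicists working with binned Hi-C maps who
want to quantify what balancing throws away.

For bin *i* of a raw contact matrix *C*,

    CCF_i = Σ_j C_ij   over j ≠ i, excluding intra-chromosomal pairs
                        separated by ≤ 5 Mb (inclusive; configurable),

reported raw and as percent of the map's maximum, in a whole-genome and an
inter-chromosomal flavor. Around this statistic the package provides:

* **I/O and grids** — fixed-size bin tables (0-based half-open), dense text
  matrices, cooler-style text tables (chroms/bins/pixels), BED/bedGraph
  tracks, masking and multi-resolution rebinning;
* **A/B compartments** — observed/expected normalization, O/E correlation
  matrix, PCA with reference-oriented PC1, proportion of variance explained;
* **TADs** — modularity-scored segmentation (resolution γ = 1) by exact
  dynamic programming, segments < 3 bins classed interTAD;
* **chromatin states** — per-bin coverage fractions from labeled
  segmentations with proportional boundary splitting; built-in human
  15-state, mouse 7-state and fly 9-color active/inactive groupings;
* **correlation analyses** — genome / per-chromosome / TAD / interTAD
  Pearson reports, 10-Mb windowed correlations with a cyclic-shift
  permutation null, downsampling controls for sample-size effects, and
  GC-content / chromosome-length confounder removal;
* **synteny** — projection of tracks between two genomes through a block
  map with proportional splitting of ambiguous mappings, and CCF
  correlations across large/small chromosome class pairs;
* **a synthetic Hi-C generator** — Poisson-sampled maps with planted
  distance decay, compartments, activity-coupled visibility bias, GC
  confound, small-chromosome inter-contact preference, and rearranged
  genome pairs sharing block-intrinsic activity, providing ground truth for
  every stage.

## Worked example

```r
library(hiccf)

spec <- sim_spec(seed = 1)          # 6 chromosomes, ~680 Mb, 1 Mb bins
g    <- generate_genome(spec)       # bins + ground truth + state annotation
hic  <- generate_hic(g)             # Poisson-sampled raw contact matrix

ccf  <- compute_ccf(hic)            # total CCF, 5 Mb near-diagonal filter
comp <- compartment_pipeline(hic, genomic_track(g$bins, g$bins$gc, "gc"))
grp  <- group_fractions(bin_state_coverage(g$states, g$bins),
                        state_grouping("human15"))

comp$pve
#> [1] 0.646077
mean(comp$label == g$truth$compartment, na.rm = TRUE)
#> [1] 1
pearson(ccf_track(ccf, "percent"), grp$active)
#> [1] 0.8095189
pearson(regress_out_gc(ccf, genomic_track(g$bins, g$bins$gc)), grp$active)
#> [1] 0.54275
```

Reading: the first principal component of the O/E correlation matrix
explains 65% of the variance and recovers every planted compartment label;
CCF (as percent of the map maximum) correlates at 0.81 with the active
chromatin-state fraction, and the association persists (r = 0.54) after
regressing out the GC confound built into the simulation.

The same steps run on files via `run_simulate()`, `run_ccf()`,
`run_compartments()`, `run_tads()`, `run_states()`, `run_correlate()` and
`run_synteny()` (YAML config, JSON reports), or from a shell through the
thin wrapper `inst/cli/hiccf.R`:

```sh
Rscript inst/cli/hiccf.R simulate --outdir out --seed 1
Rscript inst/cli/hiccf.R ccf --matrix out/matrix.tsv --bins out/bins.bed \
    --outdir out
```

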