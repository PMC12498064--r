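---
title: "Methods: comparative chromatin architecture with chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative chromatin architecture with chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromarch compares the three-dimensional genome and the regulatory landscape
of two tissues or conditions — the motivating system is a legume root versus
its nitrogen-fixing nodule — from binned Hi-C contact matrices, peak sets,
signal tracks and replicated expression tables. This vignette explains the
models and procedures, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices behind the
implementation.

## Contact-map model and normalization

A `ContactMap` holds one dense symmetric raw-count matrix per chromosome,
with a per-bin balancing weight vector and a bad-bin mask. Dense storage is
deliberate: the package targets per-chromosome matrices up to a few
thousand bins (e.g. a 20-Mb chromosome at 40-kb resolution is 500 bins),
where dense linear algebra is simpler and faster than sparse bookkeeping.

**Balancing** uses row-normalizing iterative correction: weights are
updated by the square root of the relative row sum until all unmasked row
sums agree to a relative tolerance of `1e-5` (at most 200 sweeps; failure
returns partial weights and a flag rather than an error). Bins with zero
marginal counts, or with coverage below the 2nd percentile of nonzero rows,
are masked before balancing. The percentile is a package choice — upstream
tools differ and no single convention is canonical.

**Distance decay.** `expected_by_distance()` gives the mean balanced
contact per bin-distance stratum pooled over chromosomes — the P(s) curve.
O/E matrices divide each pixel by its stratum mean, which makes them
invariant to sequencing depth.

**LOWESS z-scores.** For condition comparison, every pixel is standardized
against its distance stratum, with the stratum mean and SD smoothed by
LOWESS *in log-log space* (span 0.3 over log10 bin distance; the SD floored
at `1e-6`). Log-log smoothing matters: both moments decay roughly as power
laws, and a linear-response LOWESS cannot follow them across orders of
magnitude. The difference matrix is then a plain subtraction with a fixed
sign convention (first argument minus second), so antisymmetry is exact in
floating point. Note a calibration caveat: per-stratum moments of the
z-scores are (0, 1) only on maps whose structure is smooth in distance;
compartment plaid and domain blocks legitimately shift stratum moments and
are preserved, not removed, by this normalization.

## Compartments

Per chromosome the O/E matrix is turned into a Pearson correlation matrix
over unmasked bins and its leading eigenvector (PC1) extracted by dense
symmetric eigendecomposition (genomes at 100-kb bins are small; power
iteration would honor the same contract at scale). The eigenvector sign is
arbitrary per matrix, so it is anchored per chromosome to gene density:
PC1 is flipped so its correlation with the per-bin gene count is positive,
and A is the PC1 > 0 side — gene-dense, active chromatin. A PC1 of exactly
zero is labelled NA rather than forced into a class. Per-chromosome rather
than global anchoring is a design choice: each chromosome's eigenvector has
its own arbitrary sign, so a global correction is not even well defined.

Switches between conditions are the per-bin label pairs A2A/A2B/B2A/B2B,
with NA whenever either side is NA; the counts partition the bin universe.

**Saddle analysis.** Bins are ranked by PC1, trimmed to the 2nd–98th
percentile (`qrange = c(0.02, 0.98)`), and cut into 10 quantile groups
(the quantile count is a package default; only the range and the corner
fraction are inherited choices). The saddle matrix is the mean cis O/E per
group pair. Compartment strength uses the extreme 20% of retained bins:
`x = top(A-A)/bottom(A-B)` and `y = top(B-B)/bottom(A-B)`, the corner-mean
ratios of within-A, within-B and cross pairs. Uniform O/E gives x = y = 1
exactly; strength is invariant to uniform count scaling because O/E is.

## TADs

The insulation score of bin *i* is the log2 ratio of the mean balanced
contact in the diamond `{(u, v): i-w <= u < i < v <= i+w}` — excluding the
`ignore_diags = 2` nearest diagonals — to the chromosome-wide mean diamond.
The window half-width defaults to 10 bins (400 kb at 40-kb resolution), a
mid-range value in common insulation practice; the upstream parameter set
this package mirrors does not pin the window. Scores are NA within one
window of chromosome ends and where more than half the diamond is masked.

Boundaries are local minima with prominence-style strength: the smaller of
(nearest flanking local maximum − minimum) on each side, called when the
strength reaches `threshold = 0.1` and the bin lies at least
`min_dist_bad_bin = 5` bins from any masked bin (a hard veto). Ties between
equal adjacent minima resolve to the lower bin index; on a perfectly
symmetric two-block fixture the two bins straddling the block edge tie
exactly and the lower one is reported. TADs are the intervals between
consecutive boundary bins; boundary bins belong to no TAD, so TADs plus
boundaries tile the chromosome. `derive_tads(min_bins = 3)` drops
degenerate slivers by default; passing 1 keeps the exact tiling.

**TAD comparison** builds the bipartite bp-overlap graph between the two
TAD sets and labels each connected component: 1-to-1 with reciprocal
overlap strictly above 75% on both sides is *stable*; k-to-1 is a *merge*;
1-to-k a *split*; everything else — including 1-to-1 pairs at or below
75%, and TADs with no partner — a *rearrangement*. Swapping the conditions
exchanges merge and split and preserves the other labels. Overlap
fractions are computed in bp on half-open intervals.

## Loops

The caller tests every cis pixel between `2*outer + 1` bins and
`max_dist_bp` from the diagonal. The local expectation is the mean O/E of
a donut ring (inner radius 2, outer radius 5 bins, row/column arms
excluded so stripes do not inflate the background) *or* of the lower-left
quadrant between the anchors, whichever is higher. The second background is
essential: a domain corner sits on an elevated interior, and against a
donut that straddles the domain edge it would look punctate. The raw-space
expectation is `local_OE * P(s) / (w_i w_j)`; the p-value is the upper
Poisson tail of the raw count; BH-FDR is applied within log2-distance
strata so the decaying background cannot confound the correction across
distances. Because the local background is itself an estimate, Poisson
p-values are anti-conservative in deep maps, and a call additionally
requires observed/expected >= 2.5 (`min_enrichment`) — the same role the
fold-change gates play in donut-based callers generally. Survivors are
clustered by 8-connectivity and each cluster reduced to its
maximal-enrichment pixel.

Calls from several resolutions are merged by grouping mutually overlapping
calls (both anchors, transitively) and keeping each group's
finest-resolution calls with their anchors verbatim.

**Comparison.** Common loops require reciprocal overlap of at least
`f = 0.5` on both anchors, matched greedily by score so each loop pairs at
most once. A non-common loop is condition-specific only when no loop of
the other set lies within `slop_bp = 40000` on both anchors; loops with a
partner within the slop but below `f` are reported as *ambiguous*. The
three statuses partition each input set — a loop cannot be simultaneously
"common" and "specific", but it can honestly be neither.

**APA** averages the O/E submatrix ±`flank_bins` (default 5) around each
loop pixel, excluding loops whose window leaves the matrix or crosses the
diagonal, and scores the pileup as the center pixel over the mean of the
four corner boxes of width `max(1, floor(flank/2))` (the corner-box width
is a package choice; a single corner pixel is too noisy at small loop
counts).

## Open chromatin, differential gates, enhancers

A peak is a **local OCR** iff it overlaps, by at least 1 bp, the
strand-aware window from 3 kb upstream of a TSS through the TTS of any
gene; otherwise it is a **distal OCR** (dOCR). Peak enrichment is mean
per-base signal minus mean per-base background over the region, with
uncovered bases counting as zero.

**Differential regions** scale counts to CPM, form the log2 fold change of
condition means with pseudocount 1, and test with Welch's t on log2(CPM+1)
across replicates (an equal-rate binomial exact test on summed counts
stands in when either condition has a single replicate). BH across
regions; significant iff |log2FC| > 0.5 and q < 0.05 (both strict).
**DEG calling** mirrors this on FPKM with pseudocount 0.01, gates q < 0.01
and linear fold change > 1.5 in either direction, and classes expression
as high (mean FPKM > 100), non-expressed (< 1), or expressed. These
defined tests are the package's replacements for the black-box differential
tooling the analyses are usually run with; their type-I error and
sensitivity have explicit contracts in the test suite.

**Histone cases.** "Strong" means overlap with a called peak — the
upstream currency of ChIP analyses — rather than a continuous cutoff the
source analyses never state. Case 1 is strong H3K27me3; Case 2 all weak;
Case 3 strong H3K4me3 (with or without H3K9ac); Case 4 strong H3K9ac only.
Two conventions needed fixing: a region carrying both repressive and
active marks goes to Case 1 when the K27me3-covered fraction is at least
the best active fraction (ties conservative to repression), and a
K4me3-only region goes to Case 3, reading Case 3 as the
active-promoter-like state. Putative **enhancers** are Case 3/4 regions
that do not touch any TSS ±3 kb window; the exclusion is asserted, not
assumed, in the tests.

## Integration

dOCR–gene links restrict to intergenic–gene loops and link a loop when its
intergenic anchor contains (any overlap) at least one dOCR; linked genes
are those whose body or promoter overlaps the partner anchor (the gene-side
rule is a flag; body∪promoter is the default because both phrasings appear
in practice). dOCR activity between conditions combines openness
(overlap with a direction-matched significant ATAC region) with flanking
H3K27me3 (±2 kb, the flank being a package default where "flanking" has no
stated distance): more open and/or weaker K27me3 in a condition makes the
dOCR active there; evidence in both directions is a flagged conflict.
TFBS categories on dOCR–gene loops are assigned per motif and link — dOCR
anchor only, gene anchor only, or Joint for both. Shifted controls redraw
each region's position by a uniform shift within ±500 kb (resampled until
on-chromosome), preserving the width multiset exactly. All of these
linking operations are property-tested against brute-force enumeration on
random fixtures.

Containment of a dOCR in an anchor uses any-overlap rather than full
containment; the choice is recorded in the output metadata.

## The synthetic generator

`sim_config()` + `make_genome()` plant a complete paired-condition truth:

* **Compartments**: contiguous blocks with geometric lengths (mean 12
  bins) and alternating signs; the treatment flips `n_flipped_blocks`
  non-adjacent blocks, so each flip is exactly one maximal differing run
  and A2B/B2A recovery is unambiguous.
* **TADs**: a partition into 5–15-bin domains; treatment applies
  merge/split edits. **Loops**: shared anchor pairs 12–50 bins apart, plus
  gain/loss edits.
* **Contacts**: `Lambda = depth_norm * s^(-alpha) * (1 + delta*e_i*e_j) *
  tad_boost^[same TAD] * loop_boost^[anchor]`, with independent Poisson
  counts (a gamma multiplier for overdispersion is deliberately left out
  so closed-form oracles stay exact). Defaults: alpha 1, delta 0.4,
  tad_boost 2, loop_boost 4, depth 5e6.
* **Genes and expression**: genes placed preferentially (p = 0.8) in
  A-like blocks; planted FPKM means 30 (active), 300 (a high tail), 0.5
  (repressed); flipped blocks couple expression to architecture with the
  configured fold (default 4), plus a free 15% of DEGs. Replicate noise is
  log-normal with sdlog 0.05 (5% CV): the generator is calibrated so that
  its own planted 4-fold effect is recoverable at the q < 0.01, FC > 1.5
  gates with three replicates, which is the recovery contract the test
  suite enforces — a Welch test at n = 3 under heavier noise cannot clear
  those gates regardless of implementation.
* **Peaks and tracks**: ATAC at active promoters plus distal sites (a
  third at loop anchors so dOCR–gene links exist; target local fraction
  0.174), H3K4me3/H3K9ac at active TSSs, H3K27me3 over repressed blocks,
  planted distal K9ac(/K4me3) enhancers, bedGraph tracks with plateau
  signal over peaks above a noisy floor, and hypomethylation inside ATAC
  peaks.

What the generator does **not** emulate: restriction-fragment structure,
read-level artifacts, copy-number and mappability biases, replicate batch
effects, overdispersed counts, trans-contact structure beyond a uniform
labelled background, and correlated noise between marks. Passing the
recovery suites therefore demonstrates that the algorithms implement their
contracts on data matching their generative assumptions — not that the
pipeline is robust to every artifact of real libraries.

## Problem sizes and determinism

The shipped tests and the acceptance script run at sizes chosen to
exercise every stage at realistic resolution while staying desk-scale:
compartment analyses on 2 × 20-Mb chromosomes at 100-kb bins and 5e6
pairs; TAD analyses at 40-kb bins and 2e7 pairs; loop analyses on a 10-Mb
chromosome at 10-kb bins and 2e7 pairs (a typical loop-resolution depth
per unit genome). Every stochastic stage derives its own stream from one
master seed by stable string hashing, so the full pipeline is byte-identical
across reruns of the same configuration — the manifest records parameters
and MD5 checksums of every output.

## Known limitations

* The loop caller's Poisson test ignores uncertainty in the local
  background estimate; the enrichment gate compensates pragmatically, and
  weak loops (< 2.5-fold) are invisible by design.
* Compartment orientation needs informative gene density; a chromosome
  with near-uniform density anchors weakly, and its labels should be
  treated with caution.
* Welch-on-log gates are honest but underpowered relative to moderated
  (information-sharing) tests at very small replicate counts.
* Dense matrices cap practical chromosome sizes at a few thousand bins per
  chromosome; that covers the intended analyses (>= 10-kb bins on
  plant-sized chromosomes) but not single-kb resolutions on large genomes.
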