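---
title: "Methods: granule-neuron cell states, spatial mapping and tumor programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granule-neuron cell states, spatial mapping and tumor programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gnstates` implements a connected set of analyses for studying how the cell
states of developing cerebellar granule neurons map onto anatomical space and
onto Sonic-hedgehog-type medulloblastoma: bin-matched signature scoring and
maximum-score state assignment, spatial-region × cell-type hypergeometric
intersection enrichment, Moran's I gene-module discovery over a cell kNN
graph, steady-state RNA-velocity transition quantification, per-tumor NMF
meta-programs, moving-average copy-number inference, and kNN-regression
lineage similarity. Every stage can be exercised against a synthetic-data
generator that plants a recoverable ground truth, so the package's behaviour
is testable end to end.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the methods literature
leaves the choice open. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

# The biological template

Postnatal granule-neuron development proceeds along a chain of four states:
non-dividing granule-neuron progenitors (GNPs), dividing GNPs, migrating
granule neurons (GNs I) and mature granule neurons (GNs II). The states
occupy ordered cerebellar layers (external granule layer through internal
granule layer), and SHH-type medulloblastoma cells re-use the same
transcriptional programs with a self-renewal-biased transition structure,
chromosome-scale copy-number shifts, and a tumor-specific metabolic program.
The synthetic generator (`sim_config()`, `simulate_reference()`,
`simulate_spots()`, `simulate_kinetics()`, `simulate_tumor()`) emulates
exactly this structure.

# The synthetic-data generator

## Counts

Cells draw a state from `state_prior` (uniform over 4 states by default) and
a library size from a log-normal (`mu = log(5000), sigma = 0.3`, a typical
droplet depth profile). Gene relative abundances are log-normal; each state
owns a disjoint signature of `signature_size_per_state = 50` genes (matching
the field's top-50 program convention), plus a 50-gene cycling program and —
for tumors — a 50-gene metabolic program. A program gene's mean is multiplied
by `exp(effect_lnfc)` (default ln-fold-change 1.0) in the cells where the
program is active. Counts are negative-binomial with one global `size`
parameter, `nb_dispersion = 10` (biological coefficient of variation
≈ 0.3, in the range used by established single-cell simulators for
UMI data). Mitochondrial ("mt-") and ribosomal ("Rps") gene names are
simulated so the QC filters have something to act on; genes are placed on 19
autosomes in contiguous blocks, with mitochondrial genes on chrM.

## The transition kernel is realized through phase

Each cell carries a within-state phase in (0, 1). The row-stochastic
`transition_kernel` (diagonal + chain successor only) is realized by
position: a state-k cell is *exiting* toward its successor exactly when its
phase lies past `switch_phase = 0.85`; the kernel's self-transition
probability is the fraction of cells placed before the switch. Terminal-state
cells accumulate past the switch phase (`terminal_deep_fraction = 0.7`),
mirroring the occupancy profile of the transit states — without this the
terminal state's entry region is several-fold denser than the other states'
and distorts graph neighbourhoods at the last junction. The default kernel
uses self-transition 0.3 everywhere (absorbing last state);
`tumor_sim_config()` raises the dividing state's self-transition to 0.7.

## Kinetics

Spliced (`s`) and unspliced (`u`) levels follow the exact solution of the
two-stage model `du/dt = alpha - beta*u`, `ds/dt = beta*u - gamma*s`,
evaluated piecewise over each gene's induction and repression windows
(`kinetics_closed_form()` is exported and is the reference for the tests).
Design choices that matter:

* Rates are per-gene, `beta ~ U(20, 30)` and `gamma ~ U(1.2, 1.6)` per unit
  state-occupancy time, so splicing equilibrates much faster than
  degradation and the unspliced layer *leads* — the property the
  steady-state velocity estimator depends on.
* A state's signature is induced from the predecessor's exit window onward
  and switched off in exiting cells; switching *leads* the committed exit
  window by 0.10 phase so that every planted transition has kinetic signal
  at observation time.
* Once a residual program's off-exposure (`gamma * time`) passes 1.4 it is
  set exactly to its low steady state. This makes the "no dynamics" ground
  truth exact (zero velocity, not asymptotically small), which keeps the
  sign-agreement ground truth unambiguous.
* Noise is multiplicative log-normal with sd 0.05 on `u` and `s`. The
  kinetic layers are latent rates; the count-level noise lives in the
  negative-binomial layer.

The count matrix is deliberately blocky per state (signature means multiplied
by the full effect for every cell of the state) while the kinetic layers are
smooth along the chain: scoring and marker detection see the crisp state
structure they assume, and the velocity pipeline runs in spliced space where
the manifold is continuous. This mirrors real data, where UMI counts and
spliced/unspliced loom layers are distinct measurements.

## Spots

Spatial spots aggregate exactly `spot_cells = 30` member cells (the
approximate per-spot cell count of the emulated platform, fixed for exact
conservation testing). Member states are drawn from the layer's composition
row (default: each of four layers is 70% its home state), member cells
uniformly without replacement within a spot, and the spot's gene vector is
the exact sum of its members' counts. Spots carry grid coordinates in
contiguous layer bands.

## What the generator does not emulate

No ambient RNA, no doublets, no batch effects, no gene-gene correlation
beyond the planted programs, no spatial bleed between adjacent spots, and
state programs are disjoint rather than overlapping. Tests passing on this
generator therefore demonstrate correctness of the implementations and
recoverability under clean planted structure — not robustness to the
artifacts real data add.

# Analysis methods

## QC and normalization

`filter_cells_qc()` keeps cells with strictly more than 500 detected genes
and a mitochondrial fraction strictly below 10%, computing fractions on raw
counts *before* removing mitochondrial/ribosomal genes (the standard order;
the source procedure is silent on it). `filter_spots_qc()` removes spots with
fewer than 500 detected genes or over 10% mitochondrial signal, then genes
detected in fewer than 15 retained spots — spots first, then genes, the order
in which the criteria are stated. `lognormalize()` is
`ln(1 + count * 1e4 / total)` per cell, preserving sparsity.

## Signature scoring and state assignment

`score_signature()` ranks genes into 24 equal-frequency bins by dataset-mean
expression and draws 100 control genes per signature gene from the same bin
(seeded, signature genes excluded; with replacement when a bin is too small,
which is logged). The score is mean(signature) − mean(controls), the
established bin-matched control scheme. `assign_state_by_max()` takes the
argmax across signature columns (ties break to the first column and are
flagged). `score_cell_cycle()` scores the packaged 43-gene G1/S and 54-gene
G2/M lists and combines them by the maximum; `binarize_by_mad()` calls a cell
positive above median + 2 unscaled MADs (no 1.4826 consistency factor — the
procedure is stated in raw MAD units).

## Markers and spatial enrichment

`find_markers()` implements the one-tailed (greater) Wilcoxon rank-sum scan
with tie-corrected normal approximation and continuity correction,
vectorized over genes (ranks are computed once per gene and shared across
group-vs-rest contrasts; the implementation is cross-checked against
`stats::wilcox.test` in the tests). Genes are tested only when detected in at
least 25% of either population and when the mean natural-log difference
reaches `min_lnfc` (0.3 for the enrichment grids, 0.5 for the four-state
signature workflow). Bonferroni correction runs over the genes actually
tested per group.

`hypergeometric_overlap()` is the upper tail including the observed overlap,
`P(X >= k)`, on a shared background. `intersection_grid()` calls a
(cell type, region) pair enriched when p < 0.05 and *depleted otherwise* —
the display rule of the source analysis, kept although a dedicated lower-tail
test would be the conventional choice; the display value is −log10(p) for
enriched pairs and 0 for depleted ones. Because the hypergeometric test is
discrete, its attained size at alpha = 0.05 is below nominal for small gene
sets; the acceptance suite therefore checks the permutation null against the
exact attained size (computable in closed form) as well as against the
nominal bound.

`filter_state_signature()` is the set algebra (state DEGs ∩ module genes) \
confounder markers; `compare_region_scores()` runs two-sided unpaired
rank-sum tests per signature and layer pair; `profile_correlation()`
correlates averaged state and region profiles over the filtered signature
union.

## Gene modules by graph autocorrelation

`morans_i()` computes `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
the analytic randomization-assumption variance (kurtosis-corrected) and an
optional seeded permutation p (the two agree within Monte-Carlo error in the
tests, and the analytic implementation is cross-checked against an
independent reference implementation on row-normalized weights).
`find_gene_modules()` keeps genes with I > 0.1 and Benjamini–Hochberg
q < 0.05, then groups them by average-linkage clustering of 1 − Pearson r
between cluster-averaged profiles, cut at correlation height 0.7. This
replaces the upstream tool's internal gene-embedding + community-detection
step, which is not described in enough detail to reproduce; the replacement
is deterministic and testable. The kNN graph is built on caller-supplied
coordinates (`knn_graph()`, k = 15 by default, union-symmetrized binary
weights) so the embedding method stays out of the core.
`select_representatives()` takes each module's top 50 genes by dataset-mean
expression, and `merge_to_main_modules()` cuts a Ward tree over standardized
per-cell module scores (default 4 main modules).

## Velocity and transitions

`estimate_velocity_steady_state()` implements the classical steady-state
model: genes need 10 total counts in both layers, the top 3000 most variable
are kept, `gamma_hat` is a through-origin regression of `u` on `s` over the
upper+lower 5% extremes of `s`, and the velocity is the residual
`v = u - gamma_hat * s`. This intentionally replaces the likelihood-based
dynamical model of the upstream tool: that model is an external EM procedure
whose details are not reproducible from its description, while the
transition quantification built on top — the part this package is for — is
specified exactly.

`transition_matrix()` computes, for each cell and each neighbour in its
graph neighbourhood, the Pearson correlation between the cell's velocity
vector and the expression difference vector, restricted to the velocity
genes. The neighbourhood includes neighbours of neighbours
(`recurse_neighbors = 2`, the upstream tool's convention); with purely
1-hop neighbourhoods on a clustered manifold the candidate set almost never
contains cells of the next state and destination quantification degenerates
to self-assignment. The graph's k defaults to 10% of cells (at least 30) —
transition destinations need neighbourhoods that straddle state boundaries,
and a fixed small k under-serves larger datasets. Difference vectors default
to ln-normalized spliced space; any expression matrix over the velocity genes
can be supplied. `assign_destinations()` takes the row argmax (zero-norm
velocity rows are flagged and self-assigned), and `transition_contingency()`
tabulates destination proportions per condition and compares two conditions
with Pearson's chi-square (no continuity correction), warning on expected
counts below 5.

## Tumor programs

`nmf_programs()` factorizes one tumor's ln-normalized expression after
per-gene centering with negatives clipped to zero (the established
intra-tumor heterogeneity convention — factors then capture relative
programs, not absolute expression), using seeded multiplicative updates for
the Frobenius objective (10 factors, top 50 genes per factor). The objective
is non-increasing across updates, asserted in the tests.
`cluster_meta_programs()` scores every factor's top genes on the combined
cells, keeps factors whose score vectors correlate at ≥ 0.3 with a factor
from another sample (tumor-specific noise factors otherwise scramble the
cut; recurrence filtering is the convention of cross-tumor meta-program
analyses and can be disabled), clusters 1 − r with Ward linkage, cuts at 4
meta-programs, and derives each signature from genes appearing in at least
half the member factors' top lists, padded by aggregate loading rank.
`jaccard_similarity()` relates meta-programs to developmental state
signatures.

## Copy-number inference

`infer_cnv()` orders genes by (chromosome, start), clips per-gene relative
expression at ±3, smooths with a 101-gene moving average within each
chromosome, centers each cell by its own mean, and subtracts the reference
cells' per-window mean (so reference windows average exactly zero). Two
implementation choices depart from the plainest reading and are deliberate:
genes below a dataset-mean expression of 0.1 are excluded first (the
reference tool's expression cutoff; near-silent genes carry mostly noise),
and edge windows are clamped asymmetric (constant length) rather than
symmetric-shrunk — with desk-scale chromosomes a shrunk symmetric edge
window degenerates toward single-gene width and its undamped noise dominates
the mean-squared aggregate signal. The per-cell aggregate is the mean squared
window score; the discrete CNV-state calling (hidden Markov model) of the
reference tool is out of scope, so outputs are relative smoothed profiles.

## Lineage similarity

`knn_similarity()` projects query and reference cells onto shared principal
components computed from the concatenated matrix after centering each
dataset per gene separately (removing dataset-level offsets), and lets each
query cell's 20 nearest reference cells vote with one-hot labels; per-cell
scores sum to one, and per-sample means summarize each tumor. Per-dataset
centering implies the query needs internal structure matching the
reference's (a homogeneous one-cluster query would be centered onto the
origin); this is inherent to the batch-offset removal, not an implementation
accident.

# Numerical choices and degenerate inputs

* Determinism: every stochastic step takes a seed and uses an isolated RNG
  stream (`withr::with_seed`); identical configurations give identical
  outputs, byte for byte.
* Moran's analytic p needs n ≥ 4 (the randomization variance involves
  (n−2)(n−3)); smaller inputs report the statistic with NA p, and the
  two-node antithetic case yields I = −1 exactly.
* Zero-variance genes are skipped (Moran), reported missing (profile
  correlations), or flagged (velocity rows), never silently imputed.
* All-identical values give a zero MAD and an all-negative binarization with
  a warning.
* Tie handling: state assignment breaks ties to the first column and flags
  them; rank-sum tests use the tie-corrected variance.
* The NMF update adds `.Machine$double.eps` to denominators; an all-zero
  input after centering/clipping is an error.

# Problem sizes used by the tests and the acceptance script

Simulated datasets are kept at desk scale: 1000 cells × 2000 genes for
scoring/state recovery (the generator defaults), 1200 × 1500 for the spatial
pipeline (4 layers × 30 spots × 30 cells), 2000 cells × 1500 genes for the
velocity kernel-recovery runs (500 cells per state), three 400-cell tumors
for the NMF meta-program runs, and 600 cells × 3000 genes for copy-number
inference, which depends on having many genes per chromosome. These sizes
were chosen so each recovery question is well-posed (e.g. at least 500 cells
per state for destination proportions, as the recovery contracts assume)
while a full run stays comfortably interactive.

# Known limitations

* The steady-state velocity estimator is biased when the steady-state
  assumption fails (e.g. under strong selection on noisy spliced extremes);
  the sign structure, which the transition analysis uses, is much more
  robust than the magnitude.
* Destination assignment by argmax over graph neighbours reflects the
  neighbourhood design; on manifolds whose states are separated by gaps
  larger than the kNN radius, transitions toward a state with no reachable
  representative cannot be recovered.
* The hypergeometric "depletion" call is a display rule (p > alpha), not a
  lower-tail test; treat depleted cells in the grid as "not enriched".
* Meta-program signatures depend on the recurrence filter when tumors carry
  many sample-specific noise factors; with `min_recurrence_r = NULL` the cut
  can scramble.
* `infer_cnv()` reports relative smoothed profiles; without the HMM step it
  does not call discrete copy-number states, and amplitude depends on the
  expression scale of the input.
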