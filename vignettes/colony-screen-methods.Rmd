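---
title: "Methods: colony-array screen quantification and differential growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array screen quantification and differential growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pinned colony-array screens read out a growth phenotype for thousands of
yeast strains at once: strains are arrayed at 384 or 1,536 positions per
agar plate, grown under a control and a drug condition in several replicate
plate sets, and photographed repeatedly over days. In assays of the
protein-fragment complementation (PCA) family, colony growth under
methotrexate selection is itself the signal — it reports reconstituted
enzyme activity and hence protein self-association — so the quantity of
interest is a per-colony *integrated density* extracted from the plate
photograph, and the scientific question is which strains grow reproducibly
better or worse on drug than on control.

This package implements that analysis end to end: colony quantification
from grayscale images, normalization, a regularized differential-growth
test with multi-day hit calling, and downstream set statistics (overlap
with external per-gene datasets, conditional ontology enrichment). A
simulation module generates screens, plate images, external datasets, and
toy ontologies with known ground truth, so every stage is testable without
raw screen data.

# Colony quantification

`quantify_plate()` applies a literal implementation of a grid-walk colony
macro to every position of an estimated grid:

1. **Grid estimation** (`estimate_grid()`). The rotation angle of the
   colony rows relative to the image frame is found by maximizing the
   variance of the foreground-intensity profile projected on the row axis;
   profile peaks then give the pitch (outermost-peak span divided by peak
   count minus one, with sub-pixel peak centroids) and the top-left colony
   center. A manual anchor (top-left, angle, and/or pitch) overrides the
   corresponding estimates, for plates where automatic detection is not
   trusted.
2. **Center of gravity.** Around each predicted center, the intensity
   centroid of a 17 × 17 pixel window is taken, with the background level
   subtracted so that a flat background does not bias the centroid toward
   the window center.
3. **Border walk, twice.** From the centroid pixel, the procedure walks
   left, right, up and down to the last pixel above background, re-centers
   at the midpoint of the resulting bounding box, and repeats the walk once
   from the new center. The repetition count is configurable; the default
   of exactly one repetition follows the procedure this macro reproduces.
4. **Oval readout.** The final walk gives four border distances; the oval
   has semi-axes `(left + right) / 2` and `(up + down) / 2`, and the colony
   score is `integrated density = mean intensity inside the oval × π a b`.
   The mean is computed without background subtraction by default — the
   log-scale normalization downstream absorbs the shared offset — and a
   `subtract_background` flag is available.

**Background model.** "Background intensity" needs an operational
definition: here the per-plate background level is the median of pixels in
inter-colony margins (3 × 3 neighborhoods at the diagonal midpoints
between adjacent grid centers) and a pixel is background iff its intensity
is at most `level + k × MAD`, with `k = 3` by default. This is robust to
bright colonies dominating the intensity histogram.

**Degenerate cases.** An all-background window yields a measurement with
`missing = TRUE` and integrated density 0. Walks are capped at 40 px per
direction to stop runaway on smeared colonies; capped measurements are
flagged. Windows near the image edge are clamped inward.

# Normalization

Raw integrated densities are log2-transformed (`log_transform()`, with a
pseudocount of 1 guarding empty positions), then normalized in two steps.

**Quantile normalization within condition and day.** The replicate plate
sets of one condition on one imaging day are forced to a common empirical
distribution (rank-wise means, ties averaged, missing values left in
place). This removes additive technical differences between replicate
plate sets — a whole-column shift is exactly a distributional difference.
The implementation is `limma::normalizeQuantiles(ties = TRUE)` behind the
`quantile_normalize()` surface.

**Cyclic LOESS between condition pairs.** Drugs hit small colonies harder
than large ones, so the control-vs-drug difference has a trend in colony
size that is not a per-strain effect. For each matched pair of plate
columns (by default, control and drug of the same replicate index and
day), `cyclic_loess()` fits a degree-1 tricube local regression of the
difference `M = x_i − x_j` on the average `A = (x_i + x_j) / 2` with span
0.05, and moves each column half the fitted trend toward the other. The
corrections of one cycle are accumulated and applied simultaneously,
scaled by the number of pairs each column participates in; cycling repeats
up to `maxit = 5` times or until the largest per-column mean squared
correction falls below `epsilon = 1`. Because the two half-corrections are
antisymmetric, the pair average is preserved exactly. The local-regression
primitive is `stats::lowess` evaluated exactly at every point
(`delta = 0`): the default evaluation shortcut interpolates linearly
between fit points and can smear sharp features of the size trend.

Parameter notes. The span (0.05), `maxit` (5) and `epsilon` (1) defaults
are the working values for screens of thousands of strains; at 0.05 the
local window still covers ~175 colonies in a 3,504-strain screen. On small
tables (hundreds of strains) a 0.05 span would put only a handful of
points in each window and absorb genuine strain effects into the "trend";
use a wider span there. The unit of `epsilon` is a design choice the name
alone does not fix; here it bounds the per-column mean squared correction
of a cycle, and with the default value the loop effectively runs one full
cycle — which already removes both a constant and a size-dependent offset,
as the tests verify. The pair set is configurable (`pairing = "all"` for
every within-day column pair).

# The regularized differential-growth test

With four replicates per condition, per-strain variance estimates are too
noisy for a plain t-test. `regularized_t()` implements the empirical-Bayes
variance shrinkage of the Cyber-T family: strains are ranked by mean
normalized density, a background variance `σ₀²` is estimated for each
strain as the mean sample variance of the `window = 101` ranked neighbors
(truncated at the ends), and each group's variance becomes

```
σ̃² = (conf · σ₀² + (n − 1) s²) / (conf + n − 2)
```

with prior weight `conf = 15`, i.e. the neighborhood carries roughly four
times the weight of the strain's own three degrees of freedom. The t
statistic is `(mean_drug − mean_control) / sqrt(σ̃²_c/n_c + σ̃²_d/n_d)`.
The degrees of freedom follow the posterior-variance convention
`df = n_c + n_d + 2·conf − 4` (each group's posterior variance carries
`n + conf − 2` effective df); `df_mode = "classic"` gives the plain
`n_c + n_d − 2`. Background variances are estimated separately per
condition, from that condition's own replicate variances and ranking,
because the two conditions need not share a variance structure.

Per imaging day, p-values are BH-adjusted across strains. A strain becomes
a **hit** when at least `min_days = 2` days qualify (adjusted p below
`alpha = 0.01`) *with a consistent direction*; the shared sign assigns the
strain to the increased-on-drug or decreased-on-drug hit set, which are
disjoint by construction. A strain with two qualifying days in each
direction is not called. Whether the threshold applies to adjusted or raw
p-values is a flag (`use_adjusted`, default adjusted). Strains missing
more than one replicate in either condition on a day are excluded from
that day's test.

# Overlap with external datasets

`compile_dataset()` merges heterogeneous per-gene sources into one score
per gene by category: deletion-fitness calls (−1/0/+1) are summed; mRNA
changes are averaged over the sources a gene appears in; abundance and
quantitative phosphorylation sources are each divided by their own SD and
then summed (qualitative ±1 phosphorylation calls pass through);
localization-flux records are per-compartment/timepoint top Z-score lists
and a gene scores the sum of its absolute Z-scores, with library genes
absent from every list scoring 0.

`overlap_significance()` scans the top 1, 5, 10, 15, 20 and 25% of two
rankings (sizes floored, minimum 1, within the shared universe), computes
the one-sided hypergeometric over-representation p of each intersection,
and reports the minimum over the grid — uncorrected, as is conventional
for this scan; a Bonferroni-corrected copy is emitted alongside. Screen
results are ranked by p-value ascending (`rank_screen_results()`), ties
broken by |effect| descending then strain id: ranking by p-value rather
than colony-size difference damps the noise of small colonies. The signed
mode ranks from the most significant decreased-signal strain through
non-significant strains to the most significant increased-signal strain,
for direction-resolved comparisons. `running_overlap_curve()` smooths the
binary is-in-the-external-top-set indicator along a ranking with a span of
0.3 of the ranking length (a free parameter; the curve is an
enrichment-by-rank diagnostic, not a test statistic).

# Conditional enrichment

`conditional_enrichment()` performs DAG-aware over-representation testing:
annotations are first propagated from children to ancestors (so every
child's gene set is a subset of each parent's), terms are tested bottom-up
(children before parents, sibling ties in lexicographic term-id order for
determinism), and when a term is significant (raw p < 0.05 by default) its
currently annotated genes are removed from the annotations of all its
ancestors before those are tested. The global universe — by convention the
full set of strains tested in the screen — is left untouched; only the
ancestors' annotations shrink. On a flat ontology this reduces exactly to
independent per-term hypergeometric tests. Term significance uses raw
p-values, matching the conditional procedure this mirrors; a BH column is
emitted for information. `enrichment_map()` links enriched terms whose
gene sets have Jaccard coefficient strictly above 0.25, with the
coefficient as edge weight; the graph is exported as edge TSV or GraphML
for layout elsewhere.

`gwas_overlap()` filters SNP-association records to case-control studies
with association p below 10⁻⁵, collapses them per disease to yeast
homolog sets via a supplied mapping table, and tests each set against the
screen hits. `chi_square_independence()` is the classic Pearson chi-square
without continuity correction.

# The simulator

`simulate_screen()` generates, per strain, a baseline log2 density
(Normal, mean 10, sd 1), and per strain × condition × replicate × day a
log2 density composed of: a saturating day-growth curve
(`3 · d / (d + 3)` log2 units), a technical shift drawn once per replicate
plate set and condition (sd 0.2 — a constant column shift, the structure
quantile normalization removes), a basal drug penalty that is a decreasing
logistic function of baseline density (maximum 0.6 log2 units for the
smallest colonies — the smooth size trend cyclic LOESS removes), a sparse
set of spiked true effects (5% of strains, ±0.5 log2 by default — what the
test recovers), and Gaussian replicate noise (sd 0.15 log2). Values are
exponentiated to raw densities. These default magnitudes are chosen as
plausible for dense colony arrays; no public raw screen data pins them
down, so they are parameters, not claims about any particular dataset.

`render_plates()` inverts quantification: each colony is a Gaussian-capped
disc (truncated at 3σ) whose discrete pixel sum above background equals
its table density exactly, with radius proportional to the square root of
density — wider colonies are bigger, as on pinned arrays — capped below
half the pitch so neighbors never merge, and floored at 3 px because
pinned colonies have a minimum physical footprint. The floor also keeps
the oval readout's continuous area `π a b` within a few percent of the
discrete pixel count; for sub-pixel discs the two diverge arbitrarily.

`simulate_external_dataset()` emits category-shaped external data with a
correlation dial against the spiked truth, and `simulate_ontology()` grows
a random rooted DAG whose leaf annotations propagate upward, so the
child-subset invariant holds by construction.

What the simulator does *not* emulate: spatial plate gradients and edge
effects (the pipeline deliberately contains no positional correction),
colony morphology beyond radially symmetric discs, contamination,
pinning failures beyond empty positions, and day-dependent effect sizes
(effects are uniform across days unless configured per-day). Passing
tests on simulated screens therefore demonstrate correctness of the
algorithms under the stated generative model, not robustness to every
artifact of real plates.

# Numerical and design choices

* Coordinates are 0-based pixel indices, x = column, y = row, origin at
  the top-left; images are numeric matrices in 16-bit intensity units.
* Quantile normalization with few, widely separated strains collapses
  replicate variance to exactly zero (replicate ranks are identical); this
  degenerate regime is irrelevant at screen scale but worth knowing when
  testing on toy tables.
* Hypergeometric tails come from `stats::phyper`; BH from
  `stats::p.adjust`; both are cross-checked in the test suite against
  enumeration and hand-coded step-up oracles.
* Hit-direction ties (equal qualifying days in both directions) yield no
  call rather than an arbitrary one.
* Problem sizes in the test suite: quantification fidelity is checked on
  three rendered 1,536-format plates; error control and recovery on
  3,504-strain, 4-replicate, 9-day screens; enrichment calibration on
  1,000 random hit sets against a 25-term DAG; overlap separation over 50
  seeded trials at 1,000 genes.

# Known limitations

* `estimate_grid()` assumes a mostly regular, mostly populated array;
  plates with whole missing rows at the array edge can shift the top-left
  estimate by one pitch. The manual anchor exists for exactly that case.
* The LOESS span is a fraction of points, so its effective bandwidth
  depends on screen size; defaults target thousands of strains.
* The conditional-enrichment procedure tests terms independently per
  direction-specific hit set; no across-term FDR is applied, by design.
* Runtime scales linearly in colonies for quantification (~1.5 s per
  1,536-format plate) and in strains × days for testing.
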