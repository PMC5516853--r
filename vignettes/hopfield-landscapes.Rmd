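---
title: "Quantifying developmental landscapes with Hopfield networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developmental landscapes with Hopfield networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopscape)
```

## The model

Waddington's epigenetic landscape pictures differentiation as a ball
rolling through valleys of a hillside: cells leave a (meta)stable state,
traverse transient intermediate states, and settle into a committed one.
`hopscape` makes that picture quantitative with a Hopfield network built
from expression data.

Given a genes-by-samples matrix, every gene becomes a network node and
every pair of genes is connected by an undirected edge whose weight is
the Pearson correlation of the two genes across *all* samples, pooled
over stages. Correlations are computed on the continuous (z-scored)
values, the diagonal is forced to zero, and the matrix is exactly
symmetrised, giving the classical zero-diagonal symmetric weight matrix
$W$ of a Hopfield network. Because $W$ is estimated once from the whole
time course, every sample is placed on a single static landscape.

Each sample $s$ is represented by a ternary state vector
$H(s) \in \{-1, 0, +1\}^n$, obtained by thresholding the per-gene
z-scores (above $+t$: $+1$, below $-t$: $-1$, else $0$). Its elevation on
the landscape is the network energy

$$E[H(s)] = -\tfrac{1}{2}\, H(s)\, W\, H(s)^\top ,$$

a unitless quadratic form that decreases whenever strongly correlated
genes take concordant states. A stage whose replicates show tight,
reproducible co-variation therefore scores a low (deep) energy; a
transient stage, in which parts of the regulatory network have come
loose, scores close to zero. Crucially, energies are computed from the
*observed* states: the asynchronous recall dynamics that would descend to
a network attractor are available (`hopfield_recall()`) but are never
applied when profiling biological samples, since the point is to position
cells where they actually are, not where the network would pull them.

Under asynchronous updates with the convention that a zero input field
leaves a node unchanged, the energy is a Lyapunov function: each single
node update changes the energy by $-(s' - s)\,f$ where $f$ is the input
field and $s'$ the new state, which is never positive. The test suite
verifies this descent property on hundreds of random networks.

## Parameters that matter

* **Discretisation threshold `threshold`** (default `0.5`, in z-score
  units). A symmetric cut at $\pm 0.5$ gives all three states
  substantial mass under a standard normal (roughly 31/38/31 percent).
  Smaller values recruit more genes into $\pm 1$ states and deepen all
  energies proportionally; the stage *ordering* is insensitive over a
  broad range.
* **Z-score denominator `sd`** (default `"sample"`, i.e. $n-1$):
  conventional for the small replicate counts typical of time courses;
  `"population"` is available and only rescales rows by a common factor.
* **Feature selection** (`select_features()`): genes are ranked by
  descending raw-data variance (ties broken by identifier so the ranking
  does not depend on input order) and either the top $k$ or the prefix up
  to the elbow of the variance curve is kept. The elbow is located
  geometrically: the candidate index maximises the perpendicular distance
  between the sorted variance curve and the chord joining its endpoints;
  if that point already lies below the chord, the drop has happened and
  the elbow is taken one position earlier, so only the high-variance
  plateau is retained. This rule is deterministic and parameter-free.
  Variance is computed on the pre-normalisation matrix, because z-scoring
  equalises all row variances and would make the ranking meaningless.
* **Landscape grid** (`grid_size`, default 50; `margin`, default 10% per
  side). The sample cloud is projected onto the first two principal
  components (samples as observations, genes as features); a regular grid
  over the bounding box is mapped back to expression space with the
  inverse (transposed) loading matrix, discretised *with the same
  threshold as the samples* — the energy is defined on ternary states, so
  grid states must be ternary for the surface and the sample elevations
  to be comparable — and scored with $E$. Each PCA loading vector is
  oriented so its largest-magnitude entry is positive, making surfaces
  reproducible across linear-algebra backends. Both the resolution and
  the discretisation of grid points are recorded in the landscape's
  parameter block.
* **Perturbation analysis** (`run_perturbation_analysis()`): a fraction
  of genes (default fractions 5, 10, 20, 50, 90 percent) is selected at
  random and *all* expression values of each selected gene are replaced
  by uniform draws on $[-1, +1]$; the weight matrix is rebuilt from the
  perturbed data, and per-stage energies are compared with a size-matched
  fully random network ($\Delta E = E_\mathrm{random} -
  E_\mathrm{perturbed}$), 100 repeats per fraction by default. The unit
  of perturbation is the gene, matching the idea of knocking individual
  regulators out of their co-expression context; a `cellwise` flag
  implements the alternative reading (individual gene-sample cells).
  Per-stage significance is a Welch two-sample t-test of perturbed versus
  random energies; exact p-values are reported, never rounded to zero.
  The random baseline is generated as the fraction-1 limit of the same
  perturbation generator, so the two agree exactly for equal seeds.
  Because a "mean distance from the random network" summary can be read
  as $|\overline{\Delta E}|$ or $\overline{|\Delta E|}$, both are
  exported.
* **Switch detection** (`detect_switches()`): replicate states are
  aggregated per stage by the sign of the mean (the simplest symmetric
  consensus), and a gene is *switched* between two stages when its
  consensus is $-1$ in one and $+1$ in the other. Transitions through 0
  are excluded under this strict rule; a `lenient` flag also reports
  $0 \leftrightarrow \pm 1$ changes for exploration.

## Stage energies: mean versus centroid

Per-stage energy is by default the unweighted arithmetic mean of the
stage's per-sample energies. The alternative — the energy of the stage's
consensus (sign-of-mean) state — is available via
`stage_energies(..., stage_method = "centroid")` for comparison; it
emphasises the reproducible core of a stage and typically deepens
endpoint stages relative to transient ones.

## What the synthetic generator emulates

`simulate_arc_dataset()` produces the statistical structure the energy
function actually measures, with interpretable knobs, rather than a
mechanistic gene-regulatory simulation. Genes are partitioned into
modules; module $m$ in sample $s$ has a latent factor
$f_m(s) = 1 + \sigma_f\, \eta_m(s)$ with $\eta_m(s) \sim N(0,1)$, and
gene $g$ of module $m$ takes the value

$$x_{gs} = \mathrm{sign}(m, \mathrm{stage}(s)) \cdot
  c(\mathrm{stage}(s)) \cdot f_m(s) + \varepsilon_{gs},$$

with coherence $c$ equal to `endpoint_coherence` (default 0.9) at the
first and last stage and `transient_coherence` (default 0.2) in between,
and $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$. A `switch_fraction`
of the modules carries sign $+1$ over the first half of the stages and
$-1$ afterwards; their genes are the ground-truth switched set.

The unit mean of the latent factor is a deliberate choice: it anchors a
consistent stage-level sign for every gene, so that consensus states at
the endpoints are reliable and ground-truth switches are exactly
recoverable at low noise, while the factor's dispersion
(`factor_sd`, default 0.2) carries the within-stage co-variation that
distinguishes tight endpoint stages from loose transient ones. A
zero-mean factor would make each sample's module sign a coin flip and
stage consensus meaningless. With the defaults, within-module
correlations within a stage are roughly 0.3 at endpoints versus 0.02 at
transient stages (and much stronger pooled across stages, which is what
$W$ sees).

Default design: 200 genes in 4 modules, 4 stages with 10 replicates
each, noise SD 0.3, switch fraction 0.5, seed 7. Running the pipeline on
this design yields per-stage mean energies that are minimal at both
endpoint stages and maximal at a middle stage — the arc-shaped
trajectory — which the test suite checks across 100 generator seeds.

What the generator does **not** emulate: platform-specific measurement
error, probe-level artefacts, count noise or dropout of single-cell
assays, uneven replicate numbers, or genuinely dynamic (rewiring)
regulatory structure within a stage. Passing tests on synthetic data
therefore demonstrate that the implementation recovers the model's
intended behaviour under its own assumptions, not that any particular
real dataset will show an arc.

`simulate_null_dataset()` provides the matched negative control:
i.i.d. uniform values with no co-variation at all. On such data the
consensus sign of a gene at any stage is essentially a fair coin, so the
strict switch rule still flags roughly 40% of genes between any two
stages — switched-gene lists are only meaningful for data with real
stage structure, and the reported counts should always be compared
against this chance level.

## Numerical choices and degenerate inputs

* Zero-variance genes cannot be z-scored or correlated: normalisation
  maps them to all-zero rows with a warning (they carry no signal), and
  `build_weight_matrix()` refuses them by name, since a Pearson
  correlation with a constant is undefined.
* Correlations are clamped to $[-1, 1]$ and the weight matrix is
  symmetrised as $(W + W^\top)/2$ to remove floating-point asymmetry.
* `sign(0)` conventions: a zero input field during recall leaves the
  node unchanged (required for Lyapunov descent with ternary states); a
  zero replicate mean yields consensus 0 (no consensus).
* A landscape axis with (numerically) zero extent is expanded by a unit
  margin with a warning instead of producing an empty grid.
* All randomised analyses consume seeds derived from one master seed via
  a documented linear-congruential scheme (`derive_seed()`), keeping
  every derived seed below $2^{31}$; reruns are byte-identical.

## Problem sizes used in the test suite

Unit tests run on 60-gene, 24-sample synthetic datasets; the
whole-pipeline property checks use the full default design (200 genes,
40 samples) across 100 generator seeds, with 25 perturbation repeats per
seed for the robustness checks and 20 seeds for switch recovery. These
sizes give stable Monte-Carlo summaries (the separation margins are
several-fold, far beyond their standard errors) while keeping a complete
run of the suite under a minute on a single core.

## Known limitations

* The weight matrix is static: rewiring of the regulatory network along
  the time course appears only indirectly, as loosened co-variation.
* Energies are comparable within one dataset (one $W$), not across
  datasets of different size or gene content, since $E$ scales with the
  number of contributing gene pairs.
* Perturbation $\Delta E$ separates attractor-like from transient stages
  but is *not* an estimate of basin depth or of the time or energy a
  cell needs to escape an attractor.
* The PCA surface is a visual aid: structure orthogonal to the first two
  components is projected away, and grid points far from the sample
  cloud are extrapolations of the linear inverse map.
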