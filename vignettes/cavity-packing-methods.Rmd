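---
title: "Modelling and measuring cavity-driven cell packing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring cavity-driven cell packing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(blastopack)
```

During gastrulation the blastocoel — the fluid-filled cavity of the early
embryo — expands and presses the surrounding ectodermal cell layer against
the stiff vitelline membrane. `blastopack` provides (i) a two-dimensional
particle-based model of this process, (ii) the image-derived quantifications
used to measure its consequences in sections and cultures (packing index,
intercellular space, nuclear-to-cytoplasmic ratio, ROI integrated density,
colocalization), (iii) ground-truthed synthetic data generators, and (iv)
the normality-gated group-comparison statistics used to analyse such
measurements. This vignette explains the models, the tunable parameters,
and the numerical and design choices behind them.

## The particle model

Each cell is a point particle in the plane. A pair at separation $d$
interacts through a short-range anharmonic force (positive = repulsive),

$$
F(d) =
\begin{cases}
k_{rep}\,\bigl(\tfrac{r_0 - d}{r_0}\bigr)^{p_{rep}} & d < r_0\\[4pt]
-\,k_{adh}\,\Bigl[\tfrac{(d - r_0)(r_c - d)}{h^2}\Bigr]^{p_{adh}},
\; h = \tfrac{r_c - r_0}{2} & r_0 \le d < r_c\\[4pt]
0 & d \ge r_c,
\end{cases}
$$

so cells strongly resist compression below the rest separation $r_0$,
adhere weakly at intermediate range, and ignore each other beyond the
cutoff $r_c$. The force is continuous, vanishes at $r_0$ and at $r_c$, and
is the exact negative derivative of a piecewise-polynomial potential
(`pair_potential()`), which the test suite verifies by finite differences.
Defaults: $r_0 = 1$ (the unit of length), $r_c = 1.6$, $k_{rep} = 10$,
$k_{adh} = 1$, $p_{rep} = 2$, $p_{adh} = 1$ — the minimal smooth anharmonic
family with the three-regime behaviour; all are exposed in
`potential_params()`.

Positions follow overdamped first-order dynamics with mobility absorbed
into the time step: per step, a non-fixed cell moves by
$\Delta t\,F + \sigma\sqrt{\Delta t}\,\eta$ with $\eta$ standard bivariate
Gaussian noise. The $\sqrt{\Delta t}$ (Brownian) scaling is the default so
that refining $\Delta t$ does not change the effective temperature; a plain
$\Delta t$ scaling is available as a config switch (`noise_scaling`).
There are no velocities or inertia.

The tissue is initialised as a circular band of concentric rings at
near-uniform spacing (alternate rings staggered by half a cell so the
lattice interlocks). The outermost ring is flagged fixed and never moves —
the vitelline membrane. The blastocoel is a single immobile particle at the
band centroid that only repels, with a rest size that grows linearly in
time up to a cap below the membrane radius.

### Cavity stiffness

For the cavity interaction the rest size sets the *range* of the repulsion,
but the penetration depth is normalised by the cell rest length:
$F_{cav}(d) = k_{rep}\bigl((R - d)/r_0\bigr)^{p_{rep}}$ for $d < R$. Had
the overlap been normalised by the cavity radius $R$ itself, a growing
cavity would become progressively softer — a cell would have to sink a
distance proportional to $R$ before feeling an appreciable force — and the
expanding cavity could never displace a cohesive band. Normalising by the
cell scale keeps the cavity boundary as stiff per unit of penetration as a
cell is, independent of cavity size. The cavity force remains the exact
negative gradient of its potential, so the energy-descent property below is
unaffected.

### Burn-in and the measurement window

The uniform starting lattice is not an equilibrium of the potential:
second-shell adhesion compacts it over the first few time units, in both
the growth and the control condition. To separate cavity-driven compression
from this artificial transient, `run_simulation()` first equilibrates the
band under the run's own dynamics (including its noise) with a *static*
cavity for `relax_steps` steps (default 2,000), then resets the clock and
records observables. Initial/final comparisons therefore measure changes of
a stationary band, and a no-growth control run stays at its baseline up to
noise.

### Observables

Along a trajectory the package records, at each recorded step:

* **packing index** — each non-fixed cell is rasterised as a disc of radius
  $r_0/2$ (discs at rest separation just touch) into the annulus between
  the current cavity boundary and the membrane ring, and
  $n_{cells}\,\bar X_{cell\,area}/\text{Total area}$ is computed from pixel
  counts. Measuring over the band region available to the cells mirrors how
  tissue packing is measured over the ectoderm region in sections: as the
  cavity claims band area, the same cells occupy a larger fraction of what
  remains. The rasterisation resolution (default 10 px per length unit)
  changes the packing index by under 1% when doubled.
* **mean neighbour degree** — mean degree of the graph connecting pairs
  closer than $r_c$, i.e. the pairs that currently interact ("connected to
  neighbouring cells").
* **minimum pair separation** — guards against particle collapse.
* **total potential energy** — the Lyapunov function of the noiseless,
  static-cavity dynamics.

### Stability and determinism

With zero noise and a static cavity, each step is a gradient-descent step
on the total energy, which must then be non-increasing. Empirically the
descent property holds for $\Delta t \le 0.04$ at the default potential
(the pinned stability bound); tests run at half that bound,
$\Delta t = 0.02$, and the production default is $\Delta t = 0.01$. Every
run draws all randomness from one generator seeded from the config, so
identical configs give byte-identical output files. Exactly coincident
particles raise an error rather than being silently perturbed, and any
non-finite coordinate aborts the run with the offending step index.

### Reference conditions and problem sizes

The default configuration is a 6-ring band of 321 cells between radii 6
and 11, cavity rest size growing from 5.5 to a cap of 10.2 at rate 0.12
over 5,000 steps after a 2,000-step burn-in, with noise
$\sigma = 0.05$. The cap and rate are chosen so the cavity genuinely
engages and compresses the band within the simulated window — the regime
the model exists to depict; growth-rate 0 is the matched control. The test
suite and the acceptance script additionally use a 4-ring, 138-cell band
(radii 4–7, cap 6.5, rate 0.25, 3,000-step burn-in, 1,500-step window) for
ensembles, a size at which a 10-seed matched growth/control comparison runs
in a couple of minutes; both sizes are stated here as the package's own
choices of problem size.

In the matched-seed design, the growth condition is compared with the
control run of the same seed. Packing is compared unpaired against the
control ensemble's noise floor; connectivity is compared per seed, because
the noisy control anneals slowly (occasional discrete rearrangements raise
its degree), and the paired contrast is the estimator the matched-seed
design exists to provide.

## Image quantification

All image operations take plain numeric matrices (row-major, 0 =
background in label masks) and return tibbles.

* `packing_index(cell_areas, total_area)` implements
  $n_{cells} \times \bar X_{cell\,area} / \text{Total area}$ together with
  cell density and the percentage of intercellular space,
  $100\,(1 - \sum \text{areas}/\text{total})$ clipped to $[0, 100]$.
* `segment_nuclei()` is a deterministic surrogate for manual DAPI masking:
  global Otsu threshold, hole filling, connected components, minimum size
  30 px (all configurable), via EBImage. A blank image yields zero nuclei,
  not an error.
* `nuc_cyto_ratio()` sums the protein channel over the nucleus
  (integrated density), subtracts it from the whole-cell sum to get the
  cytoplasmic value, and reports their ratio; a non-positive cytoplasmic
  denominator is flagged undefined rather than crashing. The cytoplasmic
  value is an integrated density (not a mean intensity), matching the
  subtraction definition.
* `roi_integrated_density()` subtracts the *per-pixel mean* of a disjoint
  background ROI scaled by the target ROI size (the ImageJ convention);
  the result may be negative. Adding a constant offset to the image shifts
  the raw integrated density by offset × |ROI| but leaves the
  background-subtracted value unchanged.
* `normalize_to_control()` divides by the control-group *mean* (not
  median), so the control's own normalised mean is exactly 1.
* `colocalization()` reports the sample Pearson correlation and the Manders
  overlap coefficient $\sum AB / \sqrt{\sum A^2 \sum B^2}$ over masked
  pixels. "Overlap" is taken to be the Manders overlap coefficient — the
  standard quantity of that name — with the split M1/M2 coefficients
  available on request. Pearson is flagged undefined on zero-variance
  channels; the overlap is still returned.

## Synthetic data

`make_cell_image()` draws disc-shaped cells (jittered grid or
rejection-sampled non-overlapping placement with a 10^4 retry budget) with
a concentric nuclear disc, partitions each cell's protein signal between
nucleus and cytoplasm so the integrated-density ratio equals the requested
value exactly before noise, and adds constant background and additive
Gaussian noise. Intensity is uniform within each compartment — the simplest
model consistent with integrated-density measurements. Exact label masks
and a ground-truth table accompany the pixels, so noiseless images closed
through `quantify_nc()` return the generative ratio exactly, and geometric
quantities agree with analytic disc areas up to rasterisation.

`make_coloc_pair()` draws two jointly Gaussian channels at a requested
population correlation (shifted non-negative); `make_group_table()` draws
grouped samples from normal, lognormal (parameterised by target arithmetic
mean/sd) or exponential families.

What the generators do *not* emulate: point-spread blur, Poisson shot
noise, bleaching, autofluorescence, irregular cell shapes, or 3-D stacks.
Passing tests therefore certify the estimators' arithmetic and their
robustness to additive Gaussian noise at known SNR — not performance on
real micrographs, where segmentation quality dominates.

## Gated group comparisons

`compare_two()` and `compare_many()` implement the decision tree used
throughout such studies: each group is tested for normality (Shapiro–Wilk
by default; the D'Agostino–Pearson K² omnibus test is available, and when
both are requested both must pass — a deterministic reading of "and/or").
Two groups: unpaired two-tailed Student's t (pooled variance; Welch by
flag) when both pass, otherwise two-tailed Mann–Whitney. Three or more:
one-way ANOVA with Dunnett comparisons against the control when all pass,
otherwise Kruskal–Wallis with Dunn's rank-sum comparisons against the
control, Holm-adjusted (Dunn's correction is named without a family-wise
method; Holm is the conservative default and is configurable). All tests
are two-sided at $\alpha = 0.05$ (95% confidence). Zero-variance groups
are flagged degenerate and routed nonparametrically. Dunnett p-values come
from multcomp's quasi-Monte-Carlo integration; the stream is pinned so
results are reproducible to well below any decision threshold.

The gate inflates neither error rate materially: under a normal null
(n = 50 per group) the full gated two-group procedure's type-I error stays
near the nominal 5% (the acceptance suite measures it over 1,000
replicates), and exponential data are routed to the Mann–Whitney branch
essentially always at that sample size.

## Known limitations

* The model is 2-D, with point particles and an isotropic potential: no
  cell shapes, no membrane mechanics, no fluid pressure field, and no
  parameter fitting to embryo measurements — it is a qualitative
  feasibility model of compression by an expanding cavity.
* The original study's exact potential, parameter values and noise
  amplitude live in its external code; the defaults here are declared
  choices, not inferred ones.
* ROI placement rules for in-situ/reporter quantification are anatomical
  and cannot be reproduced; only the measurement arithmetic is provided.
* The slow annealing of a noisy adhesive band never fully stops; control
  drift over long windows is bounded by the matched-seed design, not
  eliminated.
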