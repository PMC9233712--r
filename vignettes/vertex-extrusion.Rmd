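---
title: "Vertex-model simulation and quantification of epithelial cell extrusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model simulation and quantification of epithelial cell extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extrudr)
```

## The model

`extrudr` simulates the early phase of apoptotic cell extrusion in a 2D
vertex model of an epithelium. Only the apical plane is represented: cells
are polygons sharing vertices and edges, and the tissue evolves by
stochastic vertex displacements that relax a mechanical energy. In the
dimensionless form used throughout (lengths in units of the square root of
the initial resting area, the area modulus scaled to 1), the energy is

$$
E = \sum_\alpha \tfrac{1}{2}\Big(\frac{A_\alpha}{A^{(0)}_\alpha} - 1\Big)^2
  + \sum_{(i,j)} \tilde\Lambda_{ij}\, l_{ij}
  + \sum_\alpha \frac{\tilde\Gamma_\alpha}{2} L_\alpha^2 ,
$$

with per-cell area $A_\alpha$, resting area $A^{(0)}_\alpha$, perimeter
$L_\alpha$, edge lengths $l_{ij}$, line tension $\tilde\Lambda = 0.06$ and
perimeter contractility $\tilde\Gamma = 0.02$. Edges on the tissue margin
carry $1.6\,\tilde\Lambda$, which stiffens the boundary against buckling.

Dynamics are Metropolis-style: one uniformly random vertex per iteration
receives a trial displacement; energy-lowering moves are always applied,
energy-raising moves with probability $P_{accept} = 0.05$. Time is counted
in simulation time steps (sts) of 130,000 iterations. Junctions shorter
than $d_{min} = 0.2$ that have shrunk since the previous sts can undergo a
T1 neighbour exchange, again subject to the Metropolis rule.

Extrusion of ten tracked interior cells is triggered at sts 20 in one of
two ways, per iteration:

* **contractility** — $\tilde\Gamma \leftarrow \tilde\Gamma (1 + c)$, a
  purse-string-like drive (grid $c \in \{0, 1, 2.5, 5, 7.5\}\times10^{-7}$);
* **resting area** — $A^{(0)} \leftarrow A^{(0)} (1 - r)$, a drive towards
  zero preferred apical area (grid
  $r \in \{0, 0.5, 1, 2.5, 3.5\}\times10^{-4}$).

The two protocols leave opposite fingerprints on cell shape: contractility
shrinks the perimeter while the cell rounds up (circularity
$C = 4\pi A/P^2$ increases), whereas a shrinking resting area pulls area in
faster than the junctions can follow, crumpling the outline ($C$
decreases). `regime_signature()` classifies a run by exactly this
criterion.

## The initial tissue and its pre-stretch

The tessellation is built from uniform random points in a disk: each point
is reflected across the disk boundary, the Voronoi diagram of the combined
set is computed from a Delaunay triangulation (Bowyer–Watson, implemented
in the package's compiled code because no triangulation library is part of
the package's dependency set), and the cells of the real points tile the
disk with exactly shared vertices. Three Lloyd relaxation steps give a
disordered-but-regularised packing whose tracked-cell circularity,
0.83 ± 0.01 across seeds, sits inside the reported 0.81 ± 0.088.

One design choice deserves emphasis: `initial_area_ratio`, the mean initial
cell area in resting-area units, defaults to **3.7**. The reported initial
tracked-cell state (perimeter 7.58 at circularity 0.81) implies a mean area
of $C P^2 / 4\pi \approx 3.7$ — the simulated tissue starts *pre-stretched*
relative to its resting area. This matters mechanistically: in a
pre-stretched tissue the neighbourhood holds a constricting cell's area
while its perimeter drops, so the contractility protocol rounds cells up;
a tissue started at its resting area relaxes within a few sts to
near-regular polygons whose circularity barely responds to either
protocol. Because the tissue relaxes only through its boundary (interior
moves merely redistribute area), the pre-stretch decays slowly and control
cells hold their perimeter to within a few percent over the observation
window, as required. Circularity itself is scale-free, so this choice does
not affect the initial-shape statistics.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `line_tension_tilde` | 0.06 | — | junctional tension |
| `contractility_tilde` | 0.02 | — | cortical contractility |
| `boundary_tension_factor` | 1.6 | — | margin stiffening |
| `p_accept` | 0.05 | — | thermal noise level |
| `delta_max` | 0.005 | $\sqrt{A_0}$ | trial displacement bound |
| `d_min` | 0.2 | $\sqrt{A_0}$ | T1 trigger distance |
| `iterations_per_sts` | 130000 | — | clock |
| `initial_area_ratio` | 3.7 | $A_0$ | tissue pre-stretch |
| `a0_min` | 1e-3 | $A_0$ | degenerate-resting-area floor |
| `t1_new_length` | 0.21 | $\sqrt{A_0}$ | reopened junction length |

Numerical choices:

* **Proposal symmetry.** A literal reading of the trial move — the *same*
  uniform $\delta d \in [0, 0.005]$ added to both coordinates — drifts the
  whole tissue along the $(+x,+y)$ diagonal. The default draws the two
  components independently from $[-0.005, 0.005]$; the literal variant
  stays available as `proposal_mode = "literal"` for comparison.
* **Degenerate resting areas.** Under the resting-area protocol
  $A^{(0)} \to 0$ and the relative elastic term diverges. Below
  `a0_min` the term switches to the dimensional form
  $\tfrac12 (A - A^{(0)})^2$, which keeps forces finite while preserving
  the drive towards zero area. Note that at the prescribed rates
  $A^{(0)}$ collapses within one or two sts — the gradual constriction
  seen in the runs is relaxation-limited, not ramp-limited, and the
  implementation deliberately leaves this as specified.
* **T1 operationalisation.** An edge is eligible when it is internal,
  shorter than `d_min`, and shorter than it was one sts earlier; sweeps run
  every `t1_check_interval = 100` iterations to bound cost. The rewiring
  candidate (which endpoint goes to which side, insertion order in the
  gaining cells) is chosen as the lowest-energy geometrically valid
  variant, then accepted by the same Metropolis rule as vertex moves.
  Rewirings that would create a face with fewer than 3 vertices are
  skipped. The new junction opens orthogonally at `1.05 * d_min`, which
  prevents immediate re-triggering.
* **Geometry guards.** Proposals that would make any incident face
  non-simple or non-positive in area are rejected before the energy is
  evaluated; simplicity is checked by segment-pair intersection within the
  affected face only.
* **Energy bookkeeping.** The running sum of applied energy changes (moves
  and T1s) must close with the end-to-end energy difference; the tests
  require closure to 1e-6 over a full run and agreement of the incremental
  delta with full recomputation to 1e-9.

## Desk-scale preset

The `"small"` preset (300 cells, 13,000 iterations/sts, 50 sts) keeps
property checks and the test suite within minutes on one CPU. Ramp rates
are always rescaled with `scale_rate()` so the *per-sts* ramp factor
matches the full clock, e.g. $c_{small} = (1+c)^{10} - 1$. Because the
small clock gives each vertex fewer trials per sts, constriction at matched
sts is shallower than at full scale; the regime signatures and the
monotone dose response survive, which is what the desk-scale checks assert
(4 of 5 seeds for the sign patterns, a one-sided Kendall trend test for
monotonicity). Sweeps are paired by seed: all conditions of a seed start
from the same tissue, tracked set and random stream, so trajectories are
identical until the ramp starts.

## The quantification pipeline

The trace side of the package mirrors how the imaging data are analysed:

* **Onset detection** smooths the perimeter with a 5-point moving average,
  then scans every breakpoint, fitting one least-squares line per side and
  scoring the summed squared error against the raw trace; the minimising
  breakpoint is the constriction onset. A trace whose fitted slope does not
  steepen downwards by at least `slope_min` (default 0.1 units/min) is
  flagged "no constriction" — this catches both flat traces and traces
  declining at a constant rate. The implementation uses closed-form
  cumulative-sum fits; the test suite pins it, trace for trace, to an
  exhaustive `lm()`-based oracle.
* **Pulse detection** finds local maxima by topographic prominence
  (threshold 7 intensity units by default). The pulse amplitude is the
  prominence-style height above the higher flanking minimum — "peak
  amplitude" has no universal baseline convention, and prominence is the
  convention the detection threshold itself already uses. Width is
  measured at half that amplitude with linear interpolation.
* **Cross-correlation** follows the mean-subtracted, normalised convention
  (`xcorr(..., 'coeff')`): a positive peak lag means the second channel
  lags the first. The default lag range is a third of the trace length.
* **Contraction yield** is the contraction rate at each contraction-rate
  peak divided by the (junctional) myosin intensity there, binned in 5-min
  windows relative to the onset. Rates are forward differences reported at
  interval midpoints, with the sign convention that a shrinking perimeter
  gives a positive contraction rate.
* **Alignment** is by extrusion end or by onset, with normalisation by the
  first-five-frame mean, the pre-onset mean, or none; ensemble means and
  SEMs are computed over the members present at each relative time.
* **Image operations**: radial kymographs average intensity on 3-px rings
  around the (per-frame) cell centre, with the contour radius taken as the
  ring maximising the junction-channel signal; region intensities erode or
  dilate the cell mask by 3 px (medial/total) or take a 6-px band on the
  contour (junctional), with optional background subtraction from a
  20×20-px ROI; apicobasal profiles are aligned by the reference-channel
  maximum and min-max normalised, ties broken towards the apical plane.
* **Statistics**: group comparisons dispatch on Shapiro–Wilk normality at
  $\alpha = 0.05$ (t test if both samples pass, rank-based otherwise);
  elimination proportions get exact Clopper–Pearson intervals (Wilson
  optional) and two-sided Fisher exact p-values computed by hypergeometric
  enumeration.

## What the synthetic data do and do not show

The generators produce the statistical structure the pipeline assumes:
plateau-then-linear-decline perimeters with uniform onsets and Gaussian
noise; Poisson-timed Gaussian myosin pulses driving the contraction rate
with a configurable gain, integer frame lag and post-onset yield
multiplier (perimeters integrate the rate by forward Euler, so finite
differences recover the planted rate exactly); two-channel ring/disk image
stacks; and cohorts with jittered onsets. Every output carries a truth
record sufficient to score the corresponding analysis step.

Passing these recovery tests shows the pipeline is *correct on data
matching its assumptions* — uniform sampling, additive Gaussian noise,
linear post-onset decline, well-separated pulses. Real microscopy adds
segmentation error, bleaching, non-stationary baselines and pulse overlap,
none of which the generators emulate; numbers measured on real recordings
(absolute lag times, n-values, fold-changes) are therefore not reproduced
here, only the ability of the estimators to recover planted parameters.

## Problem sizes used by the tests

The initial-shape check builds five 1141-cell tissues (~2 s each). The
regime, dose-response and control checks share one cached sweep on the
small preset: 9 distinct (condition, rate) points × 5 seeds ≈ 45 runs of
650,000 iterations, a few seconds each. Recovery checks use 100 traces
(onset), 10 pairs (lag), 50 cells (yield) and an 11-frame 64-px image
stack (kymograph). `scripts/acceptance.R` recomputes the initial-tissue
circularity from scratch over five seeds derived from `--seed`.

## Known limitations

* No cell division, no removal of fully constricted cells from the mesh,
  no 3D/apicobasal mechanics: this is the early extrusion phase only.
* The Monte-Carlo clock is not a physical time; comparisons across presets
  are made at equal per-sts ramp factors, not equal wall-clock relaxation.
* `detect_onset` assumes a single inflection; traces with multiple regime
  changes return the globally best single breakpoint.
* The Voronoi builder assumes generic point positions; exactly cocircular
  quadruples (measure zero for random seeds) are handled by merging
  near-coincident circumcenters at 1e-9 tolerance.
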