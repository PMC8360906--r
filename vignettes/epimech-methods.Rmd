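---
title: "Vertex-model mechanics of a hyper-contractile cell cluster: models, parameters and design choices"
author: "epimech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model mechanics of a hyper-contractile cell cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

# The scientific problem

A compact cluster of hyper-contractile cells (for example, cells
over-expressing an oncogene that raises cortical actomyosin activity) sits
inside an otherwise normal epithelium. The cluster pulls on its
surroundings; the host cells respond by elongating toward it, and their
division behaviour changes. `epimech` provides the complete computational
chain used to study this situation quantitatively:

1. a quasi-static **2D vertex model** of the epithelium with a central
   cluster whose cortical contractility is increased by a chosen fraction;
2. **shape and stress measurements** (shape tensor, principal axis,
   circularity, ring distance to the cluster, orientation toward the
   cluster, isotropic cell stress `Peff`);
3. an **inference stage** that compares cumulative orientation
   distributions between a measured dataset and simulations via the 1D
   Wasserstein distance, summed over three distance bands, and locates the
   contractility increase that best explains the data by grid search;
4. a **Kelvin-Voigt fit** of laser-ablation recoil traces yielding the
   initial recoil velocity (a tension proxy) and the rate `k`;
5. **synthetic-data generators** that emulate the experimental inputs
   (traced cell polygons, recoil traces, division events) so that the whole
   chain is testable without imaging data.

# The mechanical model

Every cell carries the dimensionless energy

$$U = (A - 1)^2 + \frac{\Gamma}{2}\left(L + \frac{\Lambda}{2\Gamma}\right)^2,$$

where $A$ and $L$ are the cell's area and perimeter, $\Gamma$ is a cortical
contractility/stiffness parameter and $\Lambda$ a line-tension-like
parameter prescribing the preferred perimeter $L_0 = -\Lambda/(2\Gamma)$.
Mechanical equilibrium minimises the total energy over all vertex
positions. Throughout, the defaults are $(\Lambda, \Gamma) =
(0.259, 0.172)$, values previously fitted to the Xenopus animal-cap
epithelium. A cluster is modelled by multiplying $\Gamma$ by
$1 + \mathrm{increment}$ inside flagged cells, leaving $\Lambda$ unchanged.

Cell-level stress is summarised by the isotropic component

$$P_\mathrm{eff} = A - 1 + \frac{\Gamma L^2}{2A} - \frac{\Lambda L}{4A},$$

positive under net tension and negative under net compression.

## Where the model lives on its phase diagram, and why it matters

At these parameter values two facts shape several implementation choices:

* A relaxed tissue of unit-area cells is far from stress-free: $P_\mathrm{eff}$
  of a regular hexagon vanishes at area $\approx 0.271$, not 1. The
  generator therefore sizes the periodic box so the **mean cell area starts
  near the zero-stress area** (`hexagon_zero_stress_area()`), and the
  zero-net-stress initialisation then only needs box rescaling factors
  close to 1.
* The single-cell energy is **non-convex in area below $A \approx 0.15$**:
  under-sized cells sit on a runaway branch and collapse under compression.
  Two safeguards follow. First, the initial Voronoi mesh is regularised
  with 30 Lloyd iterations (below), which keeps the smallest cells safely
  above the unstable range. Second, the compiled energy adds a soft
  quadratic barrier that activates only for negative signed areas; it is
  identically zero on every valid configuration and merely prevents
  quasi-Newton line searches from stepping through a cell inversion.

# Tissue generation and relaxation

`generate_tissue(n_cells, seed)` builds a random periodic tiling: uniform
seed points in a square periodic box, Voronoi tessellation (computed by a
compiled Bowyer-Watson triangulation of the points plus ghost copies in a
3.5-spacing margin), and Lloyd iterations. Junctions are identified
combinatorially by the triple of Voronoi seeds that meet there, which is
exact and keeps meshes bit-reproducible from `(n_cells, seed)`.

**Lloyd iterations: default 30.** With only a few iterations the frozen
cell-size disorder is large, and because $P_\mathrm{eff}$ is a difference
of order-one terms its per-cell spread is then many times larger than the
stress signal a cluster imposes on its first ring of neighbours. Thirty
iterations cost little (the tessellation is compiled), roughly halve that
spread, raise the hexagon fraction to about two thirds, and keep the
smallest cells clear of the unstable area range — the disorder regime in
which the cluster's mechanical footprint is measurable on a few seeds.

`relax()` minimises the energy with L-BFGS-B using the analytic gradient
(tested against central finite differences at $10^{-6}$), to a maximum
per-vertex gradient norm of $10^{-6}$. T1 neighbour exchanges trigger when
an edge drops below 0.05 mean edge lengths and reopen perpendicular at 1.5
times the threshold; the reconnection is selected by validating the small
set of candidate topologies against the tiling invariants. In practice T1
moves are rare at the contractility increments studied here, but they are
required for robustness during the compressive leg of the zero-stress
search.

`zero_net_stress()` rescales the box isotropically (bisection over scale
factors in [0.8, 1.2], warm-starting each relaxation from the previous
scale) until the area-weighted mean $P_\mathrm{eff}$ is within $10^{-4}$ of
zero. `apply_cluster()` flags the cell nearest the box centre plus
successive adjacency rings (19 cells by default: a centre plus two full
rings at hexagonal coordination), multiplies their $\Gamma$, and re-relaxes.

# Measurement conventions

* **Centroid** of a cell is the arithmetic mean of its junction positions;
  the **shape tensor** is the second moment of the junctions about it, the
  **principal axis** its leading eigenvector (angle in [0, 180)), and
  **circularity** the eigenvalue ratio in (0, 1]. Cells whose eigenvalue
  gap is below $10^{-6}$ relative are flagged axis-undefined and excluded
  (and counted) in orientation statistics.
* **Ring distance** is the breadth-first graph distance on the
  cell-adjacency graph to the nearest cluster cell, with bands 1-3, 4-6 and
  7+ used everywhere downstream.
* **Orientation to the cluster** is the acute angle between a cell's long
  axis and a reference line toward the cluster, in [0, 90]. The default
  reference is the **cluster centroid** direction. The alternative
  (nearest point on the cluster boundary) is also available, but it is
  measurably biased in the null model: for cells touching the cluster the
  nearest boundary point lies on one of their own edges, and the direction
  to one's own nearest edge correlates with the short axis, pushing the
  null (0%-increment) distribution tangential, whereas the centroid
  reference leaves it uniform — the shipped test suite verifies the
  uniformity of the default convention on pooled null simulations. **Division orientation** keeps the
  nearest-boundary-edge convention, matching how anaphase angles are
  measured against the closest cluster edge in practice; there the
  daughter-nuclei axis is not a shape axis of the polygon, so the
  self-edge correlation does not arise.
* **Division rate** (CDR) is 100 times divisions per cell per minute;
  rose histograms bin [0, 90] into nine 10-degree bins, the last closed.

## Stress contrasts between rings

Ring membership is itself a biased sample of cell sizes: BFS fronts reach
many-sided (hence larger, higher-$P_\mathrm{eff}$) cells earlier, so even
in an unperturbed tissue ring-1 cells average visibly higher
$P_\mathrm{eff}$ than ring-7+ cells. Stress effects of the cluster are
therefore always reported as the **cluster-induced change**: the per-cell
difference between $P_\mathrm{eff}$ after `apply_cluster()` and in the same
relaxed base tissue. At a 30% increment this change is positive in ring 1
and exceeds the far-field change (a contrast the test suite checks pooled
over seeds); at 0% it is identically zero.

# Inference: Wasserstein distance and the contractility sweep

Orientation samples are grouped into the three ring bands and pooled across
embryos (or simulation seeds). The 1D Wasserstein distance between two
samples is computed exactly as the integral of the absolute difference of
their empirical CDFs (equivalently, the earth-mover distance in degrees);
the test suite checks it against brute-force transport (permutation
enumeration and common-refinement pairing) on all sample sizes up to 6.
`summed_distance()` adds the three per-band distances without
normalisation. `contractility_sweep()` scans increments 0 to 0.20 in steps
of 0.01 (configurable), simulating each increment on every seed from a
shared zero-stress base tissue, and returns the argmin (ties resolved
toward the smaller increment). A band empty in both datasets contributes
zero with a warning — this arises only in deliberately tiny smoke-test
tissues whose periodic box cannot hold a 7th ring; a band empty on one side
only is an error.

# Kelvin-Voigt recoil fitting

Ablation traces are fitted with the step response of a spring-dashpot
element,

$$d(t) = d_0 + D\,(1 - e^{-kt}),$$

by bounded Levenberg-Marquardt least squares on the post-ablation samples,
with the baseline $d_0$ fixed to the pre-ablation mean by default (a
free-baseline mode exists). The initial recoil velocity is $d'(0) = D k$
exactly. Initial guesses are $D$ = net displacement and $k$ = inverse
half-rise time, with $k$ bounded in $[10^{-4}, 10]$ per second. Noisy
traces can push $k$ to its upper bound (an effectively instantaneous rise);
the fitter reports the bounded estimate rather than failing. `k` is
reported alongside the initial recoil without further mechanical
interpretation.

# The synthetic-data generators

The generators produce pseudo-experimental tables in exactly the dialects
the measurement functions consume, deterministically from a master seed.

* **Tracings** run the full simulation pipeline per pseudo-embryo (default
  5 embryos, 400 cells, 19-cell cluster) at a configurable true increment,
  recentre the cluster, and add isotropic Gaussian **vertex jitter** with
  sd equal to 2% of the mean edge length — a stand-in for manual tracing
  error, applied to the shared junction coordinates so neighbouring
  polygons stay consistent. 2% is small enough that self-recovery of the
  generating increment succeeds, and of the order of a pixel at typical
  magnifications.
* **Recoil traces** sample the Kelvin-Voigt curve every 4 s (the confocal
  frame interval) for 30 frames with three pre-ablation frames, adding
  Gaussian noise of 5% of the amplitude by default. Default amplitudes
  place the cluster group above wild type; the default rate is
  $k = 0.1\,\mathrm{s}^{-1}$ (half-rise about 7 s), chosen so the recoil
  saturates over tens of seconds, consistent with an acquisition protocol
  that records every 4 s for 2-3 minutes — a rate that saturates within a
  single frame would not be measurable on such a protocol, nor plausibly
  the reason for choosing it.
* **Division events** arrive as a Poisson process at a configured rate (in
  percent of cells per minute; default 0.2, a typical order for gastrula
  animal-cap epithelium), with centroids in an annulus around a disc-shaped
  cluster and in-plane axes deviating from the toward-cluster direction by
  a wrapped-normal-like angle of sd $1/\sqrt{\kappa}$ ($\kappa = 0$ gives
  uniform axes); a configurable fraction of events is out of plane and
  excluded from orientation (but counted).

What these generators deliberately do **not** emulate: embryo-to-embryo
biological variability beyond seed-to-seed tissue randomness, correlated
(non-isotropic) tracing error, segmentation failure modes, drift or
photobleaching in recoil traces, and any coupling between division events
and local mechanics. Tests that pass on synthetic data therefore establish
the correctness and power of the *analysis chain* under its stated
assumptions, not the biological fidelity of those assumptions.

# Numerical choices

* Relaxation tolerance $10^{-6}$ on the max per-vertex gradient norm;
  L-BFGS-B restarts until reached (a warning reports the final norm
  otherwise).
* Zero-stress tolerance $10^{-4}$ on area-weighted mean $P_\mathrm{eff}$.
* T1 threshold 0.05 mean edge lengths, reopening at 1.5 times threshold.
* Eigen-gap tolerance $10^{-6}$ (relative) for undefined axes; degenerate
  polygons and non-simple tracings are rejected with the offending cell
  named.
* Ties in the sweep argmin go to the smaller increment (parsimony).
* All angles are degrees in files and user-facing tables; radians are used
  internally.
* Every stochastic step draws from an explicitly seeded local RNG stream
  and restores the caller's RNG state.

# Problem sizes used in the shipped checks

The package's own test battery runs the full chain at the default study
conditions — 400-cell tissues, 19-cell cluster, grid 0-0.20 in 0.01 steps, 8
pseudo-embryos and 8 simulation seeds per grid point — for the parameter-recovery
checks at true increments 0.05, 0.09 and 0.15, and smaller meshes (25-100
cells) for unit-level mechanics checks. These sizes hold the sampling error
of the summed Wasserstein distance near its floor while keeping a complete
run in minutes on a laptop; larger tissues sharpen the 7+ band but do not
change any conclusion in our experience.

# Known limitations

* The simulator is quasi-static: no division, apoptosis, extrusion or
  active junctional remodelling beyond T1 swaps; it addresses shape and
  stress patterning only.
* Only the isotropic stress component is reported; the full (deviatoric)
  cell stress tensor is not exposed.
* The inference is a grid-search distance minimisation, not a likelihood;
  it inherits the grid resolution (0.01) as its precision floor. With five
  embryos and five seeds per grid point the recovered increment scatters
  by one to two grid steps around the truth (tissue-to-tissue variability
  of the orientation response dominates); eight and eight bring the
  scatter inside one to two steps reliably.
* Periodic boundary conditions remove free edges but impose the box's
  square symmetry on the far field; cells more than ~10 rings from the
  cluster in a 400-cell tissue wrap around and should not be
  over-interpreted.
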