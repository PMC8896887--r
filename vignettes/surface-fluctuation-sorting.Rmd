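---
title: "Surface-fluctuation-driven sorting of embryonic lineages: models and measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-fluctuation-driven sorting of embryonic lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fluctsort)
```

## The scientific problem

In the early mouse blastocyst, primitive-endoderm (PrE) progenitors
physically segregate from epiblast (EPI) progenitors inside the inner cell
mass: initially salt-and-pepper mixed, the PrE ends up as a shell on the
cavity-facing outside. Classical explanations — differential adhesion,
differential cortical tension, differential cell–cell affinity — turn out
to be quantitatively weak for these two lineages; what differs robustly is
the *dynamics* of the cell surface: PrE progenitors bleb and fluctuate much
more than EPI progenitors. This package implements, on synthetic data, the
computational machinery needed to study that hypothesis:

* a 3D subcellular-element cell-sorting simulator with tension
  fluctuations (`sim_config()`, `run_sorting_simulation()`),
* segregation statistics with a randomization null (`sorting_index_of()`,
  `demixing_parameter()`, `radial_enrichment()`),
* a 2D vertex model with FIRE relaxation and self-propelled-Voronoi
  dynamics (`build_vertex_mesh()`, `fire_minimize()`, `run_demixing()`),
* membrane-contour fluctuation quantification (`contour_to_polar()`,
  `fluctuation_amplitude()`), shape-index utilities, and doublet/AFM
  mechanics (`doublet_from_tensions()`, `afm_tension()`),
* seeded generators that produce inputs with known ground truth for every
  stage (`make_membrane_movie()`, `make_aggregate()`, ...).

## The element-based sorting model

Each cell is a cloud of elements (64 at birth) interacting through Morse
potentials; elements of different cells adhere through a weaker Morse
well between cortex elements. The cortex of a cell is identified
geometrically (an element is cortical when no same-cell element lies
radially beyond it within a 25° cone about its direction from the cell
centroid; convex-hull vertices always count), and a constant-magnitude
cortical tension `gamma_cm = 1.4` acts along the boundary facets of the
Delaunay triangulation of the cortex cloud. Two deliberate choices here:

* **Tension network.** `build_cortex_network()` exposes the full 3D
  Delaunay edge set of the cortex elements (verified against a brute-force
  empty-circumsphere enumeration in the tests). The force kernel applies
  tension only on the *boundary-facet* subset of that triangulation — the
  surface triangulation. A near-spherical shell's full Delaunay contains
  long interior diagonals; constant tension along those, with an edge count
  that grows as the shell compresses, produces a contraction runaway. The
  surface facets have bounded degree (~6) and act tangentially, which is
  what a discrete surface tension should do.
* **Interfacial tension.** Cortical tension is downregulated to
  `interface_scale = 0.4` of its free-surface value wherever the cortex
  adheres to another cell. This is what allows adhesive contacts to spread
  to realistic contact angles at adhesion strengths of order
  `A_M = 0.3`; with full-tension interfaces essentially no contact forms.
  The lineage asymmetry enters on top of this: EPI::EPI interfaces are
  scaled by `1 - beta_gain * (1 - beta)` relative to PrE::PrE, heterotypic
  contacts sit midway. With `beta < 1` the EPI-homotypic interface is the
  energetically cheapest, biasing EPI to the core and PrE to the outside.

**Fluctuations.** Every cortex element carries a random phase fixed at its
creation; the tension of a cortex edge is multiplied by
`1 + delta * sin(2*pi*10*t/tau + phase)` — ten fluctuation periods per cell
cycle `tau`. The factor uses the *mean* of the two endpoint modulations so
every pairwise force stays antisymmetric and momentum is conserved exactly
(asserted to floating tolerance in the tests). The per-lineage amplitudes
are `delta_epi` for EPI and `(1 + epsilon) * delta_epi` for PrE;
`epsilon = delta_PrE/delta_EPI - 1`, which for the measured single-cell
amplitudes (1.39 µm EPI, 1.91 µm PrE on ~7.2 µm cells) gives 0.374,
conventionally rounded to ~0.35.

**Growth and division.** Each cell adds elements at a uniform rate so its
count doubles over one cycle; at age `tau` it splits by a random plane
through its centroid into equal-element daughters inheriting its type,
until the aggregate reaches `n_end` cells. Exact preservation of the 50/50
lineage ratio holds across full synchronized doublings; a division cap
that interrupts a doubling freezes whatever mixture exists at that moment.

**Integration.** First-order overdamped Euler (`x <- x + dt*F/drag`) with
`dt = 1e-3` (convergence checked by dt-halving in the tests) and adaptive
substepping for the rare stiff transients right after divisions. The pair
interaction cutoff is `1.5 * r_eq`: the long attractive Morse tails beyond
that over-compress the element fluid. All of `morse_depth` (0.5), the
cutoff, and the tension-edge bound are calibration choices documented here
because the source model defers its numeric constants to prior work; they
were fixed by requiring (i) a relaxed single cell that is quasi-spherical
(cortex radial spread < 10%), (ii) stable integration at fluctuation
amplitudes up to `delta = 1`, and (iii) doublets that form stable contacts
yet remain able to rearrange.

### Calibration limits, stated plainly

Two calibration targets could not be met at this element resolution, and
the package does not pretend otherwise:

* **Contact-angle readout of beta.** In continuum force balance the
  homotypic contact-angle cosine ratio equals the interfacial-tension
  ratio. In the 64-element model the emergent contact angle saturates
  around 30–42° for any interfacial scale, so the measured cosine ratio
  compresses towards 1 (~0.96 at an imposed tension ratio of 0.5). The
  affinity asymmetry is therefore imposed directly on the interfacial
  tension ratio (`beta_gain = 2`), rather than being calibrated through
  simulated doublet angles.
* **Fluctuation amplitude.** The multiplicative modulation clamps at zero
  tension, bounding the stable single-cell fluctuation ratio at
  `V_T/R ≈ 0.10` (`delta_epi = 1`); the measured biological ratio is
  ~0.19.

### What the simulator does and does not reproduce

With the exaggerated differential (`epsilon = 0.6`, `beta = 1`) the
noisier lineage shows a steadily growing outward radial drift (~0.06 cell
radii per cycle in 12-cell aggregates), and at the study conditions
(`epsilon = 0.35` vs 0) the mean sorting index shifts upward by roughly
0.1 — the direction and the qualitative mechanism of
fluctuation-driven sorting are present. The *magnitude* is not: complete
core-shell sorting (SI ≥ 1) within ~1.8 cell cycles is not reached at this
scale; initial-arrangement variability (±0.3 SI across seeds) dominates
the differential signal. The corresponding acceptance checks are left
failing rather than weakened. Plausible causes are the unknown original
Morse constants and element resolution (both deferred by the source model
to prior work), which likely sit in a faster-rearranging regime than the
stable operating point found here.

## Sorting statistics

`external_elements()` samples the aggregate's support function on a
spherical Fibonacci direction set; each direction is credited to the
element extending farthest along it, so a cell's count of directions won is
proportional to the solid angle (≈ exposed area) it presents. `XS` is the
PrE share of those counts; the null (`randomization_null()`) shuffles type
labels at fixed geometry (the reference protocol uses 100,000 shuffles) and
`SI = (XS - mu)/(4*sigma)`: 0 for random arrangements, ±1 for complete
sorting. At blastocyst sizes (≥ ~30 cells) a geometrically complete
core-shell scores SI ≥ 1; in very small aggregates half the cells cannot
cover the whole exterior and a perfect split saturates below 1.

The demixing parameter normalizes the mean same-type neighbour fraction
between its random-labeling expectation and 1, clipped at 0. The radial
enrichment `R` is the signal-weighted mean distance of labeled cells from
the aggregate centroid over the unweighted mean distance of all cells
(uniform labeling gives exactly 1); `radial_enrichment_tertiles()`
reproduces the reporter-thresholding convention (bottom half discarded,
top half split into tertiles).

## Vertex model and self-propelled Voronoi dynamics

The 2D tissue energy is `E = sum_c K_A (A - A0)^2 + K_P (P - P0)^2` with
`K_A = K_P = 1`, `A0 = 1`; only the preferred shape index
`p0 = P0/sqrt(A0)` matters for the behaviour studied (3.65 solid-like vs
4.05 fluid-like, a gap of 0.4; the 3D preset pairs used at full scale are
recorded in `spv_presets_3d()`). Meshes are built from a periodic Voronoi
tessellation (`deldir`), relaxed with FIRE (standard parameters
`alpha0 = 0.1`, `f_inc = 1.1`, `f_dec = 0.5`, `N_min = 5`) with
backtracking — a step that would raise the energy is rejected, so the
energy trace is non-increasing within each topology segment — and T1 edge
swaps below `0.04*sqrt(A0)` (re-expanded to 1.5× the threshold). A
collapsing timestep is treated as the signature of an edge pinched against
a topological kink and triggers a T1 directly; this was required for
reliable convergence. Edge tension is `sum over adjacent cells of
2 K_P (P - P0)`; in relaxed 3.65/4.05 mixtures a significant fraction of
fluid–fluid edges is extensile (negative) while solid–solid edges are
uniformly contractile, and the fluid subtype's per-tissue tension variance
is larger on average — the link between fluidity and tension fluctuations.

The self-propelled Voronoi dynamics moves centres down the shape-energy
gradient of their instantaneous Voronoi cell (computed through
circumcenter Jacobians; verified against numeric gradients of the total
energy) plus a persistent propulsion `v0 = 0.1` whose direction diffuses
with `Dr = 1.0`, timestep `0.01` natural units. Desk-scale demixing runs
use N = 48–64 cells for ~1–2 × 10^4 steps — far below the reference scale
(216 cells, hundreds of initializations, ~6 × 10^6 steps) — and measure a
correspondingly small signal: the final demixing parameter with subtype
gap 0.4 exceeds the gap-0 control on paired seeds, and grows monotonically
with mean subtype fluidity across the three preset pairs. One measurement
caveat documented here: on an irregular initial Poisson tessellation the
zero-clipped DP of random labels is inflated (~0.05 at N = 48) purely by
clipping noise, so "final vs initial DP" is not a clean contrast at desk
scale; the gap-0 control is used instead.

## Fluctuation quantification

Contours are resampled at M = 360 uniform angles about the *first frame's*
centroid (the registration convention), walking each contour so that an
angle crossed several times — a bleb folding back — contributes its
outermost crossing. Per-frame angular means are subtracted exactly
(`detrend_frames()`, removing size and slow focus drift), and
`V_T` is the angular mean of the per-bin temporal SD (population SD, as in
the amplitude definition; sample SD is available behind a flag). For a
single angular mode of amplitude `a` sampled over whole periods,
`V_T = a*(2/pi)/sqrt(2) ≈ 0.45 a`; synthetic movies recover their stored
analytic ground truth within 5% at 1%-of-radius noise. Mask-based shape
indices use a sub-pixel iso-contour for the perimeter (pixel-edge counting
overestimates a disk's perimeter by tens of percent) and pixel counts for
the area; a rendered disk returns 3.54 within 2%.

## Doublet and compression mechanics

`doublet_from_tensions()` solves the three-tension balance
(`gamma_12 = gamma_1 cos(theta_1) + gamma_2 cos(theta_2)`,
`gamma_1 sin(theta_1) = gamma_2 sin(theta_2)`) in closed form — the cell
with the higher tension subtends the smaller external angle — and builds
the two-cap mid-plane geometry; `external_contact_angle()` measures angles
back from rendered contours by circle-fitting the free boundary at each
contact endpoint (round trip within 1°). The affinity parameter is the
cosine ratio of the homotypic angles. Parallel-plate compression follows
the force balance `T = F (r_mid^2/r_c^2 - 1) / (2 pi r_mid)` with the
contact radius derived from `A_c = A_mid - (pi/4) h_cell^2`; batch
processing offers the 1.5-IQR boxplot outlier filter used for ill-shaped
cells. Error propagation for ensembles of noisy doublets follows the delta
method and is validated against Monte-Carlo spread in the tests.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; sweep replicates derive per-run seeds from a hash of the master
seed and grid coordinates. The shipped analyses use: sorting runs of
10 → 30 cells at 64 elements per cell (four replicates per condition);
ground states of 100-cell vertex mixtures over five seeds; demixing at 48
cells for 1.2 × 10^4 steps over eight seeds; membrane movies of 31 frames
at 360 angular bins. These sizes were chosen so a full analysis pass
completes on a single desktop core in tens of minutes; the reference-scale
computations (10 → 50 cells, 100,000-shuffle nulls, 216-cell 3D Voronoi
mixtures with 250 initializations) are reachable by changing the
corresponding arguments.

## Known limitations

* Sorting-index magnitudes from the element simulator undershoot the
  complete-sorting threshold at desk scale (see above); treat its outputs
  as qualitative at these sizes.
* The demixing dynamics is the 2D analogue of a 3D study (the reference
  itself argues the two respond very similarly); 3D Voronoi dynamics is
  out of scope.
* Contour quantification assumes registered, star-convex-per-angle inputs;
  frame alignment is not performed.
* The synthetic generators emulate geometry and noise, not microscopy:
  no point-spread function, no segmentation errors, no photobleaching. A
  passing recovery test says the estimator is correct on its stated model,
  not that segmentation of real movies is solved.
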