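---
title: "Modelling the shoot apical meristem section with subcellular elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the shoot apical meristem section with subcellular elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samsce)
```

## The model

`samsce` simulates a longitudinal section of the *Arabidopsis thaliana*
shoot apical meristem (SAM) with a subcellular-element (SCE) model. Each
cell $i$ is a closed ring of $N_i$ wall nodes enclosing $M_i$ cytoplasm
nodes. Nodes move by overdamped (viscosity-dominated) first-order dynamics:
for a wall node $W_i^j$,

$$\eta_i \frac{d W_i^j}{dt} =
  -\sum_{k=1}^{M_i}\nabla E_{\mathrm{Turg}}(W_i^j, C_i^k)
  -\sum_{k=j\pm1}\nabla E_{\mathrm{Ext}}(W_i^k, W_i^j)
  -\nabla E_{\mathrm{M.F.B.}}(W_i^j, W_i^{j\pm1})
  -\sum_{l\neq i}\sum_k \nabla E_{\mathrm{V.E.D.}}(W_i^j, W_l^k)
  -\sum_{\mathrm{adh}}\nabla E_{\mathrm{Adh}}
  + F_{\mathrm{Boundary}},$$

and for a cytoplasm node $C_i^j$ only the cytoplasmic-pressure and turgor
terms act. Two functional forms cover the six interactions: a soft-core
Morse potential $E(r) = U e^{-r/\xi} - V e^{-r/\gamma}$ (turgor: wall
against own cytoplasm; volume exclusion: wall against other cells' walls;
cytoplasmic pressure: cytoplasm against own cytoplasm) and harmonic
springs, linear in length for wall extensibility and cell–cell adhesion
and harmonic in the wall angle for microfibril bending stiffness. The
Morse form is finite at contact; when $U/\xi = V/\gamma$ its derivative
vanishes at $r = 0$, so the pair force is continuous through coincident
nodes. `potential_params()` warns whenever a Morse block violates this
constraint.

Integration is explicit forward Euler with $\Delta t = 0.4\,$s of
represented time. The printed equations of motion contain deterministic
forces only, so the dynamics are implemented as a deterministic overdamped
gradient flow; stochasticity enters the model exclusively through the
discrete growth and division rules. Stability is guarded by a non-finite
position check that halts a run and names the offending node. The damping
$\eta_i$ is per cell and is multiplied by 10 in the bottom tissue row,
which represents the interface with the stiffer differentiated tissue
below the shoot apex; the non-dividing flank columns provide lateral
confinement passively.

### Units

Lengths are µm, forces µN, energies µN·µm, pressure MPa (1 MPa·µm² =
1 µN), damping µN·s/µm; time is seconds internally and hours in all
reported outputs.

## Boundary tension

The tunica of the SAM is under tension from the tissue that the section
boundary cuts away. Treating the meristem as a pressurized shell of
radius $r_{Ex}$, out-of-plane cell width $w$ and pressure $P_0$ gives the
total force

$$|F_{\mathrm{Boundary}}| = \frac{r_{Ex}}{2}\, w\, P_0 ,$$

with the calibrated geometry $r_{Ex} = 80.1\,$µm and $w = 7.09\,$µm and
the literature pressure range $P_0 \in [0.66, 0.98]$ MPa, i.e. totals
between 190 and 280 µN. The named conditions are free (0), low (190),
average (235), high (280) and 2x (560 µN). The total is split equally
over the flagged boundary nodes — the outward-facing wall nodes of L1/L2
cells in the left and right edge bands.

The *direction* of the pull is a modelling choice of this package (the
original construction is not published with the main text): each flagged
node is pulled along the normalized blend of (a) the tangent of the
circle of radius $r_{Ex}$ anchored at the current apex, oriented away
from the apex — generating in-plane tension — and (b) a radial correction
proportional to the node's signed distance from that circle, restoring
the target curvature. The blend weight (`direction_blend`, default 0.5)
is a first-class configuration parameter so the rule can be swapped.
Nodes lying exactly on the target circle are pulled purely tangentially.

## Signals

WUS and CK concentrations are static exponential gradients
$[S] = S_0 e^{-\mu_S r}$ around point signal centres on the apex axis,
evaluated at each cell's centroid; L1 and L2 keep CK $= 0$ (no
receptors). The centre depths are expressed in mean cell diameters below
the apex (defaults: WUS 2, CK 3.5 — the WUS centre shallower than the CK
centre), and the centres are re-placed whenever the apex has moved by
more than one mean cell diameter. The numeric gradient constants
(peaks 1, decay 0.10 and 0.06 µm⁻¹) are package placeholders: the
calibrated values are not published with the main text, and the
configuration flags them as such.

WUS shortens the cell cycle through the bounded linear map
`cycle_hours = clamp(h_max − s·wus, h_min, h_max)` with defaults
h_min = 20 h, h_max = 60 h and s = 40 per concentration unit, chosen so
that a 40 h run represents roughly one division per cell. WUS and CK also
weight the anticlinal vs periclinal bias of in-plane growth and of
basal-corpus division planes through the placeholder linear weights
`anti = 0.5 + wus`, `peri = 0.5 + ck`.

## Growth, polarization and division

Cycle progress advances as $dt/\text{cycle}(wus)$; each crossing of a
multiple of `1/nodes_per_cycle` inserts a cytoplasm node near the
centroid (with deterministic per-cell jitter) unless the cell has reached
its terminal area. The added cytoplasm inflates the cell through the
turgor potential; wall edges stretched beyond
$(1+\text{threshold})\,l_{eq}$ are bisected at their midpoints.

In the P3D variant a cell's growth direction is polarized out of the
section plane with the calibrated zone/layer probabilities

| zone | tunica | apical corpus | basal corpus |
|---|---|---|---|
| central | 47.4% | 17.8% | 10.5% |
| peripheral | 43.4% | 29.0% | 18.2% |

sampled at initialization and for both daughters at every division. The
2D variant is *defined* as the P3D variant with this table forced to
zero, which the test suite verifies bit-for-bit. Out-of-plane cells grow
isotropically (uniform wall stiffness) with a target section area reduced
by the factor 0.75 (only their minor axis stays in the section); when
they divide, the second daughter leaves the plane: no new cell appears
and the mother footprint keeps the reduced cytoplasm content. In-plane
cells soften the wall edges within 45° of their preferred expansion axis
(radial for anticlinal, tangential for periclinal) by the anisotropy
factor (default 0.3), so they elongate that way.

Division planes: tunica (L1/L2) cells always divide anticlinally,
preserving the monolayers; apical-corpus cells divide through the
centroid perpendicular to the principal direction of wall tension,
computed as the leading eigenvector of
$\sum_e t_e\, \hat d_e \otimes \hat d_e$ over the cell's wall edges with
$t_e = k_e (\ell_e - l_{eq})$; basal-corpus cells sample anticlinal vs
periclinal planes with the WUS/CK weights; boundary cells never divide.
In-plane execution splits the ring at the two plane crossings and inserts
two coincident chains of new wall nodes (one per daughter, mutually
adhered, nodes at the spring rest length); cytoplasm nodes partition by
side; both daughters restart their cycle and resample polarization.
Degenerate cases (plane not crossing exactly two edges, cells below the
minimum area) defer the division rather than corrupting the topology.

Zone labels are positional: central zone within 4 mean cell diameters of
the apex axis (the eight-cell-diameter window), re-evaluated at every
division. L1/L2 labels are clonal; the apical/basal corpus split is
positional at the configurable mid-depth of the corpus.

## Randomness

Every stochastic decision draws from a stateless counter-based stream —
a murmur-style integer hash of (seed, cell id, purpose, counter). There
is no global random state: results are independent of cell iteration
order, streams are unaffected by other cells' draws, and the 2D variant
consumes draws identically to P3D-with-zeroed-table, which is what makes
the bit-identity above hold by construction rather than by accident.
Replicate seeds in experiments derive from the base seed through the same
hash.

## Adhesion and neighbour searches

Nearby wall nodes of adjacent cells adhere. The pairing rule is not
fixed by the model equations, so this package uses the simplest
symmetric choice:
candidate pairs within the cutoff (default 1.6 µm) are accepted greedily
by ascending distance, at most one partner per node per neighbouring
cell, re-evaluated every 25 steps (also the volume-exclusion
neighbour-list cadence; cutoff `3·max(ξ,γ)` of the volume-exclusion
Morse block, beyond which the exponentially decaying force is truncated).
Candidate search uses a uniform grid with cell size equal to the cutoff.

## Parameter defaults are package calibration

The numeric coefficients of the six potentials are not published with the
main text. The shipped defaults were chosen once, by the stated rule that
an isolated generated cell must relax to a round profile of realistic
size (5–7 µm across), and then left alone. Two further considerations
shaped them:

* **Growth responsiveness** — the turgor and pressure ranges (ξ = 1.2/1.0
  µm) are short relative to the cell radius, so the wall rests just
  outside the cytoplasm cloud and the relaxed area grows with cytoplasm
  count (the growth mechanism of the model).
* **Elastic stiffness against the boundary load** — the boundary-force
  magnitudes (190–560 µN) are fixed data, so the internal force scale
  must be large enough for the tunica to carry them elastically. All
  force constants and the damping share one overall scale; multiplying
  both leaves every equilibrium and trajectory of the free tissue
  unchanged while making the fixed external load a proportionally smaller
  perturbation. The defaults (wall stiffness 600 µN/µm, η = 2000 µN·s/µm)
  put tunica strains under the calibrated loads at the few-percent level;
  with a much softer scale the tissue creeps indefinitely under tension.

Defaults: turgor U = 240, V = 120, ξ = 1.2, γ = 0.6; cytoplasmic pressure
120/60/1.0/0.5; volume exclusion 240/120/1.2/0.6; wall springs k = 600
µN/µm, l_eq = 1 µm; adhesion k = 240 µN/µm, l_eq = 0.5 µm; bending
k = 10 µN·µm/rad², θ_eq = π; η = 2000 µN·s/µm (×10 bottom row). All
satisfy U/ξ = V/γ.

## The synthetic initial tissue

`generate_initial_tissue()` is a documented stand-in for initial
conditions derived from segmented images (not available to this
package). It builds a dome section: interior cell columns under an
elliptical top profile, single-cell L1 and L2 monolayers, corpus rows
beneath, one bottom row with ×10 damping, and one non-dividing
boundary-cell column on each flank. Cells are inset wall rings (margin
0.25 µm, so adhesion spans the gap) with sunflower-pattern cytoplasm
nodes, cycle phases desynchronized uniformly over [0, 0.9], and the
tissue is relaxed mechanics-only for 500 steps before use so simulations
start near mechanical equilibrium. The mild widening `cell_aspect = 1.15`
compensates the lateral confinement of the flanks so relaxed corpus
cells start mechanically near-isotropic. The generator is validated by a
relaxation smoke test: no wall ring self-intersects after mechanics-only
relaxation.

What the generator does *not* emulate: real cell-size and shape
heterogeneity from images, primordia and the morphological SAM boundary,
curved initial walls, and any 3D geometry. Tests passing on generated
tissues therefore validate the model mechanics and bookkeeping, not
agreement with any particular imaged meristem.

## Metrics

* **Monolayer length** — the L1 cells are ordered into a left-to-right
  chain through the adhesion graph restricted to L1 (corner shortcuts
  that would bypass an in-layer cell are pruned so the healthy chain
  visits every cell) and consecutive centroid distances are summed. A
  structural break is flagged when the chain is disconnected or skips an
  L1 cell that left the layer line; the driver additionally flags jumps
  larger than twice the mean L1 cell diameter between snapshots —
  rerouting around an expelled cell adds at least one extra hop.
* **Relative curvature** — outer-face wall nodes of L1 cells in the
  apical cap (above the configurable half-height), coordinates rescaled
  so the full tissue width is 1, least-squares circle fit, reported as
  1/R. A semicircular cap gives 2; a flat top gives 0; the measure is
  scale- and translation-invariant.
* **Aspect ratio** — extent along the principal axis of the wall nodes
  divided by the perpendicular extent; ≥ 1, rotation-invariant.
* **Percent periclinal** — a division is periclinal when its plane normal
  is within 45° of the local radial (apex-to-centroid) direction; exact
  ties count as anticlinal.
* **Adhesion graph and centralities** — cells are nodes; edges join
  centroids sharing a Voronoi ridge (computed by half-plane clipping;
  degenerate zero-length ridges from cocircular centroids are dropped),
  pruned of edges longer than twice the mean cell diameter, which removes
  spurious adjacencies across concavities of the tissue outline. On this
  graph the package reports PageRank (damping 0.85, sums to 1) and the
  randomized-shortest-path betweenness family: with reference random-walk
  transitions $P^{ref}$, unit edge costs and inverse temperature β, the
  fundamental matrix $Z = (I - P^{ref} e^{-\beta})^{-1}$ yields expected
  visit counts $n_j(s,t) = Z_{sj}Z_{jt}/Z_{st} - Z_{tj}Z_{jt}/Z_{tt} +
  \delta_{jt}$ summed over all source–target pairs (RSPB), and expected
  absolute *net* edge flows accumulated onto nodes (RSPBN). β defaults
  to 1.0 (the value used for published distributions is not printed) and
  is recorded with every output; at large β the RSPB ordering converges
  to classical shortest-path betweenness, which the tests check against
  an independent implementation.

## Problem sizes used by the shipped tests

The full study design (30 replicates per arm, 40 simulated hours)
is out of desk scale; the package's own test suite runs the same
pipelines scaled down, as first-class scale knobs of the experiment
driver:

* topology/lineage invariants: one P3D run, 60 cells, 4 h, calibrated
  Table probabilities, shortened cycles (4–12 h);
* monolayer-disruption direction (2D-free vs P3D-free): 4 replicates per
  arm, 45 cells, 3 h, crowding-prone cycles (2–6 h);
* apical-corpus percent periclinal: pooled over both variants × two
  seeds, 66 cells, 4 h, cycles 4–12 h, with a ±25-point acceptance band
  around 50% reflecting the small division counts at this scale;
* relative-curvature variance vs tension: 4 replicates per arm at free
  vs 2x tension, 45 cells, 3 h.

At these sizes the qualitative directions reproduce: disruption is more
frequent in 2D-free than P3D-free, increasing tension tightens the
curvature distribution and decreases tunica aspect ratios, and the
percent-periclinal frequency sits near the middle of the band. The
quantitative values at full scale (e.g. 43% vs 7% disruption, variance
0.06 → 0.005) are not asserted by the tests.

## Known limitations

* The boundary-force direction rule, signal-gradient constants,
  WUS/CK bias maps, cycle-length calibration and initial-condition
  construction are package stand-ins for unpublished calibrations; all
  are exposed as configuration so they can be replaced.
* Small sections (tens of cells) feel their flanks: lateral confinement
  biases corpus wall tension vertically, which inflates the periclinal
  share of mechanically cued divisions relative to a full-width tissue.
* No wall viscoelasticity or plasticity beyond springs with node
  insertion; no thermal noise; no primordia; no dynamic signalling
  feedback; strictly 2D geometry with the P3D statistical treatment of
  out-of-plane behaviour.
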