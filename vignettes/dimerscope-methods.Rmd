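---
title: "Methods: dihedral PCA, free-energy landscapes and interface analysis in dimerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dihedral PCA, free-energy landscapes and interface analysis in dimerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscope)
```

dimerscope analyses molecular-dynamics trajectories of two-chain protein
complexes: collective backbone motions by dihedral-angle principal
component analysis, the organisation of the conformational ensemble into
free-energy basins, and the composition and persistence of the
inter-chain interface.  This vignette is the package's own account of the
underlying models, the numerical choices made, and what its validation on
synthetic data does and does not establish.

## Dihedral-angle PCA

A Cartesian PCA mixes internal motion with residual rigid-body motion and
depends on a superposition step.  Working in backbone dihedral angles
$\gamma_n$ ($\varphi$, $\psi$ per residue) removes both problems, but raw
angles live on a circle: a fluctuation across the $\pm\pi$ branch cut
would look like a huge variance.  dPCA therefore embeds each angle on the
unit circle,

$$q = (\cos\gamma_1, \sin\gamma_1, \ldots, \cos\gamma_N, \sin\gamma_N),$$

and performs an ordinary PCA on $q$: the covariance matrix of $q$ over
frames (mean-centred, unbiased $1/(T-1)$ normalisation) is diagonalised,
and the $k$-th principal component of a frame is the projection
$V_k = v^{(k)}\cdot(q - \langle q\rangle)$ onto the $k$-th eigenvector.
There is no mass weighting: dihedral coordinates carry no masses, and the
embedding is already dimensionless.  Covariance, not correlation, is used
— the embedded coordinates share a natural scale, and rescaling them
would distort the relative amplitude of motions.

Because each eigenvector has unit length, the paired squared entries

$$\Delta_n(k) = \left(v^{(k)}_{2n-1}\right)^2 + \left(v^{(k)}_{2n}\right)^2,
\qquad \sum_{n=1}^{N}\Delta_n(k) = 1,$$

read as the fraction of component $k$ carried by angle $n$
(`dpca_contributions()`).  This identity is exact, not approximate, and
is asserted to $10^{-9}$ in the test suite.

Numerical conventions:

* Eigenpairs are sorted by decreasing eigenvalue; tiny negative
  eigenvalues from the symmetric solver are clipped to zero.
* Each eigenvector's sign is fixed so that its largest-magnitude entry is
  positive.  Eigenvectors are only defined up to sign, and different
  linear-algebra backends make different choices; the convention makes
  projections reproducible.
* Component indices are 1-based (PC1, PC2, ...) in all user-facing
  output.
* Angles undefined at chain termini, and angles spanning a chain break
  (peptide C–N distance above 2.0 Å in any frame), are dropped with a
  warning rather than imputed; all bookkeeping refers to the retained
  angles.
* By default dihedrals of both chains enter one whole-dimer dPCA, so the
  components describe collective motions of the complex, while the
  contribution profile is still reported per chain through its labels.
  Passing a single chain to `compute_dihedrals()` gives the per-chain
  variant; which one a study wants depends on whether inter-chain
  concerted motion is the question, and the package deliberately leaves
  the choice to the caller with the whole-dimer default.

## Free-energy landscape

With $\rho(V_1,V_2)$ an estimate of the probability density over the
first two components, the free-energy surface is

$$\Delta G(V_1,V_2) = -k_BT\left[\ln\rho(V_1,V_2) - \ln\rho_{max}\right],$$

zero exactly at the most populated cell.  `fes_density()` estimates
$\rho$ by a 2-D histogram: 64×64 equal-width bins per axis over the
data's bounding box, padded by 1% so that boundary points fall strictly
inside (and the right-closed last bin causes no edge case).  Counts are
normalised by $T\times$ cell area; since only density *ratios* enter
$\Delta G$, the surface is invariant to any positive rescaling of $\rho$,
which the suite checks.  Empty cells are masked (`NA`) rather than given
an arbitrary large energy: the histogram says nothing about unsampled
regions.  Energies are reported in $k_BT$ units by default —
temperature-free and sufficient for comparing basins; an option converts
to kcal/mol with $k_B = 0.0019872$ kcal/(mol·K) at 310 K, the usual
physiological simulation temperature.

## Grid clustering

Isolated maxima of the density grid correspond to heavily populated
conformational clusters; cluster 1 is by definition the cluster holding
the global density maximum, the $\Delta G = 0$ region.  `find_clusters()`
implements this by steepest-ascent hill climbing on the 8-neighbourhood:
every populated cell follows the locally steepest uphill pointer to a
terminal maximum, and basins are ranked by raw peak density.

A raw finite-sample histogram, however, is not a smooth field.  With a
few thousand frames on a 64×64 grid, per-cell counts are small Poisson
variates, and near-flat basin tops sprout many spurious one-cell maxima;
a naive implementation fragments every basin.  Three regularisations fix
this without touching the reported $\Delta G$ values:

1. **Smoothing for seed detection.**  Climbing runs on a copy of the
   density smoothed with a small separable Gaussian kernel (default
   $\sigma = 1.5$ cells, reflected edges).  The free-energy surface
   itself is never smoothed.
2. **Climbing over the whole grid.**  A sparse histogram's basin is not a
   connected set of populated cells; paths may traverse empty cells,
   which never receive labels themselves.
3. **Prominence merging.**  A basin survives as a separate cluster only
   if its peak rises above its highest saddle to a higher-peaked basin by
   at least half its own height (default `prominence_fraction = 0.5`).
   Two genuinely separated basins have a near-zero saddle and always
   survive; shot-noise ripples on a shoulder never do.  This is the
   standard topological-persistence idea specialised to a grid.

Equal-valued adjacent maxima (plateaus, possible on raw counts with
smoothing disabled) are merged by connected components before anything
else.  Surviving maxima below 5% of the maximum density
(`min_density_fraction`) are folded into the nearest seed — they are
real but too thinly populated to report as clusters of their own.
`assign_frames()` labels each frame by its cell's cluster and refuses
points outside the grid, which can only happen when a cluster map is
reused on data it was not fitted to.

On two-state synthetic data (hidden-Markov von Mises dihedrals, see
below) this pipeline recovers the generating state of ≥95% of frames,
which is the package's end-to-end acceptance property for the whole
dPCA → histogram → clustering chain.

## Structure metrics

**Superposition.**  `superpose()` is the Kabsch algorithm via SVD of the
cross-covariance of the centred selections, with the determinant
correction that guarantees a *proper* rotation — a reflection is never
returned, even for pathological near-mirror pairs.  Selections of fewer
than three atoms, or collinear selections (second singular value
numerically zero), are rejected rather than silently under-determined.

**RMSD / RMSF.**  `rmsd_series()` superposes every frame onto a reference
frame over a selection (default: the α-carbons, the conventional choice
for backbone drift) and reports the RMSD over that same selection; the
reference frame scores 0 by construction.  `rmsf()` measures per-atom
fluctuation about the mean structure; since the mean depends on the
alignment and vice versa, frames are aligned to frame 1, then twice
re-aligned to the updated mean — two iterations are ample for the
fixed point at the precision of interest.  The fitting reference and
selection are explicit arguments: these are declared defaults, not
inferences, and studies that align differently can say so.

**Distance traces and hydrogen bonds.**  `distance_trace()` follows one
atom pair (specified as `chain:residue:atom`, e.g. `"A:226:HD21"`)
through the trajectory.  The hydrogen-bond criterion is distance-only —
no angle term — with two conventions depending on how the pair is
specified: 2.5 Å for a donor-hydrogen-to-acceptor pair and 3.5 Å for a
heavy donor-to-acceptor pair.  Both styles occur in practice (trajectory
snapshots with and without hydrogens), and each trace carries its own
default cutoff so `hbond_fraction()` needs no further input.

**SASA.**  `sasa()` is Shrake–Rupley quadrature: each atom's sphere of
radius $r_{vdW} + r_{probe}$ is sampled at `n_points` quasi-uniform
points, a point is accessible iff it lies outside every neighbour's
inflated sphere, and the atom's SASA is the accessible fraction times its
sphere area.  Radii are the Bondi set (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å), probe 1.4 Å, 960 points by default — NACCESS-comparable
settings.  Two determinism choices matter:

* The sphere points are a golden-spiral layout, not random: SASA is
  bit-reproducible and needs no seed.
* The quadrature runs in a canonical orientation of the selection (its
  principal axes, signs fixed by the third moment of the projections,
  which is itself rigid-motion invariant).  A fixed-in-space point layout
  would otherwise make SASA weakly orientation-dependent at the ~1%
  quadrature level; in the canonical frame, rigidly moved copies of a
  structure give identical results to floating-point accuracy.  Exactly
  symmetric point sets, whose principal axes or moments are degenerate,
  are the documented exception.  When several selections of the same
  frame must share a quadrature frame — as in buried-area differences —
  `canonicalize = FALSE` evaluates in the caller's frame.

A single atom's SASA at 960 points reproduces the analytic sphere area
$4\pi(r+r_{probe})^2$ within 2%, the resolution limit of the quadrature.

## Interface analysis

Published interface tables in this field typically come from external
servers with differing, partly opaque membership definitions.  dimerscope
instead declares one transparent criterion and tests it: a residue is an
interface residue of a snapshot when **any of its heavy atoms lies within
5.0 Å of the other chain**.  The buried interface area is computed from
the package's own SASA as $\frac12[S(A) + S(B) - S(AB)]$, evaluated in
one shared quadrature frame so that non-touching chains give exactly
zero.  Residue percentages are interface residues over chain residues.

Inter-chain contacts are typed with a fixed priority, so no pair carries
two kinds:

1. *hydrogen bond* — both atoms N/O/S, one a plausible donor and the
   other an acceptor, heavy-atom distance ≤ 3.5 Å; or a donor hydrogen
   within 2.5 Å of an acceptor.  Donor/acceptor status comes from a fixed
   per-residue atom table for the 20 amino acids plus the GlcNAc stand-in;
   no protonation inference is attempted.
2. *carbon–hydrogen* — one atom carbon, the other N/O, distance in
   (3.5, 3.8] Å.  The variant based on explicit C–H···O geometry is not
   implemented: it needs bond connectivity, which plain PDB atom records
   do not carry.
3. *van der Waals* — any other heavy-atom pair within 4.5 Å.

`hotspot_consensus()` defines a *hot spot* as a residue present in the
interface of every analysed snapshot — a chainwise set intersection,
monotonically non-increasing as snapshots are added.  Snapshot times are
a user input (`snapshot_report()` documents a seven-time series at 0–170
ns as the conventional example) and are matched to the nearest frame,
with a warning when the match is worse than half the frame spacing.
`glycan_interactions()` applies the same contact typing from glycan
residues to all protein residues and labels each contact intra- or
inter-chain relative to the glycosylated residue's own chain.
Interface energetics (per-residue pseudo-energies, binding free
energies) are out of scope; counts, types and areas stand in for them.

## The synthetic-data generator

No reference trajectories are distributed with studies of this kind, so
validation rests on generated data whose answers are known by
construction.  The generator emulates, at desk scale, the features the
analyses actually consume:

* **Metastable dihedral dynamics.**  One hidden-state Markov chain per
  trajectory (default: two states, symmetric 5% switching) drives both
  chains; each frame's angles are drawn from a von Mises distribution
  around the state's mean angles with concentration $\kappa$ (default
  20, i.e. ~13° angular noise).  The von Mises family is the natural
  circular analogue of the Gaussian and has an exact rejection sampler
  (Best–Fisher), stable from the uniform limit to $\kappa \sim 10^6$.
  Default state means are an α-helical and an extended basin, ~2.1 rad
  apart in mean circular distance.
* **Ideal-geometry chains.**  Backbones are rebuilt frame by frame from
  the sampled internal coordinates (bond lengths 1.46/1.53/1.33 Å, angles
  111°/117°/121°, ω fixed at 180°) by sequential NeRF placement, plus the
  carbonyl O, a Cβ on non-glycine residues, and named pseudo side-chain
  atoms (e.g. ND2, OG1, HD21) placed along the Cα→Cβ direction — enough
  geometry for contact and H-bond analyses without a rotamer library.
  Rebuilding dihedrals from the built coordinates recovers the inputs to
  $10^{-6}$ rad, the round-trip the test suite uses.
* **Controlled contacts.**  Chain B is rigidly placed per frame so each
  contact pair's distance equals its target plus Gaussian noise; a pair
  may be active only in chosen hidden states, in which case inactive
  frames drive it to a far distance (default 12 Å) — this is how
  persistent versus transient interface residues are engineered.  One
  pair is solved exactly by translation; several simultaneous targets are
  solved by BFGS least squares over the six rigid degrees of freedom,
  warm-started from the previous frame, with random-restart attempts and
  an error after bounded failures ("infeasible contact targets").
* **Glycan stand-in.**  A GlcNAc-like pseudo-residue (5 heavy atoms,
  residue name NAG) is attached to a designated asparagine's ND2 and
  rebuilt per frame in that residue's local frame, sufficient to exercise
  glycan-contact typing and span labelling.

The ground truth records the hidden-state sequence, per-frame interface
residue sets, their intersection (the persistent residues), and the
frames on which each contact pair satisfies its H-bond criterion.  Same
seed, same trajectory, bit for bit.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: there is no force field, no solvent, no
realistic side-chain packing, no thermodynamic consistency between the
Markov switching and any energy function, and the engineered interfaces
are geometrically clean in a way real ones are not.  The tests establish
that the *analyses* are correct (they recover what was put in); they say
nothing about the biology of any particular system.

## Problem sizes and defaults

The synthetic defaults mirror the conditions the analyses are meant for,
scaled to run in seconds: 171 frames at 1 ns/frame (a ~170 ns run sampled
coarsely), 24 residues per chain, two states at $\kappa = 20$, one
persistent Asn-ND2–Thr-OG1 contact at 3.0 Å and one glycan site near the
interface.  State-recovery checks use 2000 frames, where the 64×64
histogram is well populated; the interface consensus checks use 20–24
frames with per-frame snapshots.  Sequence-identity agreement with an
independent affine-gap DP oracle is checked exactly on sequences up to 30
residues; the identity convention (identical positions over alignment
columns, terminal gap overhangs excluded) is shared between the
implementation and the oracle, since published identity figures rarely
state their denominator — a ±0.5 percentage-point band is used when
comparing against printed values.

## Known limitations

* Interface membership is a single distance criterion; server-specific
  definitions (solvation-shell, Voronoi, or ΔSASA-based) will disagree at
  the margins.  A ΔSASA-based membership can be emulated by thresholding
  per-atom burial, but the distance rule is the tested default.
* Contact typing is geometric only; there are no energies and no angular
  hydrogen-bond term, so borderline contacts are typed by distance band
  alone.
* The trajectory reader handles multi-model PDB only; binary formats
  (DCD/XTC) must be converted upstream, or read by an external tool into
  the same `trajectory` contract.
* Grid clustering reports basins of the 2-D (V1, V2) marginal; states
  separated only in higher components will not be resolved — check the
  cumulative variance of the leading pair before trusting a 2-D
  landscape.
* SASA rigid-motion invariance relies on a canonical orientation that is
  undefined for exactly symmetric coordinate sets (vanishing principal
  moments); such inputs are deterministic but not invariant.
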