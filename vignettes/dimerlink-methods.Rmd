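---
title: "Methods: dynamical residue networks and dimer-interface analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamical residue networks and dimer-interface analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlink)
```

## Scope

`dimerlink` implements the dry-lab side of a dimer-interface engineering
study on a homodimeric lectin (the galectin-7 "back-to-back" homodimer is
the motivating system): dynamical residue-network analysis of
conformational ensembles, screening of interface point mutations from
predicted folding/binding free-energy tables, structural comparison of
crystal structures (superposition, solvent accessibility, interface area,
polar contacts, normalized B-factors), and the nonlinear measurement
models used to interpret the accompanying biophysics (pulsed-field-gradient
diffusion, dose-response EC50, thermal melts, monomer-dimer exchange).
Seeded synthetic generators with planted ground truth make every stage
testable without external structure downloads or instrument data.

## The dynamical residue network

Nodes are residues, each represented in every frame by the mass-weighted
center of its heavy atoms. Two residues are connected by an edge when any
pair of their heavy atoms lies within the contact cutoff (default 4.5 A)
in at least a minimum fraction of frames (default occupancy 0.75). The
edge weight is the dispersion of the center-center distance series
$r_{ij}$:

* `literal_var_over_mean` (default): $C_{ij} = \langle (r_{ij} -
  \langle r_{ij}\rangle)^2 \rangle / \langle r_{ij} \rangle$, i.e.
  variance over mean;
* `sqrt_var_over_mean`: the conventional coefficient of variation,
  sd over mean.

Both conventions are exposed because the two definitions circulate in the
dynamical-network literature; the default is the variance form, and the
convention used is recorded in the network object. Moments are population
moments (divisor $F$): the frames are a time average of one trajectory,
not a sample used to estimate a larger population. A mechanically stable
contact has a low weight, so the minimum-weight path between two sites is
the most persistent chain of contacts - the candidate allosteric route.
Because only internal distances enter, network construction needs no
prior superposition and is invariant under rigid motion of whole frames
(asserted in the tests).

Within a chain, residues separated by one position in sequence are
excluded from the edge set (`neighbor_exclusion = 1`, configurable to 0).
Covalently forced contacts have near-zero distance variance and would
otherwise dominate every optimal path; excluding nearest sequence
neighbours is standard practice in this kind of analysis.

Edge betweenness is computed with the Brandes algorithm (via igraph) with
edge length equal to the edge weight; counts are raw unordered pair
counts (no normalization) and co-optimal paths split counts equally.
"Critical" edges are those whose betweenness exceeds the mean of the edge
betweenness distribution by at least `sigma_k` standard deviations
(default 3). When the distribution is degenerate (zero spread) the
comparison is strict, so a perfectly uniform graph has no critical edges
rather than all of them. Optimal paths are reported with all co-optimal
alternatives (up to a cap, default 100), ordered lexicographically by
node label, so floating-point near-ties cannot silently change the
reported route across platforms.

The two distances in the model are deliberately distinct: the 4.5 A /
75% contact test uses the minimum heavy-atom distance (matching the
"any of its heavy atoms" edge definition), while $C_{ij}$ uses the
center-of-mass distance (matching the node definition).

## Ensembles and flexibility

Ensembles couple a topology to an $F \times 3A$ coordinate matrix and can
be read from multi-model PDB or CHARMM/NAMD-style DCD files (bio3d is the
reader; a minimal little-endian DCD writer is included because bio3d
reads but does not write the format). Frame selection follows
`first_frame` and `stride` in 1-based convention. Superposition is
mass-unweighted Kabsch on C-alpha atoms by default, because all reported
per-residue quantities (RMSF, PCA, B') are C-alpha quantities. No
equilibration discard is applied by default: synthetic ensembles need no
burn-in, and trajectory users can pass `first_frame`.

RMSF is $\sqrt{\langle |x_i - \langle x_i \rangle|^2 \rangle}$ on the
aligned ensemble. PCA is an eigendecomposition of the $3A \times 3A$
coordinate covariance with the sign fixed so each mode's
largest-magnitude component is positive. Crystallographic B-factors are
compared across structures as per-chain C-alpha z-scores (B'): the
default is the robust form $(B - \mathrm{median})/(1.4826\,\mathrm{MAD})$,
with the classic $(B - \mathrm{mean})/\mathrm{sd}$ variant available.
Normalization is per chain because the motivating analyses compare the
two protomers separately.

## Surface areas and interfaces

SASA is Shrake-Rupley sphere sampling over heavy atoms with a
deterministic golden-spiral point set (no random numbers) and a bundled
Chothia-style radius table (C 1.70, N 1.55, O 1.52, S 1.80 A; probe
1.4 A; 960 points by default). Each atom's point set is expressed in a
local frame built from its two nearest neighbours (ties broken by atom
index under a relative tolerance), so computed areas are exactly
invariant under rigid motion of the structure - a property the tests
assert at 1e-9. Relative accessibility divides residue SASA by bundled
theoretical maxima (Tien-style values). Interface residues are those
losing more than 10 percentage points of relative accessibility between
the isolated chain and the dimer - the prioritization filter for
interface mutations. Buried surface area is
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$, with the
interface area reported as half of it.

Polar contacts use distance-only criteria suited to ~2 A crystal
structures without hydrogens: N/O-N/O pairs within 3.5 A are hydrogen
bonds; side-chain N of Arg/Lys/His within 4.0 A of a side-chain
carboxylate O of Asp/Glu is a salt bridge.

Published RMSDs from molecular-graphics aligners typically include
outlier rejection, so `superpose()` offers an `iterative_reject` mode (up
to 5 cycles, discarding pairs deviating by more than twice the current
RMSD) and always reports the all-pairs value alongside.

## The mutation screen

Candidate point mutations arrive as a table of predicted folding
free-energy changes for the monomer and the dimer
($\Delta\Delta G_F$, positive = destabilizing) and optionally a predicted
binding penalty ($\Delta\Delta G_B$). Filters are applied in a fixed
order, and every record is annotated with the first filter it fails:

1. interface membership (positions from the accessibility screen);
2. $\Delta\Delta G_F(\mathrm{dimer}) - \Delta\Delta G_F(\mathrm{monomer})
   \ge 2$ kcal/mol - destabilize the dimer fold selectively;
3. no Gly/Pro/Cys replacements (secondary-structure breakers and
   disulfide formers);
4. charge preservation at pH 7 (Asp/Glu -1, Lys/Arg +1, His neutral -
   the protonation convention of the simulations);
5. $\Delta\Delta G_B \ge 4$ kcal/mol.

The predicates are independent, so the surviving set does not depend on
filter order (a property test shuffles the records), and tightening any
threshold can only shrink it. Survivors are ranked by
$\Delta\Delta G_B$ descending.

## Measurement models

**Diffusion decay.** The bipolar-pulse-pair LED attenuation
$I(g) = I(0)\exp[-D(\gamma g \delta)^2(\Delta - \delta/3 - \tau/2)]$ is
fitted by nonlinear least squares; the initial $D$ comes from the
log-linear slope. Defaults are the acquisition constants of the
motivating experiment: $\delta = 8.6$ ms (the instrument fixes
$\delta/2 = 4.3$ ms), $\Delta = 70$ ms, $\tau = 0.226$ ms, proton
$\gamma$, and gradients accepted in G/cm (x 0.01 to T/m) varied in 40
steps from 3.6 to 32.5 G/cm.

**Dose-response.** A four-parameter logistic on log10 concentration with
free bottom (activity is normalized to a reference condition but the
floor is not pinned). The EC50 interval is profile-based, falling back
to a Wald interval only if profiling fails. Nested shared-vs-separate
fits are compared with the extra sum-of-squares F-test,
$F = ((RSS_{sh} - RSS_{sep})/\Delta df)/(RSS_{sep}/df_{sep})$.

**Thermal melts.** Savitzky-Golay smoothing/differentiation (default
window 11 points, order 3) followed by quadratic interpolation of the
derivative extremum. A linear baseline has no interior extremum and is
rejected rather than silently returning an endpoint.

**Dimer exchange.** The titration of trace-labeled protomer with
unlabeled protein is modeled as mass-action monomer-dimer equilibrium
with equal homo/heterodimer affinity: the monomer concentration is the
positive root of $2M^2 + K_D M - K_D T = 0$ and the signal interpolates
between free and bound plateaus with the protomer dimer fraction. The
exchange functional form is not specified by the motivating study (only
fitted $K_D$ values are reported), so this documented mass-action model
is the package's choice. The fit runs on $\log K_D$, which keeps the
constant positive and the gradient finite near zero - a bounded fit on
the natural scale stalls on the $\sqrt{K_D}$ singularity at the
boundary.

All fitters are scale-equivariant in the response: rescaling the signal
rescales plateaus and leaves $D$, EC50, $T_m$ and $K_D$ unchanged.

## Synthetic data: what it emulates, and what it does not

`make_planted_ensemble()` builds a toy dimer - two zig-zag chains of
4-heavy-atom pseudo-residues crossing perpendicularly 3.4 A apart - and
realizes per-residue rigid Gaussian displacements: residues on a planted
route (along one chain, across the geometrically closest interface
contact, away down the other chain) fluctuate with a small target
distance CV (`cv_low`, default 0.02), all others with a large one
(`cv_high`, default 0.08, i.e. 4x contrast). The geometry guarantees a
margin band: no residue pair's static minimum heavy-atom distance falls
between 4.2 and 4.8 A, so the 4.5 A / 75% contact criterion cannot
straddle a pair, and the ground-truth cross-chain contact set is
unambiguous. The planted path stored in the truth record is the analytic
geodesic of the expected-weight graph (weights
$(\sigma_i^2 + \sigma_j^2)/d_{ij}$ over base contacts), which guards the
construction against accidental shortcuts for any chain length. The
generator refuses infeasible geometries instead of producing ambiguous
truth.

These ensembles emulate the statistical structure the network analysis
consumes - contact occupancies and distance-variance contrasts - not
molecular mechanics: there are no dihedral correlations, no anisotropic
or collective motions, and no solvent. Passing the recovery tests
demonstrates that the pipeline identifies a planted low-CV route at the
stated contrast and frame count; it does not certify the biological
pathways of any real trajectory.

`make_enm_ensemble()` draws Gaussian frames from the pseudo-inverse of a
Hookean (anisotropic-network) Hessian and emits analytic per-particle
variances, giving RMSF and PCA an independent closed-form oracle.
`make_ddg_table()` plants a known pass set with >= 0.5 kcal/mol margins
on every threshold and makes every other row violate a named criterion.
`make_curves()` evaluates each measurement model's closed form on its
standard grid (the diffusion gradient grid above; a duplicated 8-point
1-50 uM log series; a 20-80 C melt sampled every 1 C, the natural
acquisition density of a 1 C/min ramp; a 16-step 2-fold dilution from
50 uM over a 5 nM labeled floor) and adds seeded noise - multiplicative
Gaussian for the decay, additive Gaussian otherwise, stated in every
truth record.

## Numerical choices and degenerate inputs

* Alternate locations resolve to the highest occupancy, ties to the
  lexicographically first identifier; parse errors name the offending
  line.
* Elements are inferred from atom names when the element column is
  blank; within standard residues two-letter element candidates are not
  trusted ("CA" is the alpha carbon, not calcium).
* Zero-variance distance series give exactly zero edge weight; tiny
  negative variances from floating-point cancellation are clamped to 0.
* A flat diffusion decay fits $D = 0$ (a negative estimate is an error
  only when the implied attenuation is distinguishable from flat).
* Degenerate superposition selections (< 3 non-collinear atoms) and
  disconnected spring networks are rejected with explicit errors.
* The 4PL coverage and recovery simulations, the 20-ensemble path
  battery (F = 2000, 30 residues per chain), the 50-seed diffusion
  battery and the 10-experiment pooled-triplicate exchange battery are
  the problem sizes the package uses for its own validation; they run in
  well under a minute combined. Replicate pooling for the exchange assay
  reflects the triplicate design of the emulated experiment and is also
  statistically necessary: a single 16-point titration at 1% noise
  determines a 0.06 uM constant only to about +/-5% (one standard
  deviation), so single-series recovery checks at that tolerance would
  be dominated by estimator variance rather than implementation quality.

## Known limitations

* The published structure-derived benchmark values (the ~4 A
  Gly16 C-alpha distance across the interface and the four printed
  apo/holo RMSDs) require the deposited crystal structures, which cannot
  be redistributed with the package; the corresponding checks only run
  when a user supplies those files locally, and are reported as failing
  otherwise rather than silently skipped.
* The headline trajectory-derived quantities of the motivating study
  (the seven named interprotomer critical edges, the N62-to-H49 optimal
  path and its 0.27 weight) derive from microsecond-scale MD and are out
  of scope at desk scale; the network stage is validated against
  exhaustive-enumeration oracles and planted-truth ensembles instead.
* Hydrogen-bond and salt-bridge calls are distance-only (no angular
  term), appropriate for the resolution of the target structures but
  cruder than a full interaction calculator.
* The BANDIT-style robust B' normalization is implemented as a
  median/MAD z-score; the server's exact pipeline is not reproduced.
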