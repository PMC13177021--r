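---
title: "Energetic interaction networks of supercritical water: model and methods"
author: "scwnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic interaction networks of supercritical water: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwnet)
```

## The problem

Above its critical point (T_c = 647.096 K, P_c = 220.64 bar) water loses its
persistent hydrogen-bond network and organizes into transient clusters whose
size and connectivity fluctuate with temperature and pressure. This package
treats a configuration of water molecules as a graph — molecules as nodes,
energetically significant pair interactions as edges — and asks how the
topology of that graph (density, average degree, PageRank, the distribution
of connected-component sizes) responds to the thermodynamic state.

The molecular model is rigid four-site water of the TIP4P/2005 family: two
hydrogens carrying +q_H each, a Lennard-Jones center on the oxygen, and a
massless M site on the H–O–H bisector carrying −2q_H. Frames are read from
fixed-width GRO-dialect coordinate/velocity files (positions in nm,
velocities in nm/ps) or produced by the package's own synthetic generator.

Units are fixed project-wide: nm, ps, kJ/mol, K, bar, e, g/mol. With these
choices (g/mol)·(nm/ps)² = kJ/mol exactly, so kinetic energies never need a
conversion factor.

## The interaction criterion

A pair (i, j) is connected when

V_Coulomb^ij + V_LJ^ij + E_kin^ij + λ·4·E_kin^H < 0 (strictly),

that is, when the pair's attraction outweighs both its relative kinetic
energy and a thermal penalty for the four hydrogen atoms of the pair.

* **V_Coulomb^ij** — Coulomb's law summed over the nine charged-site pairs
  (H_a, M, H_b of each molecule), plain Euclidean distances.
* **V_LJ^ij** — the single O–O Lennard-Jones term,
  4ε[(σ/r)¹² − (σ/r)⁶]; no other site pair carries dispersion in this
  model.
* **E_kin^ij** — the kinetic energy of relative center-of-mass motion,
  ½μ|Δv_com|² with the two-body reduced mass μ = m_w/2. The model text
  defining this term fixes only "relative motion of the two molecules";
  the reduced-mass form is the standard decomposition of relative kinetic
  energy and is the package's documented choice (a ½m_w|Δv|² convention
  would simply rescale λ by a factor close to 2).
* **E_kin^H** — the kinetic energy of a hydrogen-mass particle at the
  most probable Maxwell–Boltzmann speed v_p = √(2k_BT/m_H), expressed per
  mole. The mass cancels algebraically and the value equals RT
  (5.60 kJ/mol at T = 1.04·647.096 K); the implementation goes through
  the velocity formula to keep the physical definition explicit, and the
  identity is asserted in the tests.
* **λ** — a phenomenological weight on the thermal penalty, absorbing
  constraints on hydrogen motion (the O–H covalent bond, cooperative
  hydrogen bonding) that the pair terms do not see. The calibrated
  default is 0.655. The factor 4 is the number of hydrogen atoms in a
  molecular pair and is deliberately not configurable.

The inequality is strict: a pair summing to exactly zero is not connected.
Because the penalty is positive, the edge set can only shrink as λ or the
temperature grows — a monotonicity that is property-tested and exploited
by the calibration code.

## Geometric filters

Two filters isolate genuinely pairwise, boundary-safe interactions, applied
in cheapest-first order (inner cube → candidate pre-screen → cylinder →
energy criterion; the order does not affect the result):

* **Concentric cube (default 85% of the box edge).** Pair distances are
  computed without minimum image, so molecules near the periodic boundary
  would see spurious across-the-box geometry. Only molecules whose center
  of mass lies in the concentric cube are nodes. Frames are wrapped
  rigidly — each molecule translated by a lattice vector so its center of
  mass lies in [0, L) — because wrapping sites independently would tear
  molecules apart at the boundary.
* **Interference cylinder (radius r_c = σ_OO = 0.3159 nm, the oxygen
  diameter).** A candidate pair is discarded if any third body's center
  of mass lies inside the finite cylinder whose axis joins the two
  centers of mass: axial projection strictly between the endpoints, radial
  distance ≤ r_c. The cylinder is capped — an infinite cylinder would
  discard pairs because of molecules sitting *behind* either partner —
  and the third-body test point is the center of mass, consistent with
  the axis definition. Both choices are configurable
  (`cylinderBlocked()` is exported on its own). Ions count as blocking
  third bodies by default (`ionsBlock = FALSE` disables this); water–ion
  pairs are never network edges.
* **Candidate pre-screen (default 0.8 nm COM–COM).** A cell-list distance
  cutoff applied before any energy is computed. At the calibrated λ and
  supercritical temperatures the thermal penalty (≈ 14.7 kJ/mol) is
  unreachable by the pair potential beyond ≈ 0.6 nm, so 0.8 nm is a
  conservative superset; the test suite checks that raising the cutoff
  never changes an edge set.

## Topology metrics and the power-law size model

With E edges over N nodes, network density is ρ = 2E/(N(N−1)) and the
average degree is ⟨k⟩ = 2E/N = ρ(N−1) (an identity the tests assert
exactly). Density is reported both over all nodes and over interacting
(degree ≥ 1) nodes; excluding monomers shrinks the denominator, which is
why the two variants can trend in opposite directions with temperature.
PageRank (damping 0.85, uniform teleportation, dangling nodes
redistributing uniformly) is computed on the undirected graph via igraph
and summarized as its mean over interacting nodes; the all-node mean is
trivially 1/N and is emitted only for completeness. The damping value is
a package default — the underlying algorithm's classical choice — since
the method description fixes no value.

Connected components are transient clusters; their size counts n_c(s)
(monomers included) are modelled by n_c(s) = A·s^b, fitted by ordinary
least squares of log n_c(s) on log s over sizes with positive counts.
A = exp(intercept) is the model's monomer count and b < 0 the decay
exponent. Raw counts are the default regression target (normalized
fractions change A, never b); a count-weighted variant is selectable.
The fit is exact on noiseless power-law data to 1e-10 and recovers the
exponent within 0.05 under 5% multiplicative noise (200 replicates,
fixed seed) — both frozen as tests.

## Calibrating λ

`calibrateLambda()` scores a λ grid (default 0–1 in steps of 0.001,
covering the calibrated 0.655 at its printed precision) against a
reference cluster-size distribution: for each λ the networks of all
supplied frames are rebuilt (geometry filters are λ-independent and
computed once), component-size counts pooled across frames, normalized to
fractions, and compared by MAE over the union of sizes (absent sizes count
as zero). λ* is the MAE argmin, ties resolved toward the smaller λ; RMSE
is reported alongside. MAE is the primary objective because the reference
comparison reports both and one must decide the argmin; distributions are
compared as fractions rather than counts so that the reference (typically
experimental, arbitrarily normalized) and the model pool are on one scale.

A degeneracy is worth knowing about: if no pair's base energy falls in the
window between two adjacent grid values, both λ give identical networks
and the tie rule picks the smaller. The synthetic dimer sweep
(`plantedClusterFrame()` with graded spacings) covers the threshold range
densely and pins λ* uniquely; the self-recovery property (reference
generated at λ₀ ⇒ λ* = λ₀ with MAE 0) is exercised in the tests at
several λ₀.

## Representative selection by PCA

*Frames.* Each frame is flattened to one row of 12 coordinates per
molecule (x, y, z of H_a, O, M, H_b — 102,528 columns for 8544
molecules), mean-centered across frames without per-column scaling (all
columns share units), and projected onto the smallest number of leading
principal components explaining ≥ 90% of the variance (minimum 2). The
representative frames are those closest to the origin of the projected
space — the mean of the distribution; ties go to the lower index. The
variance threshold and component floor are package defaults, stated here
because the method description fixes neither.

*Components.* Within one size/topology group (e.g. "3:Linear"),
components are described by four statistics: sum and population standard
deviation of their bond lengths (O–O distances of their edges) and mean
and population standard deviation of their edge interaction energies.
"Interaction energy" here is the pair potential V_Coulomb + V_LJ: the
kinetic terms describe instantaneous motion, not the bond, and are
excluded (configurable by building descriptors from a custom edge table).
These mixed-unit descriptors are z-scored, PCA-projected, and the
component nearest the origin is the group representative. Because all
components are retained in the projected space, PCA is an isometry and
the selection provably equals nearest-to-centroid in standardized
descriptor space — which is exactly how the tests check it.

## QTAIM classification

Bond-critical-point tables (atomic units throughout, no conversion) carry
ρ, ∇²ρ, the Lagrangian kinetic energy density G ≥ 0, the Hamiltonian
kinetic energy density K, and the potential energy density
V = −G − K; H = G + V = −K is the total energy density. A missing member
of {K, V} is derived from the identity; a supplied triple violating it
beyond 1e-8 is rejected.

Classification follows the sign conventions of the hydrogen-bond
literature: ∇²ρ > 0 with H > 0 is noncovalent (density depletion, kinetic
dominance), ∇²ρ > 0 with H < 0 partially covalent, ∇²ρ < 0 with H < 0
covalent. Exact zeros fall back to the −G/V ratio (> 1 noncovalent,
(0.5, 1] partially covalent, ≤ 0.5 covalent); with V < 0 the ratio
threshold 1 is algebraically the H = 0 boundary, so the two rules agree
where they overlap (property-tested). The combination ∇²ρ < 0 with H > 0
is physically inconsistent and is flagged rather than raised. Labels are
scale-invariant under a common positive rescaling of (G, K, V). All
thresholds sit in one place (`classifyBcp()`) for adjustment.

Cross-condition comparisons (`compareGroups()`) default to
Kruskal–Wallis — robust for the small per-condition samples typical of
BCP tables — with one-way ANOVA selectable; the test used is recorded in
the output and the significance threshold used in reporting is 0.05. The
sampling unit (per-frame metric, per-component property) is the caller's
choice; the function accepts any grouped numeric lists.

## The synthetic generator

`generateWaterFrame()` emulates a thermally agitated snapshot: oxygen
positions by rejection sampling with a minimum O–O separation, uniform
random rigid orientations (quaternion sampling), H/M sites from the rigid
geometry, and per-molecule COM velocities drawn from the
Maxwell–Boltzmann distribution at the requested temperature. Velocities
are rigid-body translations only — no rotational sampling — because only
COM velocities enter E_kin^ij; this is a documented limitation, not an
oversight. Equipartition of the sampled velocities (mean kinetic energy
(3/2)RT within 2% over 10⁴ molecules) is a frozen test.

`plantedClusterFrame()` builds ground-truth clusters: linear chains with
the donor O–H pointing at the next oxygen, successive molecules flipped
180° about the chain axis (the twist minimizing the pair potential,
≈ −21.4 kJ/mol at 0.28 nm spacing — comfortably below the criterion
threshold of ≈ −14.7 kJ/mol at λ = 0.655, T = 673 K), clusters separated
by more than the candidate cutoff and placed entirely inside the
retention cube. Per-cluster spacings may be graded to sweep pair energies
across the criterion threshold. What passing the planted-recovery tests
shows is that the pipeline's filters and criterion compose correctly —
not that the generator reproduces real supercritical structure: the
generator has no orientational correlations, no realistic radial
distribution, and no dynamics.

`syntheticBcpTable()` samples BCP records strictly inside each class's
defining region with the energy identity holding exactly, for classifier
round-trip tests.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the criterion; ties excluded.
* PageRank convergence 1e-10 (igraph/PRPACK); the tests compare against
  dense power iteration at 1e-8.
* Power-law fitting requires ≥ 2 distinct positive-count sizes; fewer is
  an error, not a guess.
* PCA on an all-identical frame cloud (zero total variance) returns the
  first n indices rather than dividing by zero.
* `curveAgreement()` refuses a constant observed curve (SS_tot = 0).
* Degenerate group comparisons (all values identical) return p = 1 with a
  warning instead of erroring inside the rank test.
* Empty frames, empty specs and empty networks propagate as empty
  objects, not errors, wherever a downstream empty result is meaningful.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
frames of 40–600 molecules (10⁴ for the equipartition check), planted
specs of a few dozen clusters, 200-replicate noise studies, and a
17-point λ grid on an 80-dimer sweep. These sizes were chosen so each
check isolates one property with comfortable statistical margin; nothing
in the methodology depends on system size beyond the usual graph-size
scalings.

## Known limitations

* No minimum-image pair construction: the concentric cube is the only
  supported boundary treatment. Edges never cross periodic faces.
* No triclinic boxes; multi-frame trajectory formats are read as
  concatenated single frames by the caller.
* Ions are geometric obstacles only; ion–water energetics are out of
  scope.
* E_kin^ij's reduced-mass convention and the cylinder's cap/COM choices
  are assumptions where the method description is silent; all are
  documented above and overridable.
* The synthetic generator is not a simulator: no forces, no integration,
  no thermostats, no rotational velocities.
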