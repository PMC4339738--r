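---
title: "Elastic-network normal modes and comparative flexibility: methods"
author: "flexcmp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network normal modes and comparative flexibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexcmp)
```

## The model

`flexcmp` models a protein as a network of beads, one per residue at the
C-alpha position, connected by harmonic springs. The interaction between
beads $i$ and $j$ is

$$U_{ij}(\mathbf{R}) = k(\lVert \mathbf{R}^0_{ij}\rVert)\,
 (\lVert \mathbf{R}_{ij}\rVert - \lVert \mathbf{R}^0_{ij}\rVert)^2,$$

where $\mathbf{R}^0_{ij}$ is the pair separation in the input structure and
the force constant depends on the reference distance $r$ (in nm):

$$k(r) = \begin{cases} a\,r - b, & r < d\\ c\,r^{-6}, & r \ge d \end{cases}$$

with defaults $a = 8.6\times10^5$ kJ mol$^{-1}$ nm$^{-3}$,
$b = 2.39\times10^5$ kJ mol$^{-1}$ nm$^{-2}$, $c = 128$ kJ mol$^{-1}$ nm$^4$
and $d = 0.4$ nm (`enm_params()`). Sequence-adjacent C-alpha pairs sit just
under 0.4 nm apart, so the linear branch gives them near-uniform stiff
springs, while all other pairs interact through the rapidly decaying
$r^{-6}$ branch. The boundary $r = d$ belongs to the long-range branch
($k(0.4) = 31250$). Every pair interacts — the decay itself provides
locality — though `build_hessian()` accepts an optional hard cutoff for very
large systems. These parameters were fitted once against an all-atom model
and transfer between proteins, so the package exposes them but does not
encourage refitting; per-protein parameterisation would have to lean on
crystallographic B-factors, a disputed proxy for thermal motion.

Because the potential is minimal at the input configuration only if no two
beads are anomalously close, `validate_min_distance()` rejects any structure
with a C-alpha pair closer than 0.278 nm (2.78 Å). The comparison is strict:
exactly 0.278 nm passes.

Internally all lengths are nm (the units of the force-field constants);
conversion from Å happens once, at the PDB boundary.

## Normal modes

`build_hessian()` assembles the analytic second derivative of
$U = \sum_{i<j} U_{ij}$ at the reference configuration: each pair
contributes $-2k\,\hat u \hat u^{\mathsf T}$ to its off-diagonal
$3\times3$ block ($\hat u$ the unit vector along the reference separation)
and the opposite to both diagonal blocks, so every row-block sums to zero
(translation invariance) and the matrix is positive semidefinite.

`compute_modes()` diagonalises the mass-weighted matrix
$M^{-1/2} H M^{-1/2}$, with per-residue masses from a standard average
residue-mass table (unknown residues get the table mean; a uniform-mass
scheme is available). Eigenvalues are squared vibrational frequencies in
model units (kJ mol$^{-1}$ nm$^{-2}$ Da$^{-1}$); only relative quantities
are ever reported, so no conversion to physical frequencies is made.

Rigid-body (trivial) modes are detected by a relative threshold,
$\lambda < 10^{-9}\lambda_{\max}$, rather than by assuming exactly six: a
connected three-dimensional network has six, a two-bead dimer five, and a
perfectly collinear chain of three or more beads has more than six because
bending perpendicular to the axis is soft at second order in a central-force
network. More than six near-zero modes raises a warning, escalated to an
error when the spring graph is disconnected. Single-structure analyses use
at most the 200 lowest-frequency non-trivial modes (`truncate_modes()`);
the full spectrum is used in the comparative track.

## Single-structure analyses

**Fluctuations.** The normalised mean-square displacement of atom $i$ is
$f_i \propto \sum_m \lambda_m^{-1}\lVert \mathbf d_{m,i}\rVert^2$ over the
retained modes, with $\mathbf d_m = M^{-1/2}\mathbf X_m$ the cartesian
displacements; values are normalised to sum to one (a max-to-one option
exists for visual comparison).

**Deformation energies.** The elastic energy a mode stores in pair $(i,j)$
is $k(r^0_{ij})(\hat u_{ij}\cdot(\mathbf a_{m,i}-\mathbf a_{m,j}))^2$,
split half to each partner, where
$\mathbf a_m = \mathbf d_m/\sqrt{\lambda_m}$ is the displacement at thermal
amplitude. Per-atom totals are then averaged over modes with
$1/\lambda$ weights and normalised to sum to one. The thermal amplitudes
matter: the pair-energy total of a *unit* mode is identically
$\lambda_m$, so weighting unit-mode energies by $1/\lambda$ alone would give
every mode — including the many spatially bland high-frequency ones — an
equal share and wash out localisation. Evaluating energies at thermal
amplitude keeps the soft modes, which dominate the actual motion, in charge
of where energy accumulates; on a two-domain dumbbell the linker then holds
several times the per-residue energy of the domain cores, the hinge
signature this profile exists to expose. Rigid-body input fields store no
energy and are reported as exact zeros rather than being normalised.

**Correlations.** `correlation_matrix()` computes
$$C_{ij} = \frac{\sum_m \lambda_m^{-1}\,\mathbf d_{m,i}\cdot\mathbf d_{m,j}}
{\left(\sum_m \lambda_m^{-1}\lVert\mathbf d_{m,i}\rVert^2\right)^{1/2}
 \left(\sum_m \lambda_m^{-1}\lVert\mathbf d_{m,j}\rVert^2\right)^{1/2}},$$
the expected inner product of displacements, in $[-1, 1]$ with unit
diagonal. `correlation_viewer_script()` renders the significant couplings as
red (positive) and blue (negative) distance objects on a cartoon in a PyMOL
script. Only pairs at least 0.8 nm apart are eligible, removing couplings
dominated by the stiff backbone springs; the threshold is a percentile of
$|C_{ij}|$ over eligible pairs — 95 below 200 atoms, 99.9 above 2000,
linearly interpolated in $N$ between (the two printed endpoints admit many
interpolations; linear in $N$ is the simplest). Percentile and threshold are
written as header comments, and a script is emitted even when one or no pair
passes.

**Overlap analysis.** Given a second conformation of the same protein,
`overlap_analysis()` superposes it onto the first by Kabsch least squares on
all C-alphas — removing rigid-body difference the modes cannot represent —
and projects the remaining difference $\Delta\mathbf R$ on each mode:
$O_m = (\mathbf d_m\cdot\Delta\mathbf R)^2 /
(\lVert\mathbf d_m\rVert^2\lVert\Delta\mathbf R\rVert^2)$, with cumulative
overlap $\mathrm{CO}_k = (\sum_{m\le k} O_m)^{1/2}$. Identical conformations
(RMSD below $10^{-6}$ nm after fitting) are rejected as degenerate input.

## Comparative analyses

**Alignment mapping.** The user supplies a gapped FASTA alignment (ideally
from a structural aligner) and one structure per record. `map_alignment()`
checks each record's ungapped sequence against its structure (`X` matches
anything) and collects the *conserved* columns — those with a residue in
every record. Conservation here means presence, not identity: the reduction
below needs coordinates in every structure, and demanding identity would
discard most columns of any interesting family.

**Effective Hessian.** Each structure's Hessian is reduced to its conserved
coordinates $a$ by the Schur complement
$\ddot{\mathbf H} = \mathbf H_{aa} -
\mathbf H_{ab}\mathbf H_{bb}^{-1}\mathbf H_{ab}^{\mathsf T}$,
the exact quadratic energy after minimising over the non-conserved
coordinates $b$ — so the discarded residues still shape the retained
dynamics. $\mathbf H_{bb}$ is solved directly; if singular (a disconnected
$b$ fragment), the Moore–Penrose pseudo-inverse is used with a warning. The
reduction preserves the six rigid-body zero modes of a connected system.

**Profiles on alignment columns.** Fluctuation and deformation profiles are
computed from each structure's *full* (unreduced) mode set over all
non-trivial modes and tabulated on alignment columns, with empty fields at
gaps so the per-structure columns line up; the reduction applies only to the
similarity measures.

**RMSIP.** The root mean squared inner product over the ten
lowest-frequency non-trivial modes of each reduced system,
$\mathrm{RMSIP} = (\tfrac1{10}\sum_{i,j\le10}(\mathbf X_i\cdot\mathbf
Y_j)^2)^{1/2}$ — a purely directional subspace overlap, blind to how energy
is distributed across those directions. If fewer than ten modes exist, all
available are used with a warning.

**Bhattacharyya coefficient.** Covariances
$\mathbf A \propto \sum_m \lambda_m^{-1}\hat{\mathbf d}_m\hat{\mathbf
d}_m^{\mathsf T}$ are built from the reduced modes and rank-reduced twice:
each protein keeps its $n$ lowest-frequency modes retaining 95% of its
variance (the $1/\lambda$ sum, i.e. the covariance trace) and is
trace-normalised; both are then projected on the $s$ leading eigenvectors of
their average retaining 75% of its trace. Then

$$\mathrm{BC} = \exp\!\Big(-\tfrac1{2s}\ln\big[\,
 |\tfrac12(\tilde{\mathbf A}+\tilde{\mathbf B})|\,
 (|\tilde{\mathbf A}||\tilde{\mathbf B}|)^{-1/2}\big]\Big),$$

evaluated through log-determinants of eigenvalues to avoid underflow. BC is
1 for identical ensembles and decreases as either the directions *or* the
energetic weights diverge — the property that lets it separate families
whose low-mode subspaces coincide but whose spectra differ, where RMSIP is
blind by construction.

**A common frame.** Mode vectors are directions in space, so comparing them
across structures is only meaningful after the structures share a frame.
`rmsip()` and `bhattacharyya()` therefore rotate the second system's mode
vectors into the first's frame using the Kabsch rotation of the conserved
coordinates before comparing (a `superpose` flag disables this for callers
who have pre-aligned coordinates). Without this step both measures would
change under an arbitrary rigid motion of one input file, which is physically
meaningless. Both measures use unit-normalised cartesian displacements by
default; a `mass_weighted` flag switches to the mass-weighted eigenvectors
(for uniform masses the two coincide).

**Clustering.** `similarity_matrix()` computes all pairs, attaches a
complete-linkage dendrogram on the distance $1 - \text{similarity}$, and
plots as a heat map (rows in input order, dendrogram on the periphery).

## Synthetic fixtures

`make_structure()`, `make_family()` and `make_open_closed_pair()` generate
seeded, self-contained inputs so every analysis is testable without
downloading structures:

* *helix* — ideal C-alpha helix (rise 0.15 nm, radius 0.23 nm, 100° per
  residue, ~0.38 nm spacing);
* *compact_blob* — a confined self-avoiding walk with 0.38 nm steps and a
  0.30 nm hard core, kept inside a ball sized for protein-like density;
* *two_domain_dumbbell* — two blobs joined by an extended helical 4-residue
  linker. The linker is deliberately non-collinear: a straight or planar
  linker bends or twists for free in a central-force network, producing a
  degenerate near-zero mode instead of a hinge;
* *family* — one base blob per family, copies perturbed by Gaussian
  coordinate noise (default σ = 0.02 nm, five copies per family, matching a
  "close homologs" regime), optionally with short deletions that become
  alignment gaps;
* *open/closed pair* — a dumbbell and a copy with one domain rotated 30°
  about a hinge axis through the linker.

These fixtures emulate the geometry and connectivity statistics of
coarse-grained proteins, not their chemistry: they are poly-alanine (uniform
masses), have no secondary-structure regularity beyond the helix fixture,
and their "families" differ by fold, not by sequence divergence. Tests
passing on them demonstrate the correctness of the machinery — force field,
eigenproblem, reduction, measures — on valid inputs of realistic size and
geometry; they do not demonstrate biological conclusions about real
families, which depend on real folds and alignments.

## Numerical choices

* Dense symmetric eigensolver (LAPACK via `eigen(symmetric = TRUE)`), full
  spectrum; exact at the problem sizes this package targets (up to a few
  thousand residues).
* Trivial-mode threshold $10^{-9}\lambda_{\max}$; escalation to an error
  only on a disconnected spring graph.
* Hessians and reduced Hessians are explicitly symmetrised
  ($\tfrac12(H + H^{\mathsf T})$) before diagonalisation to shed rounding
  asymmetry.
* Schur complement via a direct solve of $H_{bb}$; pseudo-inverse fallback
  with a warning when singular.
* BC determinants in log space from eigenvalues; a non-positive projected
  covariance raises an error naming the degeneracy instead of returning a
  silent `NaN`.
* Altloc ties resolve to the first conformer in file order; quantile type is
  R's default (type 7) for the viewer threshold.
* Degenerate inputs produce typed conditions (`flexcmp_parse_error`,
  `flexcmp_validation_error`, `flexcmp_mapping_error`) that the command-line
  wrapper maps to distinct exit codes (2/3/4).

The test suite exercises structures of 8–50 residues, families of 2 × 5
copies of 30 residues over 10 seeds, and ~25 random reduced-system pairs —
sizes chosen so the whole suite settles in seconds while every code path,
including the $O(N^2)$ all-pairs assembly and the double rank reduction,
runs on non-trivial inputs.

## Known limitations

* One model per PDB file (the first), C-alpha only; no mmCIF, no residue
  repair or renumbering, no fetching by PDB ID.
* The ENM sees shape only: ligands, chemistry and any modulation of
  dynamics not mediated by geometry are invisible (the adenylate-kinase
  style analyses work *because* ligand binding changes the backbone
  conformation).
* Eigenvalues are left in model units; absolute frequencies and
  thermodynamics are out of scope, as is any comparison to crystallographic
  B-factors.
* The alignment is taken as given; alignment quality directly limits the
  comparative measures, and no structural aligner is bundled.
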