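---
title: "Surface-based prediction of protein binding sites and interactions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based prediction of protein binding sites and interactions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfppi)
```

# The model

`surfppi` treats a protein as its molecular surface rather than as a residue
sequence or an atom graph. The premise is that whether two proteins interact
is decided by the chemistry and the shape of the patches through which they
would touch. The pipeline therefore has four stages:

1. **Surfacing.** Atoms from a PDB file become a signed Euclidean distance
   field $f(x) = \min_i\,(\lVert x - p_i\rVert - r_{\mathrm{vdw},i}) - r_p$
   on a regular grid ($r_p = 1.4$ Å probe), whose zero level set is
   triangulated by marching tetrahedra. Face windings are chosen so vertex
   normals point toward increasing $f$, i.e. outward.

2. **Chemical features.** Each surface point aggregates its $k$ nearest
   atoms ($k = 16$). An atom record carries its element one-hot over
   $\{C, N, O, S, H, \mathrm{other}\}$, Fourier distance features
   $\gamma(d) = (d, \cos d/2^0, \sin d/2^0, \dots, \cos d/2^F, \sin d/2^F)$
   with $F = 4$, the Kyte–Doolittle hydrophobicity of its residue rescaled to
   $[-1, 1]$ (division by 4.5), and a hydrogen-bond surrogate. The records
   are transformed by a small MLP, mean-pooled per point, and passed through
   one graph-convolution layer over the point k-NN graph.

3. **Geometric features.** The shape operator at a point is fitted by least
   squares from the $k$ nearest neighbours: relative positions and relative
   normals are projected onto the tangent plane, the $2\times 2$ differential
   $D$ of the normal field is solved for (ridge $10^{-8}$ when the projected
   neighbourhood is rank-deficient), symmetrised, and diagonalised. Its
   eigenvalues are the principal curvatures $k_1 \le k_2$ (Å$^{-1}$), fed to
   a two-layer MLP. The sign convention makes convex regions of an
   outward-oriented surface positive, so a sphere of radius $r$ gives
   $k_1 = k_2 = +1/r$; the analytic tests pin this convention.

4. **Radius convolution and heads.** Chemical and geometric embeddings are
   concatenated and processed by three spatial convolution layers: for point
   $i$ with neighbours $j$ within 12 Å (self included),
   $\mathrm{out}_i = \mathrm{post}\big(\sum_j w_{ij}\,\mathrm{pre}(f_j)\big)$,
   where the scalar weight $w_{ij}$ is an MLP applied to the position and
   normal differences of the pair. A final MLP yields an 8-dimensional
   vector per point. The *site head* maps it through a logistic unit to an
   interface probability. The *interaction head* scores a patch pair by the
   symmetric combination $[e_a + e_b,\, |e_a - e_b|]$, so
   $\mathrm{score}(a,b) = \mathrm{score}(b,a)$ exactly.

Training minimises binary cross-entropy with the AMSGrad variant of Adam
(one gradient step per protein or per protein pair), holds out 10% of the
items for validation, and stops after `patience` epochs without validation
improvement, returning the best-validation parameters. Evaluation uses
AUROC in its rank form (Mann–Whitney statistic with half-credit for ties);
interface labels use the 1.4 Å vertex-to-vertex cutoff.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `spacing` | 0.7 Å | distance-field grid; finer grids refine vertex positions at cubic cost |
| `probe_radius` | 1.4 Å | water-probe inflation of the vdW envelope |
| `n_points` | 256 | surface points sampled per protein for the network stage |
| `k_atoms` | 16 | atoms aggregated per surface point |
| `k_geom` | 16 | neighbourhood of the shape-operator fit |
| `F` | 4 | Fourier order; feature length $1 + 2(F{+}1)$ |
| `conv_radius` | 12 Å | spatial convolution neighbourhood |
| `n_conv_layers` | 3 | convolution stack depth |
| `hidden_dim` | 16 | width of hidden layers |
| `out_dim` | 8 | per-point output dimension (fixed) |
| `interface_cutoff` | 1.4 Å | vertex-to-vertex interface labeling |
| `lr`, `patience`, `max_epochs` | 1e-3, 10, 300 | optimizer step size and early stopping |

Van der Waals radii are Bondi values (C 1.70, N 1.55, O 1.52, S 1.80, H
1.10, other 1.80 Å). Coordinates are Ångström throughout.

# Numerical choices

* **Distance field.** Values are exact minima over atoms. The pipeline uses
  a banded evaluation (per-atom local sweeps, values clamped to `+band` far
  from the surface): because the field is 1-Lipschitz, every cell that can
  straddle the zero level is evaluated exactly, so the extracted surface is
  identical to the exhaustive evaluation (asserted by test).
* **Marching tetrahedra.** Each grid cube is split into six tetrahedra along
  a common diagonal (Freudenthal), so adjacent cubes agree on shared faces
  and the mesh is closed whenever the level set avoids the grid boundary;
  padding guarantees that. Field values equal to the level are nudged by
  $10^{-12}$ to avoid degenerate on-grid crossings.
* **Neighbour queries.** k-NN and fixed-radius queries are exact brute-force
  scans with a deterministic tie-break (lower index wins), asserted against
  O(NM) re-computation. Interface labeling uses an exact cell-list query.
* **Curvature scale.** On dense meshes the $k$ nearest mesh vertices span a
  patch below the grid resolution, where the normal field is dominated by
  discretisation noise. The pipeline therefore estimates curvature on the
  *subsampled* point cloud (`point_cloud_curvatures`), whose k-NN scale
  tracks the sampling density (a few Å) — the scale at which binding-relevant
  shape lives. The mesh-level operator is kept for analytic-fixture work.
* **Rotation handling.** The default kernel consumes raw position/normal
  differences: translation-invariant, not rotation-invariant. The optional
  `frame = "tangent"` mode resolves both differences in the receiving
  point's tangent plane with the in-plane axis aligned to the projected edge
  direction; all six kernel inputs are then rigid-motion invariants. (A
  tangent frame chosen by a global-axis rule would *not* co-rotate with the
  surface and does not deliver invariance; we verified this before adopting
  the edge-adapted gauge.)
* **Degenerate inputs.** Isolated mesh vertices are dropped with a warning;
  empty convolution neighbourhoods reduce to the self term; rank-deficient
  curvature neighbourhoods trigger the ridge fallback and a flag; unknown
  residues get hydrophobicity 0 with a warning; unknown elements map to
  `other`.

# The synthetic generator

Real training corpora for this problem are large curated collections of
experimental complexes. To make every stage of the pipeline trainable and
testable without downloads, `make_blob()`/`pose_pair()` build pseudo-protein
pairs with a *planted, learnable* interface:

* each protein is a jittered sphere of atoms (default 300 surface atoms,
  radius 12 Å, jitter $\sigma = 0.1$ Å) filled with a deterministic interior
  carbon lattice so the molecular surface is a single outer sheet;
* the interface cap (angular radius 0.9 rad) is flattened to a facet that
  carries a central bump on the "lock" and a matching depression on the
  "key" (height 2.5 Å). Two mated facets keep a near-constant surface gap
  (default 1.0 Å), giving an extended contact patch — like the locally flat
  interfaces of real complexes — rather than the point tangency two convex
  spheres would produce;
* cap residues are hydrophobic with probability lifted by the correlation
  parameter (default 0.7 over a 0.35 background), so the chemical stream
  carries signal that is informative but not deterministic;
* elements follow a fixed C:N:O:S ≈ 62:17:20:1 composition; atoms are
  written as valid PDB ATOM records so the full real-data path (parsing →
  surfacing → featurisation) is exercised unchanged.

What passing tests on this generator *do* show: the implementation can carry
a joint geometric + chemical interface signal end-to-end from raw PDB input
through surfacing, featurisation, training, and evaluation, and loses it
when the labels are shuffled. What they do *not* show: performance on real
proteins, whose surfaces are far richer (secondary structure, clefts,
electrostatics, conformational variability) and whose interfaces are not
axially symmetric caps.

A finding worth knowing when interpreting ablations: the chemical stream's
multi-scale distance features, pooled over 16 atoms and three 12 Å
convolution layers, are themselves a capable *shape* sensor. Retraining
without the curvature stream therefore costs almost nothing on this
generator — the information is redundant — whereas retraining without the
chemical stream costs substantially (the curvature-only model still learns,
but less). The curvature stream is functional; it is just not uniquely
informative here.

A note on the shuffled-label control: items are constructed (as in
training) by pairing an interface vertex with its nearest interface
counterpart, while negatives are uniform vertex pairs. These two populations
differ geometrically, so even a label-agnostic model — an untrained network,
or one trained on shuffled labels, which has no gradient pressure to remove
its initialisation structure — can score measurably away from 0.5 on them.
The control therefore checks that no *label* information leaks through the
pipeline, not that the score is exactly chance.

# Design choices where the design was open

* **Patch embedding.** A patch is represented by the 8-dimensional output at
  its centre vertex; the convolution stack has already pooled the 12 Å
  neighbourhood, so no extra pooling is layered on top.
* **Positive/negative pair construction.** Positives match an interface
  vertex of A to its nearest interface vertex of B; negatives are uniform
  pairs with at least one non-interface member; items are balanced exactly.
* **Stream fusion.** Chemical and geometric embeddings are concatenated
  before the first convolution layer.
* **Separate models.** The site and interaction tasks train separate
  parameter sets; no weight sharing or pre-training across tasks.
* **Subsampling.** The network stage runs on 256 sampled surface points per
  protein (interface labels are computed on the full meshes first, and the
  subsample is guaranteed a handful of interface vertices when any exist).
  This keeps a full 250-pair training study on one CPU core in the
  ten-minute range; the spatial convolution sees a point spacing of a few Å,
  comparable to its 12 Å radius.
* **Hydrogens** are kept when present in the file and never added; HETATM
  records are excluded by default (a flag admits them as `other` atoms).
* **Hydrogen-bond feature.** A distance-weighted donor/acceptor surrogate
  (N: donors, O: acceptors, $w = \max(0, 1 - d/3.0)$ via the nearest atom of
  each class, summed and clamped to $[-1,1]$). It deliberately omits angular
  ideal-geometry terms; it is a labelled surrogate, not a full
  chemistry-stack reproduction. Electrostatics are intentionally absent.
* **Eigenvalue order** is $k_1 \le k_2$; no normalisation is applied to the
  curvatures before the embedding.

# Problem sizes used by the shipped studies

The packaged benchmark (`synthetic_benchmark()`, also driven by
`scripts/acceptance.R` and the acceptance test) uses 200 training and 50
held-out pairs at the generator defaults, trains with epoch caps of 30
(interaction) and 40 (site) with patience 6 — early stopping typically ends
the runs well before the caps — and evaluates 64 balanced items per held-out
pair. Analytic-fixture checks use icospheres of 2562 vertices and grid
fixtures of 400–1700 vertices.

# Known limitations

* The distance-field surface is a probe-inflated envelope (solvent-accessible
  family); re-entrant solvent-excluded patches are not reproduced, and no
  mesh decimation or repair is performed.
* Brute-force neighbour queries are quadratic; they are exact and fast at
  the shipped problem sizes but would need spatial indexing for
  100k-vertex meshes.
* The learned model shipped by the benchmark is trained on synthetic data
  only; applying it to real PDB files runs the full pipeline but transfers
  no knowledge of real interfaces.
* Training is single-threaded and deterministic by construction; there is no
  GPU path.
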