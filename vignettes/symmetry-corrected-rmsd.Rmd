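---
title: "Symmetry-corrected RMSD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-corrected RMSD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symrmsd)
```

## The problem

The root mean square displacement between paired atoms of two conformers is
the standard score for how well a docked ligand pose reproduces the
crystallographic one. Its weakness is the word *paired*: most scripts pair
atom $i$ of one file with atom $i$ of the other. Atoms of the same element
are physically indistinguishable, so for symmetric molecules (or files that
simply order atoms differently) the positional pairing can report a large
displacement between chemically identical structures. The cure is to
minimise over all *chemically admissible* pairings, which is what this
package does.

## The four RMSD flavours

Let $A, B$ be the $N\times3$ coordinate matrices of two conformers of one
molecule, with rows $\mathbf a_i$, $\mathbf b_i$.

**Standard.** $\mathrm{RMSD} = \sqrt{\frac1N\sum_i
|\mathbf a_i-\mathbf b_i|^2}$ (`rmsd_standard()`). No superposition: a rigid
translation of one conformer shows up in full.

**Minimised (QCP).** To measure conformational similarity irrespective of
pose, both sets are centred on their centroids and the minimum over rotations
is computed by the quaternion characteristic polynomial method:
$$\mathrm{RMSD}_{\min}=\sqrt{\frac{G_A+G_B-2\lambda_{\max}}{N}},\qquad
G_A=\mathrm{Tr}(A^TA),\; G_B=\mathrm{Tr}(B^TB),$$
with $\lambda_{\max}$ the largest eigenvalue of the symmetric $4\times4$ key
matrix $K$ assembled from $S=B^TA$. Rather than diagonalising $K$, its
characteristic polynomial
$P(\lambda)=\lambda^4+C_2\lambda^2+C_1\lambda+C_0$ (with
$C_2=-2\,\mathrm{Tr}(M^TM)$, $C_1=-8\det M$, $C_0=\det K$, $M=B^TA$) is
solved by Newton–Raphson started at $(G_A+G_B)/2$. That start is an upper
bound on $\lambda_{\max}$ ($\lambda_{\max}$ cannot exceed it, else the
radicand would be negative), so the iteration descends monotonically onto the
largest root.

**Hungarian.** Atoms of each element $e$ are re-paired by solving the linear
sum assignment problem on the $N_e\times N_e$ matrix of squared pairwise
distances, and the minimised per-element costs are pooled:
$$\mathrm{RMSD}_{\mathrm{Hungarian}}
=\sqrt{\frac1N\sum_e\min_{X^e}\sum_{ij}D^e_{ij}X^e_{ij}}.$$
Solving per element rules out pairing a carbon with an oxygen, but the
assignment still knows nothing about bonds: it happily maps an atom onto a
*different* chemical position of the same element if that is closer, breaking
the molecular graph and understating the displacement. It is provided only
for comparison with other software (`rmsd_hungarian()`), and the
command-line tool deliberately does not expose it.

**Symmetry-corrected.** The molecule is a graph: vertices are atoms labelled
by atomic number, edges are bonds. A pairing is chemically admissible exactly
when it is a graph isomorphism between the two conformers' graphs — a
bijection preserving labels and edges. `rmsd_symmetry()` enumerates *all*
isomorphisms (VF2, via igraph) and retains the lowest RMSD among them,
scoring each mapping with the positional RMSD or, with `minimize = TRUE`,
with the QCP-minimised one.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `minimize` | `rmsd_symmetry()`, `rmsd()`, CLI | `FALSE` | positional RMSD is the docking convention; minimisation answers a different question (conformation only) |
| `cache` | `rmsd_symmetry()` | `TRUE` | poses of one ligand share a graph, so the isomorphism list is reused; caching is provably value-neutral and only skips recomputation |
| Newton–Raphson tolerance | QCP solve | 1e-9 (absolute, on $\lambda$) | $\lambda$ has the magnitude of $G_A+G_B$ (tens to thousands of Å²); 1e-9 is far below any meaningful RMSD difference |
| Newton–Raphson iterations | QCP solve | 50 | the quartic converges in a handful of steps from the upper-bound start; 50 is a generous cap before the eigensolver fallback |
| hydrogens | CLI | stripped | heavy-atom RMSD is the docking convention; `--keep-hydrogens` overrides |
| `--precision` | CLI | 6 decimals | diff-stable machine-readable output |

## Numerical choices

* **Centring.** The QCP formula is the minimum over rotations only; for it to
  be the minimum over all rigid motions both inputs must be centroid-centred.
  `rmsd_qcp()` centres internally; `qcp_lambda_max()` documents the centred
  precondition instead, so the intermediate state it returns is exactly the
  textbook one.
* **Perfect overlap.** When $A$ and $B$ coincide, $\lambda_{\max} =
  (G_A+G_B)/2$ analytically and the radicand $G_A+G_B-2\lambda_{\max}$ can
  come out as a tiny negative number in floating point. The radicand is
  clamped at zero — the minimal monotone correction — so the result is exactly
  0, never `NaN`.
* **Fallback eigensolver.** If Newton–Raphson fails to converge, or its
  iterate drifts above the $(G_A+G_B)/2$ bound, the largest eigenvalue of $K$
  from `eigen(symmetric = TRUE)` is used. The eigendecomposition is the
  *definition* of $\lambda_{\max}$; the polynomial iteration is only the fast
  route to it, so correctness never depends on its convergence.
* **Degenerate $N=1$.** The standard RMSD of a single atom pair is the
  interatomic distance; the minimised RMSD is 0 by definition, since a
  translation removes everything.
* **Ties between mappings.** Only the minimum RMSD is returned, so no
  tie-break among isomorphisms is needed.
* **Tolerances in tests.** All accumulation is in double precision;
  comparisons use an absolute tolerance of 1e-6 Å unless an oracle justifies
  tighter (the quartic root is checked against the eigensolver at 1e-8
  relative; assignment costs are checked for exact equality).

## Design decisions that were genuinely open

* **Vertex match criterion.** Vertices are matched on atomic number *only*;
  bond orders, aromaticity flags, formal charges and isotopes are ignored and
  edges are unweighted. This makes the result robust to bond-perception
  disagreements between file-reading toolkits, and matches an API that takes
  nothing but coordinates, atomic numbers and an adjacency matrix.
* **Disconnected graphs.** Multi-fragment ligands (e.g. dot-disconnected
  records) stay one molecule with a disconnected graph; isomorphism is
  computed over the whole vertex set, so fragment-swapping mappings are found
  (the `disconnected-pair` fixture has exactly two automorphisms: identity
  and the fragment swap).
* **Exhaustive enumeration, no cap.** The minimum must range over *all*
  isomorphisms, so no cap is imposed. Graph isomorphism is NP, so the method
  is suited to small and medium sized ligands;
  `options(symrmsd.verbose = TRUE)` reports the mapping count.
* **Hungarian + minimise not offered.** The Hungarian variant exists only for
  cross-tool comparison; coupling it with QCP minimisation would lend it a
  legitimacy it does not have.
* **PDB bond perception.** Delegated entirely to OpenBabel (via ChemmineOB →
  SDF); this package performs no perception of its own. SDF and MOL2 bonds
  are taken from the files' bond blocks.
* **Mapping direction.** A mapping `m` pairs reference atom `i` with probe
  atom `m[i]`; the igraph VF2 result is inverted to this convention and
  the property tests verify label and edge transport explicitly.

## The fixture generator

Tests and the acceptance script use no external data. `make_molecule()`
produces ideal geometries — benzene as a regular hexagon (C–C 1.39 Å, radial
H at 1.09 Å; fixture conventions, not measured values), ethanol, linear
chains with arbitrary element patterns, a two-fragment pair, and an
asymmetric O–C(–N)–C–O chain — then applies, in order, an optional rigid
transform (rotation / mirror / translation), an optional atom permutation
(an automorphism, a same-element swap, or a cross-element swap, with the
adjacency permuted consistently), and seeded Gaussian jitter. Identical
arguments give bit-identical molecules, so every failure is reproducible.

The generator emulates what matters to the *pairing* problem: symmetry,
reordering, rigid motion and coordinate noise. It does not emulate real
conformational change (torsions), force-field geometry, protonation or
tautomerism — so passing tests demonstrate correctness of the RMSD
machinery, not anything about the chemistry of real docking sets. The mirror
scenario (benzene vs its reflection) reproduces synthetically the classic
inflation of the positional RMSD, and the `oxo-chain` vs its mirrored pose
reproduces the Hungarian pathology: the element-wise assignment swaps the two
graph-inequivalent oxygens and reports 0.63 Å where the graph-constrained
value is 2.87 Å.

## Problem sizes used in the checks

The oracle suites run 50 fixture molecules of at most 8 atoms against
exhaustive permutation search, 100 random 8-atom coordinate pairs against a
Kabsch SVD superposition (agreement to 1e-6 Å), 100 random 6×6 cost matrices
against the full 720-permutation minimum (exact), 100 random rigid motions
for invariance (drift below 1e-6 Å), and 10-pose cache-neutrality checks
(bit-identical). These sizes keep exhaustive enumeration exact and the whole
suite fast while covering every code path; the method itself has no such size
limit beyond the NP caveat above.

## Known limitations

* Exhaustive isomorphism enumeration is exponential in the worst case; large
  highly symmetric ligands will be slow.
* No mass-weighted RMSD, atom-subset selections, per-atom deviation reports,
  or return of the optimal rotation.
* PDB input quality is bounded by OpenBabel's connectivity perception; SDF or
  MOL2 with explicit bond blocks are the safer inputs.
* `rmsd_symmetry(minimize = TRUE)` runs one QCP solve per isomorphism; no
  pruning is attempted (correctness first — the solve is microseconds).
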