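# symrmsd

Symmetry-corrected RMSD calculations between conformers of the same molecule,
for R. The typical use is protein–ligand docking evaluation: a docking program
produces many poses of one ligand, and each pose is scored by its heavy-atom
root mean square displacement (RMSD) from the crystallographic pose. Naive
RMSD scripts pair atoms by their position in the file, which inflates the
score whenever the molecule is symmetric or the two files order atoms
differently; `symrmsd` computes the pairing-corrected value.

## What it computes

For two conformers with coordinate matrices $A, B \in \mathbb{R}^{N\times 3}$
(rows $\mathbf a_i$, $\mathbf b_i$, displacements
$\mathbf r_i = \mathbf a_i - \mathbf b_i$):

* **Standard RMSD** — `rmsd_standard()`:
  $\mathrm{RMSD} = \sqrt{\tfrac1N \sum_i \mathbf r_i^2}$ under the stored atom
  order.
* **Minimised RMSD (QCP)** — `rmsd_qcp()`: the minimum over rigid rotations
  and translations, computed without constructing a rotation matrix via the
  quaternion characteristic polynomial method:
  $\mathrm{RMSD}_{\min} = \sqrt{(G_A + G_B - 2\lambda_{\max})/N}$, where
  $G_A = \mathrm{Tr}(A^TA)$, $G_B = \mathrm{Tr}(B^TB)$ and $\lambda_{\max}$ is
  the largest eigenvalue of the 4×4 key matrix built from $S = B^TA$, found as
  the largest root of the quartic $\lambda^4 + C_2\lambda^2 + C_1\lambda + C_0$
  by Newton–Raphson from the upper bound $(G_A+G_B)/2$.
* **Hungarian RMSD** — `rmsd_hungarian()`: for each element separately, the
  linear sum assignment problem on squared pairwise distances is solved and
  the minimised costs are pooled. Provided for comparison with other tools
  only: the assignment is blind to connectivity and can report artificially
  low values.
* **Symmetry-corrected RMSD** — `rmsd_symmetry()`: the molecule is represented
  as a graph (atoms as vertices labelled by element, bonds as edges), every
  graph isomorphism between reference and probe is enumerated with VF2, and
  the lowest RMSD over all such atom mappings is retained — optionally with
  QCP minimisation per mapping (`minimize = TRUE`). Isomorphisms are cached
  across poses of the same molecule.

The array-level front ends `rmsd()`, `hrmsd()` and `symmrmsd()` take plain
coordinate matrices, atomic-number vectors and adjacency matrices, so any
toolkit that can produce those three arrays can drive the package.

## Worked example

Benzene compared with its mirror image. The mirror is a symmetry operation of
the molecule, so chemically the two structures are identical — but the
positional pairing does not know that:

```r
library(symrmsd)

ref     <- make_molecule("benzene")                    # ideal C6H6, 12 atoms
flipped <- make_molecule("benzene", mirror = c(1, 0, 0))

rmsd_standard(ref$coords, flipped$coords)
#> [1] 2.842974
rmsd_symmetry(ref, flipped)
#> [1] 6.261277e-16
```

The standard RMSD reports 2.84 Å between two indistinguishable structures;
minimising over the 12 automorphisms of the labelled benzene graph recovers 0.

The converse failure mode — the Hungarian assignment being too permissive —
shows up on an asymmetric O–C(–N)–C–O chain versus its mirrored pose. The
element-wise assignment swaps the two (chemically distinct) oxygens because
they happen to land near each other, breaking the bond structure:

```r
oxo <- make_molecule("oxo-chain")
oxo_mirror <- make_molecule("oxo-chain", mirror = c(1, 0, 0))
rmsd_hungarian(oxo, oxo_mirror)   # connectivity-blind: misleadingly low
#> [1] 0.626099
rmsd_symmetry(oxo, oxo_mirror)    # graph-constrained: the real displacement
#> [1] 2.869146
```

## Command-line tool

The installed `exec/symrmsd` script exposes standard and symmetry-corrected
RMSD (the Hungarian variant is deliberately not exposed) over SDF, MOL2 and
PDB files, one `name<TAB>rmsd` line per probe record, hydrogens stripped by
default:

```sh
$ symrmsd reference.sdf poses.sdf --minimize
pose1	0.277751
pose2	0.355155
pose3	0.161742
```

Flags: `--minimize`, `--no-symmetry`, `--keep-hydrogens`, `--no-cache`,
`--precision INT`. Exit codes: 0 success, 1 I/O or usage error, 2 reference
and probe are not the same molecule.

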