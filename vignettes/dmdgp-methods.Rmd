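---
title: "Distance geometry on protein backbones: model, encoding and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance geometry on protein backbones: model, encoding and search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdgp)
```

## The problem and the model

Nuclear magnetic resonance experiments yield a sparse set of interatomic
distances. Embedding a weighted graph $G = (V, E, d)$ of atoms and known
distances in $\mathbb{R}^3$ is the molecular distance geometry problem
(MDGP). The *discretizable* MDGP (DMDGP) assumes a vertex order in which

* the first three vertices form a distance clique (H1), and
* every vertex $v_t$, $t \ge 4$, knows its distances to the three
  immediately preceding vertices (H2).

Under H2 each new vertex lies on the intersection of three spheres centred
at its predecessors. For non-collinear predecessors that intersection has
at most two points, so after the first three vertices are pinned (vertex 1
at the origin, vertex 2 on the negative x axis, vertex 3 in the upper
xy half-plane) the whole solution space is a binary tree. Extra distances
between non-successive vertices ("pruning" distances) cut branches of that
tree.

## A backbone order with repeated alpha-carbons

`build_order(n)` builds the order this package uses for an $n$-residue
proline/glycine-free backbone over the atoms N, C$_\alpha$, C, H (amide)
and H$_\alpha$: residue 1 contributes (N, H$_\alpha$, C, C$_\alpha$),
every later residue contributes (H, N, C$_\alpha$, H$_\alpha$, C), and
each intermediary residue repeats its C$_\alpha$ right after its C, giving
$6n - 3$ vertices. The repetition is what keeps the order discretizable:
under the rigid-geometry hypothesis (fixed bond lengths and angles) every
1-2 and 1-3 distance is known, and the planarity of the trans peptide unit
(C$_\alpha^i$, C$^i$, N$^{i+1}$, H$^{i+1}$, C$_\alpha^{i+1}$) supplies the
remaining reference distances, but only if C$_\alpha$ can serve as a
reference twice. Every vertex $t \ge 4$ then has references
$(t-1, t-2, t-3)$ exactly.

The first-residue block is fixed as (N, H$_\alpha$, C, C$_\alpha$). Any
permutation with the same printed consequences (H$_\alpha$ at position 2,
segment spans 10/7/5 for the three edge families below) would serve; all
quantities the package reports are invariant to that residual choice.

## Binary encoding

Each vertex $t \ge 4$ records an orientation bit: 1 if it lies on the
positive side of the plane through its three references (signed volume
above a tolerance), 0 on the negative side *or on the plane*. Repeated
vertices always record 0: their coordinates are copies, so their bit
carries no information. Because vertex 4 never has a fourth predecessor,
both of its positions extend to full solutions and the two families are
mirror images; `normalize_bits()` therefore inverts every free bit from
position 4 onward whenever $b_4 = 1$, and `reduce_bits()` drops the four
fixed leading bits.

Two conventions here are deliberate:

* **Degenerate bits.** When the sphere intersection is a single in-plane
  point (exactly planar peptide units), encoding records 0 and decoding
  ignores the stored bit. This makes encode/decode total and deterministic
  on exactly planar synthetic data.
* **Flips never touch fixed bits.** Besides repeated vertices,
  normalization and `flip_bits()` also leave degenerate bits unchanged: a
  reflection maps an in-plane point to itself, so the geometric bit of the
  mirrored conformation is unchanged there. Experimental coordinates are
  never exactly planar, so on real data this extension is vacuous.

For a pruning edge $(i, j)$ only the bits at positions $i+3, \dots, j$ can
change the realized distance $\lVert x_i - x_j \rVert$; these *relevant*
bits (there are $j - i - 2$) are what `edge_sequence()` extracts, and the
edge-type label "KIND$_i$-$(j-i+1)$-KIND$_j$" groups edges whose windows
are geometrically equivalent. The three families the package analyzes are
HA-10-H and HA-7-HA (H/H$_\alpha$ contacts detectable by NMR, windows of
7 and 4 bits) and C-5-CA (fixed by peptide-plane geometry, 2 bits).

## The build-up solver and its two searches

`solve_dmdgp()` orders pruning edges ascending by $j$ then $i$ (prefixes
are realized before suffixes; any total order preserves correctness) and
groups them into components that share relevant bits (`decompose()`). The
first edge of a component is searched exhaustively over its free window
bits; by the mirror symmetry of the order, a feasible edge sequence and
its complete flip are the only two solutions of an independent edge, so
the search pins the first free bit to 0 and explores one representative
per flip pair. Later edges of a component first try the accumulated
partial assignment and its complete flip, then search whatever free bits
remain.

Two search strategies are available for the exhaustive step:

* **DFS** explores the window tree left-first (0 before 1) and counts
  *unique expanded nodes*: shared prefixes are counted once. On a 4-bit
  window whose solution is the 7th of 8 leaves this expands 14 of the 15
  tree nodes -- everything but the rightmost leaf.
* **FBS** (frequency-based search) tests candidate sequences in descending
  training-frequency order (ties lexicographic, unseen sequences appended
  in left-first order) and charges every tested candidate a full root-leaf
  path, so the accepted candidate at rank $k_b$ in a window of $n$ bits
  costs exactly $k_b \cdot n$ nodes; the same 4-bit window with the
  solution ranked third costs $3 \times 4 = 12$.

The asymmetry between the two accounting schemes (unique nodes for DFS,
full paths for FBS) reproduces the search-cost analysis this design
follows and is preserved deliberately; one consequence, asserted in the
tests, is that under a *uniform* table FBS's candidate order collapses to
the DFS leaf order and $k_b \cdot n$ can never strictly beat the DFS
count. FBS pays off exactly when training mass concentrates on few
sequences.

`bp_reference()` is the independent oracle: an exhaustive branch-and-prune
enumeration of all feasible normalized strings, against which the build-up
solutions are checked.

## Frequency tables

`build_freq_table()` tallies the per-edge sequences of first solutions
under their type labels; ranks are by descending count with lexicographic
tie-breaks, for reproducibility. `kmax()` reports the sequence-space size
of a type with relevant length $L$ as $2^{L-1}$: the exhaustive search
emits one canonical representative per flip pair (first free bit 0), so
one bit per independent-edge sequence is never free. The raw count $2^L$
is available with `raw = TRUE`. `accumulated_curve()` maps the $k$-th
ranked sequence to the normalized index $k/K$ and accumulates
probabilities; a peaked law majorizes the uniform diagonal, which is the
regime where FBS wins.

## The synthetic generator

`sample_conformation()` emulates the study conditions without any
download. One idealized reference chain is built in chemical bonding
order (NeRF placement; amide hydrogens by in-plane trilateration, the
three angles around N summing to 360 degrees), and every discretization
distance of the order is measured from it, guaranteeing a feasible,
mutually consistent instance whose solutions are exactly the orientation
mirror family of the reference chain. Generation then replays the DMDGP
construction itself: canonical placement of the first three vertices,
trilateration for each later vertex, with a bit sampler choosing between
two intersection points at free positions.

Default parameters (all configurable through `geometry_params()`):

| parameter | default | meaning |
|---|---|---|
| N-CA, CA-C, C-N | 1.458, 1.525, 1.329 A | backbone bond lengths |
| N-H, CA-HA | 1.01, 1.09 A | hydrogen bond lengths |
| N-CA-C, CA-C-N, C-N-CA | 111.0, 117.2, 121.7 deg | backbone angles |
| C-N-H | 119.0 deg | amide H placement (H-N-CA derived for a planar N) |
| N-CA-HA, C-CA-HA | 108.5 deg | tetrahedral H$_\alpha$ placement |
| phi, psi | 57, 47 deg | torsion *magnitudes* (alpha-helical values) |
| omega | 180 deg | trans peptide torsion |
| omega_jitter | 0 (sd, deg) | peptide non-planarity; 5 emulates PDB data |

The torsion magnitudes deserve a note: distances along a path through one
rotatable bond depend only on $|\phi|$ or $|\psi|$, while the *sign* of
each torsion is precisely the orientation bit the discretization chooses.
Fixing the magnitudes therefore yields a discrete mirror ensemble -- the
exact setting of the binary-tree model -- with the bit sampler as the
only source of conformational variety. What the generator consequently
does **not** emulate: continuous Ramachandran variation (all instances of
one parameter set share torsion magnitudes), side chains, steric
exclusion, and interval (lower/upper bound) restraints. Tests passing on
this ensemble certify the combinatorial machinery, not robustness to
experimental noise beyond the 1e-3 A coordinate rounding covered by the
PDB round-trip tests.

With `omega_jitter = 0`, amide N and first-occurrence C$_\alpha$ positions
are forced (single in-plane intersection): a 3-residue instance has 7 free
bits. Jitter frees those positions, which is how experimental data behaves
-- every position away from exact planarity carries a genuine bit. This
also explains why observed sequence counts can reach `kmax` on PDB-derived
data while exactly planar synthetic data populates fewer.

The default pruning policy emits all three edge families. For DFS/FBS
benchmarking the harness instead uses single-family policies (e.g. only
HA-10-H with `omega_jitter = 5`): under the default policy all edges of an
instance couple into one component through their window overlaps, so the
strategy-dependent exhaustive search would only ever run on the trivial
first edge and the comparison would be vacuous. Single-family windows are
independent, matching the per-independent-edge framing of the comparison.

## Numerical choices

* Trilateration is closed-form in the local orthonormal frame of the three
  anchors; the discriminant is clipped to zero within `tol^2`
  (`tol_disc = 1e-4` A by default), which decides forced versus free
  positions deterministically. Forcedness depends only on the
  discretization distances, so it is intrinsic to an instance.
* Orientation bits use a signed-volume tolerance of `1e-7` A^3 for exact
  synthetic coordinates; `1e-3` is recommended for PDB input.
* Feasibility of pruning restraints is `1e-6` A by default.
* Ties everywhere (two intersection points, equal counts) break
  deterministically: positive-orientation point first, lexicographic
  sequence order.
* The repeated C$_\alpha$ carries a measured distance of exactly 0 to its
  first occurrence; restraint validation admits zero only for such pairs,
  keeping H2 literally satisfied without ever trilaterating a zero radius
  (repeats copy coordinates).

## Problem sizes

The test-suite and benchmark sizes are chosen to exercise every code path
at desk scale: oracle-equivalence sweeps use 200 planted instances of 3-5
residues, round-trips 1000 random cases of 2-4 residues, flip-symmetry
enumerations windows of up to 7 free bits, frequency recovery 5000 draws
from a 0.7/0.2/0.1 law, and the paired DFS/FBS comparison 200 held-out
instances against a table trained on 120. Corpus-scale empirical figures
(win rates over tens of thousands of PDB segments) are out of scope; the
package reproduces the mechanism and its exactly checkable quantities.

## Known limitations

Exact distances only; no interval trilateration. Proline and glycine are
excluded by construction, as are side-chain atoms. The PDB reader keeps
the first model, blank/'A' alternate locations, and the plain H/HA
hydrogen names; nonstandard hydrogen nomenclatures are treated as missing
atoms and break segments rather than being remapped.
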