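---
title: "Anisotropic network models with atom-type-specific cutoffs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic network models with atom-type-specific cutoffs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anmkit)
```

## The model

anmkit builds anisotropic elastic network models (ANM): a structure is
reduced to $N$ point nodes, and every node pair closer than a cutoff is
joined by a Hookean spring of uniform stiffness $\gamma$ that is relaxed at
the observed separation.  The potential is

$$ E = \sum_{(i,j)\,\in\,\text{contacts}} \frac{\gamma}{2}
   \left(\lVert \mathbf R_i - \mathbf R_j \rVert - d^0_{ij}\right)^2 , $$

whose second-derivative matrix at the input structure is the $3N \times 3N$
Hessian with off-diagonal super-elements
$\mathbf H_{ij} = -(\gamma / d_{ij}^{0\,2})\, \mathbf r_{ij} \mathbf r_{ij}^\top$
and diagonal super-elements $\mathbf H_{ii} = -\sum_{j \ne i} \mathbf H_{ij}$.
Its low-frequency eigenvectors are the collective motions of the structure;
because displacements are three-dimensional the modes are direction-resolved
(anisotropic), unlike the scalar Gaussian network model.

The assumptions are the standard ones for elastic network analysis: the
input structure is an equilibrium conformation, fluctuations are harmonic
and small, all springs are identical, and node masses are uniform (no
mass-weighting).  Within those assumptions a connected three-dimensional
network has exactly six zero eigenvalues — rigid translations and rotations
— and $3N-6$ internal modes.

### Pair-dependent cutoffs

Rather than one global cutoff, each node type $i$ carries a half-range
$t_i$ (Å) and a pair $(i,j)$ is in contact when
$d^0_{ij} \le t_i + t_j$.  With a uniform $t_i = r_c/2$ this reduces
exactly to the classical single-cutoff model with cutoff $r_c$; the
reduction is a tested invariant.  The default is $r_c = 15$ Å
($t_i = 7.5$ Å for every type), a compromise between the larger cutoffs
that fit isotropic B-factors best and the smaller ones that give more
realistic anisotropic displacement tensors.  Half-ranges are looked up by
full type key (`"NUC:P"`, `"PRO:CA"`, `"LIG:C1"`), then by bare atom name
(`"CA"`), then fall back to $r_c/2$.  The cutoff test is inclusive
($\le$), so the uniform reduction is exact at $d^0 = r_c$.

### Coarse graining

* **Proteins** — one node per residue at the C$\alpha$ atom (configurable
  to any atom-name list).
* **Nucleotides** — three nodes per residue, at P, C4$'$ and C2, which
  balances resolution against cost for protein–DNA/RNA complexes.
  5$'$-terminal nucleotides have no phosphate and simply contribute two
  nodes (a notice is emitted, not an error, since essentially every real
  PDB chain starts this way).  Both the selection and the atom list are
  configurable.
* **Ligands** — every non-hydrogen HETATM becomes a node, except residues
  in the exclusion set (waters `HOH`/`WAT`/`DOD` by default; ions can be
  excluded the same way).  One node per heavy atom is deliberate: small
  ligands contribute few nodes anyway, and a centroid representation would
  hide binding-site anisotropy.

Hydrogens never become nodes.  Two nodes closer than $10^{-6}$ Å are an
error rather than a merged node: coincident nodes make the spring direction
undefined and almost always indicate an input problem (duplicated atoms).

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `cutoff` ($r_c$) | 15 | Å | fallback pairwise cutoff; $t_i = r_c/2$ |
| `range_table` ($t_i$) | empty | Å | per-type half-ranges overriding the fallback |
| `gamma` ($\gamma$) | 1 | arbitrary | uniform spring constant |
| `n_modes` | 20 | — | nonzero modes computed |
| `amplitude` | 2 | Å | peak node displacement in animations |
| `n_frames` | 20 | — | frames per animation period |

Because $\gamma$ is not physically determined, all fluctuation outputs use
$k_BT/\gamma \equiv 1$ and are *relative*; the least-squares scale from
`fit_experimental_b()` maps them onto experimental B-factors.  The spring
constant is uniform by design — no distance-dependent or sequence-dependent
stiffness — which keeps the model's single parameter the cutoff geometry.

## Eigensolvers

Two routes produce the modes, and their agreement is a tested invariant
rather than an implementation detail:

* **dense** — full symmetric eigendecomposition (LAPACK via `eigen()`),
  used automatically for $3N \le 1500$;
* **subset** — shift-invert Lanczos with full reorthogonalization over a
  sparse Cholesky factor of $H + \sigma I$ (σ = $10^{-6}\lambda_\max$),
  which retrieves only the smallest eigenpairs and scales to systems where
  the dense route is wasteful.  Ritz values are refined by a Rayleigh
  quotient on $H$ itself.

Eigenvalues below $\max(10^{-8}\lambda_\max,\,10^{-10})$ are classified as
rigid-body modes, counted, and excluded.  A count other than six raises a
disconnected-network error; `allow_rigid_mismatch = TRUE` downgrades it to
a warning, which is also the route for deliberately degenerate systems
(the two-node system is collinear and has five rigid modes).  Eigenvector
sign is fixed by making each vector's largest-magnitude component positive
— needed for byte-reproducible output files.  Comparisons between mode
sets use subspace overlaps within eigenvalue clusters, because individual
vectors are arbitrary inside a degenerate eigenspace.

## Observables

With modes $(\lambda_k, \mathbf u_k)$ and $\mathbf u_{k,i}$ the
3-component block of node $i$:

* mean-square fluctuation
  $\mathrm{msf}_i = \sum_k \lambda_k^{-1} \lVert\mathbf u_{k,i}\rVert^2$,
  and the theoretical B-factor $B_i = (8\pi^2/3)\,\mathrm{msf}_i$;
* ADP tensors
  $\mathbf U_i = \sum_k \lambda_k^{-1}\, \mathbf u_{k,i}\mathbf u_{k,i}^\top$
  (so $\operatorname{tr}\mathbf U_i = \mathrm{msf}_i$ identically), written
  to PDB `ANISOU` records as $\mathrm{round}(10^4\, U_{ij}\cdot s)$ for a
  user scale $s$;
* cross-correlations
  $C_{ij} = \mathrm{cov}_{ij}/\sqrt{\mathrm{msf}_i\,\mathrm{msf}_j}$ with
  $\mathrm{cov}_{ij} = \sum_k \lambda_k^{-1} \mathbf u_{k,i}\!\cdot\!\mathbf u_{k,j}$;
* distance fluctuations
  $D_{ij} = \mathrm{msf}_i + \mathrm{msf}_j - 2\,\mathrm{cov}_{ij}$, the
  mean-square fluctuation of the relative displacement
  $\Delta\mathbf R_i - \Delta\mathbf R_j$.  The map is named after the
  quantity it approximates — fluctuations of inter-node distance — and this
  relative-displacement form is the standard elastic-network proxy for it.

With the full mode set, the matrix of $\mathrm{cov}_{ij}$ equals the
3×3-block traces of the Moore–Penrose pseudo-inverse of $H$; the test suite
asserts this equivalence against an independent pseudo-inverse.
Correlation maps use **all computed modes** by default (the mode count is
recorded in the run manifest), since truncating to a fixed subset is a
presentation choice, not a model property.

Mode animations displace the structure along a unit mode vector through one
full sine period.  The default normalization makes the *maximum per-node
displacement* equal the requested amplitude, so animations of different
modes are visually comparable; `thermal_amplitude = TRUE` scales by
$1/\sqrt{\lambda}$ instead when relative amplitudes matter.  Frame 0 is the
input structure exactly.

## Synthetic structures and what they do (not) show

All tests run on generated PDB text, so the suite needs no downloads:

* `make_ca_chain(n)` places $n$ C$\alpha$ nodes at 3.8 Å spacing along a
  spherical spiral with ~4 Å turn separation, jittered by ±0.5 Å per axis.
  The spiral keeps large fixtures *globular* — like folded proteins, whose
  radius grows far slower than chain length — so the softest internal modes
  remain separated from the rigid-body modes by several orders of
  magnitude.  (A straight 200-residue rod, by contrast, has bending modes
  so soft they are numerically indistinguishable from rigid rotations at
  the zero-mode tolerance; that is a real property of rods, not an
  artifact, and is why the generator coils the chain.)  `n = 2` with zero
  jitter is the analytic two-node system: one stretch mode with
  $\lambda = 2\gamma$, msf $= 0.25$, $C_{12} = -1$, $D_{12} = 1$,
  $\mathbf U_1 = \mathrm{diag}(0.25, 0, 0)$.
* `make_mixed_complex(n_res, n_nt, n_lig)` adds a mock nucleotide chain
  (P/C4$'$/C2 per residue, no P on the 5$'$ residue), a HETATM ligand and a
  water, all within contact range.
* `perturb_rigid()` applies a seeded random rotation + translation.

Identical arguments and seed give byte-identical files, and the generators
restore the caller's RNG state.  The geometry is schematic: bond lengths,
angles and sequence are not realistic, and B-factor columns carry a smooth
synthetic profile.  Passing tests therefore demonstrate the *mechanics* of
the method — spectral structure, invariances, solver agreement, format
fidelity — not predictive power on real crystal structures, which depends
on contact topology these toys do not reproduce.

## Numerical choices and degenerate inputs

* **Altloc policy**: the highest-occupancy conformer is kept; ties go to
  file order.  **Multi-model files**: first model only, with a notice.
  Both are conventions, chosen to match common practice for
  single-conformation analyses.
* **Old-dialect atom names**: `C4*` is normalized to `C4'` on parse.
* **PDB coordinate precision**: coordinate columns carry three decimals, so
  any PDB-text round trip quantizes positions to $10^{-3}$ Å and a rigid
  motion applied *through text* preserves the spectrum only to about
  $10^{-4}$ relative.  `transform_structure()` applies rigid motions in
  memory at full precision (conjugating ADP tensors), and the $10^{-8}$
  invariance tests use that route; `perturb_rigid()`'s text round trip is
  asserted at the format's own resolution.
* **Disconnected networks**: refused by default with the rigid-mode count
  in the message; two far-apart components show twelve near-zero modes.
* **Zero-variance B-factors** make the Pearson correlation undefined and
  raise a classed error rather than returning `NaN`.
* Imported mode vectors are normalized but *not* re-orthogonalized; a
  notice reports the largest off-diagonal overlap above $10^{-3}$, since
  external methods (e.g. PCA of a trajectory) may legitimately supply
  non-orthogonal directions.

## Problem sizes in the test suite

Unit and property tests run chains of 2–50 nodes; solver-equivalence and
spectral-structure checks go up to 200 nodes (3N = 600), where the dense
reference is still cheap and the sparse route is already exercised well
above its design regime boundary.  Oracle equivalences against the
pseudo-inverse and finite-difference Hessian use 10–40 nodes, where those
oracles are exact and fast.  These sizes were chosen so the whole suite
runs in seconds while every numerical claim is still tested in the regime
it is made for.

## Known limitations

* No mass-weighting, no distance-dependent springs, no Gaussian (isotropic)
  network variant, no crystal-contact augmentation.
* mmCIF input, symmetry expansion and hydrogen handling beyond exclusion
  are out of scope; input is single-model PDB.
* Fluctuation units are relative; absolute B-factor prediction requires the
  fitted scale and inherits its noise.
* The sparse solver assumes the Hessian is well-conditioned after the
  $\sigma$ shift; pathological near-disconnected networks should be (and
  are) caught by the rigid-mode count first.
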