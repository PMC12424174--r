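---
title: "First-order SAPT with double exchange from density matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order SAPT with double exchange from density matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapt1dm)
```

## The model

In symmetrized Rayleigh–Schrödinger (SRS) perturbation theory the
first-order interaction energy of a dimer is the ratio
$E^{(1)} = (\langle\hat V\rangle + \langle\hat V\hat P\rangle)/(1 +
\langle\hat P\rangle)$ over the product of the isolated monomer states.
The exchange operator $\hat P = \sum_k \hat P_{2k}$ collects all
$k$-pair electron exchanges between the monomers; each $\hat P_{2k}$
carries $2k$ powers of the intermolecular overlap, so expanding the
ratio organizes the exchange energy in even overlap orders.  This
package evaluates the electrostatic term, the single-exchange ($S^2$)
term and the double-exchange ($\propto S^4$) increment.

Every expectation value is computed from monomer $k$-body reduced
density matrices ($k \le 3$) contracted with interaction tensors.  The
interaction operator is kept in a single two-index-pair form by dressing
the two-electron integrals with the nuclear attraction and internuclear
terms divided by the monomer electron counts (the modified potential
$\tilde v$).  The $\langle\hat V\hat P_{2k}\rangle$ expectations are
assembled from four contraction intermediates per order (the
Moszynski-type $G_k$, $F_k$, $D_k$, $C_k$ tensors), each pairing
$k$- and $(k{+}1)$-body RDMs of the two monomers through overlap chains.
The $(-1)^k$ of the exchange operators lives in the expectation
functions, never in the intermediates, so the sign bookkeeping has one
canonical location.

Two independent evaluation routes coexist:

* a **dense spinorbital path** that materializes the RDMs over each
  monomer's support orbitals and performs the contractions literally —
  transparent, used for validation and for compact active spaces; and
* a **factorized geminal fast path** for strongly orthogonal
  geminal-product states (APSG/GVB-PP; Hartree–Fock and any two-electron
  singlet are special cases).  Group RDMs factor into per-geminal
  densities and rank-one antisymmetric pair amplitudes; the
  antisymmetrized combination across geminals is expanded
  programmatically, and each resulting term is a product of matrix
  chains contracted with one modified-potential block.  No 3-RDM is ever
  formed.  Numerical identity with the dense path (to well below
  $10^{-9}$ hartree) is the correctness contract of this path, asserted
  over Hartree–Fock, single-geminal, core-plus-geminal and two-geminal
  fixtures.

A third, fully independent standard is the **determinant-space oracle**:
the exchange-operator strings are applied literally (sparse
creation/annihilation algebra with overlap-dressed creators) to the
tensor product of the monomer CI expansions.  On every fixture small
enough for it, the five expectation values agree with the density-matrix
routes to machine precision, and the summed operator expectations
reproduce the first-quantized antisymmetrizer identity
$\langle 1 + \hat P\rangle = \det M$ over the combined occupied-orbital
overlap matrix — including open-shell, unequal-electron-number cases.

## Monomer states

All monomer wave functions are expanded in the dimer-centered basis
(partner atoms carry basis functions but no charge).  The package
provides

* restricted Hartree–Fock (DIIS),
* exact singlet full CI for two-electron monomers (symmetrized
  orbital-pair basis; any root, with mirror-symmetry characters for
  excited-state targeting),
* state-specific CAS(2,n)SCF above an optional closed-shell core
  (two-step: exact active CI plus first-order orbital rotations with
  DIIS acceleration), and
* frozen-core FCI for a two-valence-electron atom (CI of the valence
  pair over all non-core orbitals above a frozen Hartree–Fock core).

A two-electron singlet is exactly one geminal (its natural expansion is
the Schmidt decomposition), so GVB-PP is CAS(2,2), APSG with $n$
orbitals is CAS(2,$n$), and even a full-space FCI state enters the fast
path as a single geminal spanning every natural orbital.  Valence
CAS($n$,$n$) states of perfect-pairing character can be mapped onto a
GVB-PP model by comparing 2-RDM elements (`map_cas_to_gvb`): strongly
and weakly occupied orbitals are paired by an exhaustive minimum-score
matching over the pair-coupling 2-RDM elements, coefficients are
$\pm\sqrt{n_i/2}$ with signs taken from those elements, and the
root-mean-square deviation of the reconstructed 2-RDM is reported as a
fit score (error above $10^{-1}$ per element, warning above $10^{-2}$).

## Parameters that matter

* **Basis sets** (`aug-cc-pvdz`, `aug-cc-pvtz`, `sto-3g`): bundled as
  text; diffuse augmentation is essential for every benchmark here
  because the exchange tails at 4–8 bohr are carried by the most diffuse
  functions.
* **Geminal truncation** (`method_spec(..., trunc = 1e-7)`): natural
  orbitals whose geminal coefficient falls below `trunc` relative to the
  leading one are dropped from the FCI support.  At the default the
  double-exchange term changes by less than 0.01%; the setting exists
  because the support size drives the cost of the interaction tensors.
* **Electron counts in the modified potential**: always the number of
  electrons carried by the RDMs.  In frozen-core (index-range
  restricted) calculations the core is excluded from every sum, the
  valence count is used, and the one-electron attraction operators are
  screened by the frozen core's Coulomb potential so that the partners
  remain electrostatically neutral; the internuclear term becomes the
  full electrostatic interaction of the two frozen (nucleus + core)
  distributions.
* **CASSCF convergence**: orbital-gradient max-norm $5\times10^{-7}$,
  with acceptance after twenty energy-stagnant iterations below
  $10^{-5}$ — near-redundant rotations among degenerate weakly occupied
  orbitals otherwise tail off indefinitely without changing the energy
  or the exchange quantities at any reported digit.
* **AO linear dependence**: overlap eigenvalues below $10^{-8}$ are
  removed by canonical orthogonalization with a warning; the smallest
  eigenvalue is stored on the system handle (`sys$smin`) and written
  into the CLI provenance block.

## Design choices in genuinely open spots

* **T-shaped H₂···H₂ orientation.**  The benchmark geometry fixes the
  center-to-center distance at 6.21 bohr with one bond stretched.  The
  package places the stretched (probe) molecule perpendicular to the
  intermolecular axis and the spectator (1.44 bohr) along it: with the
  stretched bond on the axis, a 7.2-bohr bond would push an atom to
  within ~2.6 bohr of the partner and the single-exchange term would
  grow explosively instead of reaching the plateau that characterizes
  this scan.  The perpendicular choice also reproduces the reported
  magnitude of the single-exchange term and its geminal-method errors.
* **Generalized modified-potential blocks.**  The normal-ordered
  $\hat V\hat P_{2k}$ classes contain blocks with orbitals of one
  monomer replacing partner indices.  These resolution-of-identity
  objects are computed as direct hybrid AO integrals, which is exact
  because each monomer's orbital set spans the full dimer basis; an
  overlap-projected variant (`projected = TRUE`) exists for models whose
  single-particle space *is* a truncated support, and the two are
  verified to coincide on complete supports.
* **Frozen-core reading.**  The hybrid correction (frozen-core value
  plus the all-electron-minus-frozen-core Hartree–Fock difference) is
  only meaningful if the frozen-core calculation genuinely omits the
  core from the exchange sums; with core-embedded RDMs the Hartree–Fock
  difference would vanish identically.  The index-range-restricted
  reading with core-screened operators is therefore used, and the
  small-model validation below supports it.
* **CAS(n,n) mapping conventions.**  Leading geminal coefficients are
  taken positive; partner signs come from the pair-coupling 2-RDM
  elements (only products of coefficients are observable).  All perfect
  matchings are scored exhaustively (up to ten pairs) — deterministic
  and safe at these sizes.
* **Fast-path term generation.**  The published closed-form geminal
  expression for the double-exchange term runs to more than a hundred
  terms; transcribing it is the dominant error risk.  Instead the
  antisymmetrization expansion is generated programmatically at run
  time, and equality with the dense path is asserted in the test suite.
  For perfect-pairing products with many geminals the term count grows
  with the fourth power of the geminal count (each term at most quartic
  in the support size); for the core-plus-one-geminal and two-electron
  monomers used throughout the benchmarks this is far below the formal
  sixth-power bound in active orbitals, but it is *not* the optimal
  many-geminal factorization.

## What the generator and fixtures emulate

The bundled fixtures produce the three model dimers programmatically
(T-shaped H₂···H₂; T-shaped He···H₂ in ground and mirror-odd excited
arrangements; collinear Be···Be), plus arbitrary XYZ input.  Test
fixtures are tiny synthetic systems (minimal or custom compact bases)
chosen so the determinant oracle is exact and fast; they exercise every
code path (open shells, four-electron monomers with nonzero 3-RDM
contributions, multi-geminal products) but not large-basis numerics,
which are covered by the benchmark scripts instead.  Passing tests
therefore demonstrate the algebraic machinery exactly, while agreement
with published large-basis numbers additionally depends on the bundled
basis-set data.

## Numerical behaviour and limitations

* Problem sizes used in the shipped benchmarks: 92 spherical AOs
  (H₂···H₂/aug-cc-pVTZ, one geometry), 69 AOs per point over a 21-point
  scan (He···H₂/aug-cc-pVTZ), 46 AOs (Be···Be/aug-cc-pVDZ).  A scan
  point costs tens of seconds on one core; warm starts carry orbitals
  between neighbouring geometries.
* The double-exchange increment at van-der-Waals separations is orders
  of magnitude smaller than the single-exchange term and is assembled
  from strongly cancelling expectation values; it is also the quantity
  most sensitive to weakly occupied diffuse natural orbitals (including
  ghost-centered ones), whose contributions enter linearly through the
  pair amplitudes.  Truncated geminal spaces consequently converge
  slowly toward the full-CI double-exchange increment at long range in
  these calculations — markedly more slowly than some published
  benchmark error statistics for the same systems suggest, a
  discrepancy that survives every internal cross-validation available
  here (dense vs factorized vs determinant-space evaluation and the
  first-quantized antisymmetrizer identity).
* Out of scope: second-order terms (induction, dispersion and their
  exchange counterparts), infinite-order first-order exchange, and
  monomer-centered basis setups.

## Frozen-core validation on a small model

The frozen-core machinery can be checked against an all-electron FCI
oracle in a compact basis, where the four-electron monomer is solved by
determinant CI and the dense path supplies the exchange terms; the
corrected frozen-core values track the all-electron ones to a few
percent at the S² level on such models (see
`tests/testthat/test-expansion.R` and the Be fixtures), which is the
accuracy regime the hybrid correction is designed for.
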