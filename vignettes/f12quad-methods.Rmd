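---
title: "Seminumerical evaluation of the exchange-type MP2-F12 intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seminumerical evaluation of the exchange-type MP2-F12 intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Explicitly correlated MP2-F12 methods augment the conventional double
excitations of second-order perturbation theory with geminal functions
$F_{12}\,|ij\rangle$ built from a Slater-type correlation factor

$$F_{12} = \tfrac{1}{\gamma} e^{-\gamma r_{12}},$$

which restores the correct electron–electron coalescence behaviour and
dramatically accelerates basis-set convergence.  In the diagonal,
orbital-invariant 3C ansatz with fixed amplitudes the correction to the MP2
energy needs three pair intermediates,

$$V^{ij}_{kl} = \langle ij|F_{12}\hat Q_{12} g_{12}|kl\rangle,\qquad
  X^{ij}_{kl} = \langle ij|F_{12}\hat Q_{12} F_{12}|kl\rangle,\qquad
  B^{ij}_{kl} = \langle ij|F_{12}\hat Q_{12}(\hat f_1+\hat f_2)\hat Q_{12}
  F_{12}|kl\rangle,$$

with $g_{12} = r_{12}^{-1}$, the strong-orthogonality projector
$\hat Q_{12} = (1-\hat o_1)(1-\hat o_2)(1-\hat v_1\hat v_2)$, and the Fock
operator $\hat f$.  The package evaluates the *exchange-type* index patterns
of these intermediates (and, for the final energy, their direct-pattern
companions) with a hybrid of three techniques:

* **NQ** — numerical quadrature: six-center three-electron integrals and
  selected four-center two-electron (4c2e) integrals are decomposed over a
  molecular grid, e.g.
  $\langle ijk|\hat W_{12}\hat Y_{23}|kij\rangle \approx
   \sum_g w_g\, \phi_j^g \phi_i^g\, (g|\hat W_{1g}|ik)(g|\hat Y_{1g}|kj)$,
  where $(g|\hat O_{1g}|\mu\nu)$ are one-electron kernel integrals centred
  at grid points;
* **DF** — density fitting of the remaining 4c2e factors in an auxiliary
  basis, with the operator's own kernel as the fitting metric;
* **CABS-RI** — resolution of the identity in the union of the
  Hartree–Fock orbital space and a complementary auxiliary basis set,
  used only where the $B$ intermediate requires it.

Decomposing the products of two 4c2e integrals with one factor on the grid
and the other density-fitted reduces their formal cost from
$O(M^5)$ (DF alone) to $O(M^4)$; the package's operation counters expose
exactly this separation on linear-chain model systems.

The energy is assembled over active occupied pairs as

$$E_{\mathrm{F12}} = \sum_{ij}\Bigl[-\tfrac{5}{4}V^{ij}_{ij}
  + \tfrac14 V^{ij}_{ji} + \tfrac{7}{32}B_{(1)} + \tfrac{1}{32}B^{ij}_{ji}
  - (\epsilon_i+\epsilon_j)\bigl(\tfrac{7}{32}X_{(1)}
  + \tfrac{1}{32}X^{ij}_{ji}\bigr)\Bigr].$$

The coefficients are the closed-shell spin summation of the fixed
s-/p-wave coalescence amplitudes $(-3/8, -1/8)$ that belong to the
positive-defined correlation factor above: the variationally optimal
diagonal amplitude computed by the dense oracle on helium is $-0.53$,
within a few percent of the s-wave cusp value $-1/2$, and the
fixed-amplitude energy agrees with the optimal-amplitude value to better
than one percent.  A formulation that attaches a positive sign to the $V$
terms would make the "correction" positive, which the variational bound
excludes.  Two readings of the leading $B$ and $X$ coefficient pattern are
defensible; both are implemented behind `b_direct_fix` (default: the
direct pattern carries $7/32$, mirroring the $5/4$ direct / $1/4$
exchange structure of the linear terms).

## How each intermediate is computed

**V and X** stay entirely free of CABS indices.  With the exact projector,

$$V^{ij}_{ji} = (FG)^{ij}_{ji} + F^{ij}_{kl}G^{kl}_{ji}
  - F^{ij}_{ab}G^{ab}_{ji}
  - \langle ijk|F_{12}g_{23}|kij\rangle - \langle jik|F_{12}g_{23}|kji\rangle,$$

and analogously for $X$ with $(F,F)$ kernels.  The $FG$ and 6c3e terms are
evaluated in the AO picture with occupied-density dressings (Algorithm 1
style); the occupied–occupied and virtual–virtual products use the hybrid
DF+NQ path with the Coulomb factor on the grid, so no 3c2e or 2c2e Coulomb
integrals are needed.  With canonical orbitals, the $X\cdot$Fock
contraction of the energy reduces to $(\epsilon_i+\epsilon_j)$-weighted
pair sums, implemented through energy-weighted active densities
$\tilde P = \sum_i \epsilon_i c_i c_i^T$.

**B** uses the reduction of $\hat Q_{12}\hat f_1\hat Q_{12}$ to eight
operator/projector combinations (`reduce_qfq()` carries the full
expansion, the annihilation marks from $\hat o\hat v = 0$ and
$\hat o\hat f\hat v = 0$, and the final term list with transpose markers;
a matrix oracle on random model spaces verifies the reduction to
$10^{-13}$).  The terms are then routed as follows:

* $\hat f_1$ — through the commutator relation
  $F f_1 F = \tfrac12(\nabla_1 F\cdot\nabla_1 F) - F\hat k_1 F
  + \tfrac12\{(\hat f+\hat k), F^2\}$: the gradient-square term is exactly
  $\gamma^2$ times the $F^2$ quadrature term; the anticommutator is a
  single full-RI insertion evaluated with one union-space dressing;
  both ride on the Algorithm-2 $F^2$ pass and may be omitted with
  `commutator_level = "none"`;
* $\hat k_1$, $\hat f_1\hat o_1$, $\hat o_1\hat f_1\hat o_1$ — dressed AO
  6c3e contractions sharing one evaluation pass, with dressings
  $\Pi k \Pi$, $P f \Pi$ and $P f P$ ($\Pi = S'^{-1}$ is the union-space
  RI projector);
* $\hat f_1\hat o_2$, $\hat f_1\hat o_1\hat o_2$,
  $\hat o_1\hat f_1\hat o_1\hat o_2$ — the U intermediate;
  $\hat f_1\hat v_1\hat v_2$, $\hat v_1\hat f_1\hat v_1\hat v_2$ — the T
  intermediate.  Sub-space variants ride along by scaling the dressing
  matrix of the union index with the term coefficients $(-1, +2, -1)$ and
  $(-2, +1)$; the union index is contracted out first, so the
  $(g|F|i p'')$ block is never formed.

Two consistency choices matter and are enforced in code: (i) when the
generalized/extended Brillouin conditions zero the occupied/virtual–CABS
Fock blocks, the AO-side dressings are rebuilt from the zeroed union-MO
Fock via $S' C f^{\mathrm{MO}} C^T S'$ so the AO and MO pictures describe
the same operator; (ii) within each term, the direct pattern places the
quadrature on the same electron as the exchange pattern, which makes the
two patterns bit-wise degenerate for single-pair systems (helium), as the
pair structure demands.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1.3 bohr⁻¹ | correlation-factor exponent |
| `grid_level` | g2 | production grid (g0…g4, g7) |
| `theta_nq` | 1e-10 | conservative screen on grid 3c1e shell pairs |
| `weight_threshold` | 1e-5 | relative grid-point screen |
| `batch_grid` | 64 | grid points per batch |
| `batch_aux` | 16 | auxiliary functions per DF batch |
| `batch_mo` | 16 | grid sub-batch of the AO→MO transformation |
| `frozen_core` | 0 | frozen occupied orbitals |
| `occ_products` | occupied | range of the $k,l$ product indices under frozen core |
| `n_stg` | 6 | Gaussians in the Slater-geminal expansion |

All batching choices affect memory and speed only: the batching-invariance
tests require every reported term to be identical to $10^{-11}$ hartree
for grid caps $\{16, 64, 128, \mathrm{all}\}$ and auxiliary batches
$\{16, \mathrm{all}\}$; per-batch partial sums are accumulated with
compensated summation so this holds to near round-off.

## Numerical choices

* **Slater-geminal expansion.**  The correlation factor is expanded in
  `n_stg = 6` Gaussians fitted by weighted least squares (weight $r^2$,
  logarithmic mesh on $(10^{-3}, 10)$ bohr) on a fixed even-tempered
  exponent ladder $\beta_k = 0.16\,\zeta^2\, 5.2^{k}$.  The ladder makes
  fits of increasing $n$ nested, so the stored residual is rigorously
  non-increasing in $n$.  The pointwise accuracy of any 6-Gaussian fit of
  $e^{-1.3 r}$ over that domain is cusp-limited to a few times $10^{-3}$
  (a direct minimax optimization of all twelve parameters bottoms out near
  $2\times10^{-3}$); this is irrelevant for the validation design because
  the dense oracle uses the same expansion, so fit error cancels in every
  production-versus-oracle comparison.  $e^{-2\gamma r}$ is fitted
  separately rather than by squaring, and the $FG$ kernel damps the exact
  Coulomb singularity with the Gaussians of the $e^{-\gamma r}$ fit, so
  $1/r_{12}$ is treated exactly.  The gradient-square kernel is defined as
  $\gamma^2$ times the $F^2$ expansion, making the tensor identity exact
  by construction.
* **Integral engine.**  McMurchie–Davidson recursions over Hermite
  Gaussians with three radial kernel families (Coulomb, Gaussian geminal,
  Gaussian-damped Coulomb) and a Boys function accurate to $10^{-14}$;
  angular momenta through $d$; validated against closed forms and an
  independent real-space quadrature oracle at machine precision.
* **Quadrature grids.**  Mura–Knowles radial maps ($\alpha = 5$ bohr,
  region boundaries at $\{0.35, 1.0\}\times$ Bragg–Slater radius) with
  spherical product rules (Gauss–Legendre in $\cos\theta$ × uniform $\phi$)
  matched to the polynomial exactness degree of the nominal angular order
  of each pruning region; the printed per-level radial counts and angular
  orders are preserved as the grid's layout metadata, while realized point
  totals differ from any particular production grid library.  Angular
  points are generated in the molecule's principal-axis frame, which makes
  the correction invariant under rigid rotations to $10^{-8}$ hartree.
  Becke partitioning uses the standard three-fold iterated polynomial with
  Bragg-radius size adjustment.  Point screening drops $g$ when
  $w_g \max_\mu |\chi_\mu^g|^2$ falls below `weight_threshold` times the
  global maximum.  Batches are ordered by a Morton (Z-order) spatial key —
  locality only; results are partition-invariant.
* **Screening.**  A shell pair is skipped for a batch when
  (max batch weight) × (Gaussian pair prefactor) × (kernel radial envelope
  at the closest approach minus the pair extent) falls below `theta_nq`.
  The bound is deliberately conservative; the audit tests verify that
  retained entries are identical to the unscreened evaluation and that
  dropped entries stay below the bound.
* **Conditioning.**  Union-overlap eigenvalues below $10^{-8}$ are dropped
  in the Löwdin orthogonalization (the $\Pi S'\Pi = \Pi$ check is applied
  relative to $\lVert\Pi\rVert$, which matters for near-dependent chain
  unions); CABS vectors are the left singular vectors of the
  Löwdin-set/MO overlap with singular value $< 0.5$; DF metrics are
  pseudo-inverted with a relative eigenvalue drop of $10^{-10}$.
* **Reference.**  The internal closed-shell RHF uses the package's own
  Coulomb integrals with DIIS, converged to a commutator norm of
  $10^{-9}$; canonical orbitals are required and validated, and an
  external provider can replace the internal solver through a small
  backend contract.

## The dense oracle and the synthetic fixtures

`dense_reference()` recomputes pair-resolved V, X, B from exact
(non-fitted) MO 4c2e tensors, with the genuinely three-electron terms on an
extensive unscreened g7-level grid — an independent, MO-picture,
loop-structured code path that shares only the primitive integral kernels
with the production engine.  On the helium and hydrogen-dimer fixtures the
production values at the g4 grid agree with it to well below
$5\times10^{-6}$ hartree, and the full correction converges monotonically
through g0…g4 for both the dimer and water.

The fixture systems (He, H₂, H₂O, linear H chains, a pseudo-peptide chain
generator for size scans) use compact synthetic even-tempered bases
embedded in the package.  They emulate the *structure* of production
calculations — separate orbital, CABS and fitting sets, s/p/d functions,
realistic geometries — but not their size: real F12 basis families are an
order of magnitude larger, their CABS sets are optimized, and core regions
are far tighter than the fixtures'.  Passing tests therefore demonstrate
the correctness of the formulation and implementation at desk scale, not
production basis-set convergence; the Gaussian94 reader accepts real basis
files whenever the user supplies them.

For scaling probes the linear H-chain series is used with pruning disabled
so point counts grow exactly linearly; the probe reports formal operation
counts of the executed contractions (never wall time), with chain lengths
4, 8, 16 as the default series.

## Known limitations

* Closed-shell references only; no effective core potentials, point-group
  symmetry, gradients, or open-shell/CCSD-type extensions.
* Angular momenta through $d$; higher shells raise a capability error.
* The direct-type intermediates are obtained from the same engine paths
  with direct pairings and are validated against the dense oracle, but no
  production-optimized direct-type formulation is attempted.
* Dense algebra throughout: the asymptotic sparsity exploits of
  block-sparse AO contractions are out of scope at desk scale.
* The `df_only` comparator resolves the three-electron terms with an
  additional CABS-RI insertion, so it carries a small RI error relative to
  the CABS-free hybrid path (a few $10^{-6}$ hartree on the fixtures).
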