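# f12quad

Seminumerical evaluation of the exchange-type intermediates of the
closed-shell MP2-F12(3C/FIX) correction.

## What this is for

Explicitly correlated (F12) methods cure the painfully slow basis-set
convergence of MP2 correlation energies by augmenting the doubles space
with geminals `F12 |ij>` built from a Slater-type correlation factor
`F12 = exp(-γ r12)/γ`.  The price is a set of involved pair
intermediates,

```
V_ij,kl = <ij| F12 Q12 g12        |kl>
X_ij,kl = <ij| F12 Q12 F12        |kl>
B_ij,kl = <ij| F12 Q12 (f1+f2) Q12 F12 |kl>
```

with `g12 = 1/r12`, the strong-orthogonality projector
`Q12 = (1-o1)(1-o2)(1-v1v2)` and the Fock operator `f`.  Their
exchange-type index patterns are the cost bottleneck of the whole
correction: evaluated with density fitting (DF) and the CABS resolution of
the identity alone they scale as O(M⁵) with system size.

This package implements the hybrid **NQ/DF/CABS-RI** evaluation of V, X
and B: three-electron integrals and one factor of every 4c2e product are
decomposed over a Becke-partitioned molecular quadrature grid (NQ), the
remaining factors are density-fitted, and CABS-RI insertions are confined
to the B intermediate.  The formal scaling of the 4c2e products drops to
O(M⁴), which the package demonstrates with operation counters rather than
wall time.  V and X use the exact projector and remain entirely CABS-free.

Everything needed to run and to validate the method at desk scale is
included: a McMurchie–Davidson Gaussian integral engine with
Slater-geminal kernels (s/p/d), a minimal closed-shell RHF reference,
CABS construction by Löwdin orthogonalization, pruned molecular grids with
conservative distance screening, a purely density-fitted O(M⁵) comparator,
and a dense brute-force oracle (exact MO tensors + extensive unscreened
grids) against which every reformulated contraction is checked.

The intended audience is method developers who want a transparent,
fully-testable reference implementation of the seminumerical exchange-type
F12 machinery on small closed-shell systems — not a production code for
large molecules.

## Worked example

```r
library(f12quad)

sys <- generate_fixture("h2")        # H2 at 0.74 A with embedded bases
cfg <- run_config(grid_level = "g2") # gamma = 1.3, theta_NQ = 1e-10, ...
rep <- f12_energy(sys$molecule, sys, cfg)
print(rep)
```

```
F12(3C/FIX) correction [nq mode, grid g2]
  E_F12      = -0.005090639656 hartree
  E_SCF      = -1.128781477186 hartree
  V_d       =  0.007819436846
  V_x       =  0.007819436846
  X_d       =  0.000850922745
  X_x       =  0.000850922745
  B_d       =  0.009904489934
  B_x       =  0.009904489934
  X_eps_d   = -0.001010698825
  X_eps_x   = -0.001010698825
  grid points kept/dropped: 7332 / 1320
```

The correction is the pair sum
`-5/4 V_d + 1/4 V_x + 7/32 B_1 + 1/32 B_x - Σ(εi+εj)(7/32 X_1 + 1/32 X_x)`;
for H2 there is a single occupied pair, so the direct (`_d`) and exchange
(`_x`) patterns coincide and the correction collapses to
`-V + B/4 - 2ε₁X/4`.  It is negative (it recovers correlation energy the
orbital basis misses) and small here because the fixture basis is compact.
A dense brute-force reference for the same system,

```r
dn <- dense_reference(sys$molecule, sys, run_config(oracle_level = "g7"))
dn$energy$total            # -0.005089967864
```

agrees with the g4-grid production value to below 1e-6 hartree.
`summary(rep)` prints the per-term breakdown (FG term, occ-occ and
virt-virt products, 6c3e terms, commutator add-ons, U/T intermediates) and
the operation counters.  A command-line front end with the same
functionality is installed at `inst/scripts/f12quad`
(`compute`, `oracle`, `probe-scaling`, `audit-screening`, `fixtures`).

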