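# Reference state and orbital-space bookkeeping.

test_that("internal RHF matches an independent textbook implementation", {
  sys <- fix_sys("h2")
  ref <- fix_ref("h2")
  expect_lt(max(abs(t(ref$C) %*% ref$S %*% ref$C - diag(ncol(ref$C)))), 1e-9)
  psp <- ref$P %*% ref$S %*% ref$P
  expect_lt(max(abs(psp - ref$P)), 1e-8)

  # independent oracle: plain Roothaan iteration with explicit loops,
  # no DIIS, no shared code path beyond the integral primitives
  core <- core_hamiltonian(sys$obs)
  eri <- eri_4c2e(kernel_spec("G"), sys$obs)      # Dirac <mn|ls>
  n <- sys$obs$nao
  X <- with(eigen(core$S, symmetric = TRUE),
            vectors %*% diag(1 / sqrt(values)) %*% t(vectors))
  C <- X
  for (it in 1:200) {
    P <- tcrossprod(C[, 1, drop = FALSE])
    G <- matrix(0, n, n)
    for (m in 1:n) for (l in 1:n)
      G[m, l] <- sum((2 * eri[m, , l, ] - eri[m, , , l]) * P)
    f <- core$H + G
    ev <- eigen(t(X) %*% f %*% X, symmetric = TRUE)
    o <- order(ev$values)
    C <- X %*% ev$vectors[, o]
  }
  e_ind <- sum(P * (core$H + f)) + f12quad:::nuclear_repulsion(sys$molecule)
  expect_equal(ref$scf_energy, e_ind, tolerance = 1e-8)

  expect_error(compute_reference(
    molecule(c("H", "H"), sys$molecule$coords, multiplicity = 3L), sys$obs),
    "unsupported")
})

test_that("external reference providers are validated", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  ext <- compute_reference(sys$molecule, sys$obs,
                           backend = function(mol, obs)
                             list(C = ref$C, eps = ref$eps,
                                  scf_energy = ref$scf_energy))
  expect_equal(ext$scf_energy, ref$scf_energy)
  # a non-canonical provider (swapped orbitals break f-diagonality) is refused
  Cbad <- ref$C
  Cbad[, 1:2] <- Cbad[, 1:2] %*% matrix(c(0.8, 0.6, -0.6, 0.8), 2)
  expect_error(compute_reference(sys$molecule, sys$obs,
                                 backend = function(mol, obs)
                                   list(C = Cbad, eps = ref$eps)),
               "non-canonical")
})

test_that("CABS construction: orthogonality, completeness, degeneracies", {
  sys <- fix_sys("h2")
  ref <- fix_ref("h2")
  cab <- build_cabs(sys$obs, sys$cabs_aux, ref)
  sp <- fix_spaces("h2")
  # occupied orthogonal to CABS; CABS orthonormal in the union metric
  Ccab <- sp$C[, sp$idx$cabs, drop = FALSE]
  expect_lt(max(abs(t(sp$C[, sp$idx$occ, drop = FALSE]) %*% sp$S_union %*%
                      Ccab)), 1e-8)
  expect_lt(max(abs(t(Ccab) %*% sp$S_union %*% Ccab -
                      diag(ncol(Ccab)))), 1e-8)
  expect_equal(length(sp$idx$all),
               length(sp$idx$p) + length(sp$idx$cabs))
  # union completeness: any union-space vector is reproduced by the p' span
  v <- sp$S_union %*% sp$C[, 3, drop = FALSE]
  proj <- sp$S_union %*% sp$C %*% (t(sp$C) %*% v)
  expect_lt(max(abs(proj - v)), 1e-8)

  # auxiliary identical to the orbital basis adds no span
  cab0 <- build_cabs(sys$obs, sys$obs, ref)
  expect_equal(cab0$n_cabs, 0L)
  expect_gt(cab0$n_dropped, 0L)
})

test_that("space assembly: frozen core, GBC zeroing, single-pair He", {
  sys <- fix_sys("h2o")
  ref <- fix_ref("h2o")
  cab <- build_cabs(sys$obs, sys$cabs_aux, ref)
  sp0 <- assemble_spaces(ref, cab, frozen_core = 0L)
  expect_identical(sp0$idx$act, sp0$idx$occ)
  sp1 <- assemble_spaces(ref, cab, frozen_core = 1L)
  expect_equal(length(sp1$idx$act) + 1L, length(sp1$idx$occ))
  expect_error(assemble_spaces(ref, cab, frozen_core = 10L),
               "invalid configuration")
  # GBC/EBC: Fock blocks between occ+virt and CABS exactly zero
  expect_identical(max(abs(sp0$f_mo[sp0$idx$p, sp0$idx$cabs])), 0)
  spn <- assemble_spaces(ref, cab, gbc_ebc = FALSE)
  expect_gt(max(abs(spn$f_mo[spn$idx$p, spn$idx$cabs])), 0)

  sp_he <- fix_spaces("he_min")
  expect_equal(length(sp_he$idx$occ), 1L)
  expect_equal(length(sp_he$idx$virt), 0L)
})
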