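# The integral engine is validated against closed forms and an independent
# real-space quadrature oracle (trapezoidal product mesh; exponentially
# convergent for Gaussian integrands).

.mk_shell_basis <- function(mol, specs) {
  shells <- lapply(specs, function(s)
    list(l = s$l, center = s$center, exponents = s$e, coefficients = s$c))
  basis_set(shells, mol, role = "orbital")
}

test_that("4c2e closed forms and permutational symmetry hold", {
  he <- molecule("He", matrix(0, 1, 3))
  b1 <- .mk_shell_basis(he, list(list(l = 0L, center = 1L, e = 1.0, c = 1.0)))
  eri <- eri_4c2e(kernel_spec("G"), b1)
  expect_equal(eri[1, 1, 1, 1], 2 / sqrt(pi), tolerance = 1e-12)

  sys <- fix_sys("h2")
  for (op in c("G", "F", "FG", "F2")) {
    t4 <- eri_4c2e(kernel_spec(op, 1.3), sys$obs)
    # Dirac tensor symmetries of real integrals: particle exchange and
    # bra/ket transposition
    expect_lt(max(abs(t4 - aperm(t4, c(2, 1, 4, 3)))), 1e-10)
    expect_lt(max(abs(t4 - aperm(t4, c(3, 4, 1, 2)))), 1e-10)
  }

  # large-exponent limit of the correlation factor
  tF <- eri_4c2e(kernel_spec("F", 60), b1)
  expect_lt(abs(tF[1, 1, 1, 1]), 2e-4)
  expect_lt(abs(tF[1, 1, 1, 1]) / (1 / 60), 1)  # vanishes faster than 1/gamma
})

test_that("mixed s/p/d integrals match an independent quadrature oracle", {
  mol <- molecule(c("He", "He", "He"),
                  rbind(c(0, 0, 0), c(0.9, -0.4, 0.7), c(0.2, 0.5, -0.3)))
  bs <- .mk_shell_basis(mol, list(
    list(l = 0L, center = 1L, e = c(1.3, 0.4), c = c(0.7, 0.5)),
    list(l = 1L, center = 2L, e = 0.9, c = 1.0),
    list(l = 2L, center = 3L, e = 0.65, c = 1.0)))
  kern <- kernel_spec("FG", 1.1)
  h <- 0.22
  pts1 <- seq(-6.8, 6.8, by = h)
  gp <- as.matrix(expand.grid(pts1, pts1, pts1))
  amps <- eval_aos(list(points = gp), bs)
  blk <- grid_3c1e(kern, list(points = gp), bs, bs)    # (g|O|mu nu)
  eri <- eri_4c2e(kern, bs)                            # <mu nu|O|la si>
  # <a b | O | c d> = int chi_a chi_c (r1) (r1 | O | b d)
  for (el in list(c(1, 2, 1, 5), c(2, 10, 3, 6), c(5, 9, 4, 4))) {
    num <- sum(amps[, el[1]] * amps[, el[3]] * blk[, el[2], el[4]]) * h^3
    expect_equal(eri[el[1], el[2], el[3], el[4]], num, tolerance = 1e-7)
  }
})

test_that("grid kernels obey the point-charge closed form and decay", {
  he <- molecule("He", matrix(0, 1, 3))
  a <- 0.85
  b1 <- .mk_shell_basis(he, list(list(l = 0L, center = 1L, e = a, c = 1.0)))
  blk <- grid_3c1e(kernel_spec("G"), list(points = matrix(0, 1, 3)), b1, b1)
  expect_equal(blk[1, 1, 1], 2 * sqrt(2 * a / pi), tolerance = 1e-12)

  far <- grid_3c1e(kernel_spec("F", 1.3),
                   list(points = matrix(c(0, 0, 50), 1, 3)), b1, b1)
  expect_lt(abs(far[1, 1, 1]), 1e-14)

  # Boys function against R's numeric integration
  for (x in c(0.3, 7.9, 41)) {
    ref <- vapply(0:6, function(m)
      stats::integrate(function(t) t^(2 * m) * exp(-x * t^2), 0, 1,
                       rel.tol = 1e-13)$value, numeric(1))
    expect_equal(drop(f12quad:::cpp_boys(6L, x)), ref, tolerance = 1e-12)
  }
})

test_that("DF metric behaves: scalar inverse, positivity, redundancy", {
  he <- molecule("He", matrix(0, 1, 3))
  one <- .mk_shell_basis(he, list(list(l = 0L, center = 1L, e = 0.8, c = 1.0)))
  m <- df_2c2e(kernel_spec("G"), one)
  expect_equal(m$Yinv[1, 1], 1 / m$Y[1, 1], tolerance = 1e-12)

  sys <- fix_sys("he")
  mf <- df_2c2e(kernel_spec("F", 1.3), sys$df_aux)
  expect_gt(min(eigen(mf$Y, symmetric = TRUE)$values), -1e-10)

  dup <- .mk_shell_basis(he, list(
    list(l = 0L, center = 1L, e = 0.8, c = 1.0),
    list(l = 0L, center = 1L, e = 0.8, c = 1.0)))
  md <- df_2c2e(kernel_spec("G"), dup)
  expect_equal(md$n_dropped, 1L)
  P <- md$Yinv %*% md$Y
  expect_lt(max(abs(P %*% P - P)), 1e-8)   # idempotent on the kept subspace
})

test_that("3c2e integrals: FG small-gamma limit and vacuous input", {
  he <- molecule("He", matrix(0, 1, 3))
  bs <- .mk_shell_basis(he, list(list(l = 0L, center = 1L, e = 0.9, c = 1.0),
                                 list(l = 1L, center = 1L, e = 0.5, c = 1.0)))
  aux <- .mk_shell_basis(he, list(list(l = 0L, center = 1L, e = 1.1, c = 1.0)))
  g <- 1e-3
  tFG <- df_3c2e(kernel_spec("FG", g), bs, bs, aux)
  tG <- df_3c2e(kernel_spec("G"), bs, bs, aux)
  expect_equal(g * tFG, tG, tolerance = 2e-3)

  empty <- structure(list(shells = list(), molecule = he, role = "orbital",
                          nao = 0L, norm = numeric(0)), class = "f12_basis")
  t0 <- df_3c2e(kernel_spec("G"), empty, bs, aux)
  expect_equal(dim(t0), c(0L, 4L, 1L))
})

test_that("AO-to-MO grid transformation is sub-batch invariant and exact", {
  sys <- fix_sys("he")
  pts <- matrix(rnorm(90, sd = 1.2), 30, 3)
  blk <- grid_3c1e(kernel_spec("F", 1.3), list(points = pts), sys$obs)
  n <- sys$obs$nao
  id <- mo_transform_3c1e(blk, diag(n), diag(n))
  expect_equal(id, blk, tolerance = 1e-14, ignore_attr = TRUE)
  C <- fix_ref("he")$C
  t16 <- mo_transform_3c1e(blk, C, C, sub_batch = 16L)
  tall <- mo_transform_3c1e(blk, C, C, sub_batch = 1000L)
  expect_lt(max(abs(t16 - tall)), 1e-13)
  # explicit-loop oracle for the occupied-occupied element
  o <- vapply(seq_len(30), function(g)
    sum(outer(C[, 1], C[, 1]) * blk[g, , ]), numeric(1))
  expect_equal(t16[, 1, 1], o, tolerance = 1e-12)
  expect_error(mo_transform_3c1e(blk, diag(3), diag(n)), "shape mismatch")
})
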