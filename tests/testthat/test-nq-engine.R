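# Generic contraction paths: MO/AO 6c3e chains, DF fitting, and the product
# evaluators, validated against explicit nested-loop oracles.

.const_kernel <- function(cval) {
  # near-constant synthetic kernel: a single ultra-diffuse Gaussian
  structure(list(op = "F", gamma = 1, n_stg = 1L,
                 components = matrix(c(1, 1e-12, cval), 1)),
            class = "f12_kernel")
}

.he_batch <- function(level = "g1") {
  sys <- fix_sys("he")
  g <- build_grid(sys$molecule, level, 0)
  list(sys = sys, batch = list(points = g$points, w = g$w), w = g$w)
}

test_that("MO 6c3e contraction equals an explicit-loop oracle", {
  hb <- .he_batch("g0")
  sys <- hb$sys
  ref <- fix_ref("he")
  Cocc <- ref$C[, 1, drop = FALSE]
  blkF <- grid_3c1e(kernel_spec("F", 1.3), hb$batch, sys$obs)
  blkG <- grid_3c1e(kernel_spec("G"), hb$batch, sys$obs)
  Fm <- mo_transform_3c1e(blkF, Cocc, Cocc)
  Gm <- mo_transform_3c1e(blkG, Cocc, Cocc)
  amps <- eval_aos(hb$batch, sys$obs)
  phi <- list(i = amps %*% Cocc, j = amps %*% Cocc)
  e <- contract_6c3e_mo(Fm, Gm, phi, hb$w)
  # explicit loop
  e_loop <- sum(hb$w * phi$i[, 1] * phi$j[, 1] * Fm[, 1, 1] * Gm[, 1, 1])
  expect_equal(e, e_loop, tolerance = 1e-12)
  expect_equal(contract_6c3e_mo(Fm, Gm, phi, 0 * hb$w), 0)
})

test_that("constant-kernel collapse reduces 6c3e to a 4c2e trace", {
  hb <- .he_batch("g2")
  sys <- hb$sys
  ref <- fix_ref("he")
  Cocc <- ref$C[, 1, drop = FALSE]
  cval <- 0.37
  blkF <- grid_3c1e(kernel_spec("F", 1.3), hb$batch, sys$obs)
  blkC <- grid_3c1e(.const_kernel(cval), hb$batch, sys$obs)
  Fm <- mo_transform_3c1e(blkF, Cocc, Cocc)
  Cm <- mo_transform_3c1e(blkC, Cocc, Cocc)
  amps <- eval_aos(hb$batch, sys$obs)
  phi <- list(i = amps %*% Cocc, j = amps %*% Cocc)
  e <- contract_6c3e_mo(Fm, Cm, phi, hb$w)
  # collapse: c * sum_ij <ij|F|ji> (here the single pair <11|F|11>)
  tF <- eri_4c2e(kernel_spec("F", 1.3), sys$obs)
  target <- cval * f12quad:::.mo4(tF, Cocc, Cocc, Cocc, Cocc)[1, 1, 1, 1]
  expect_equal(e, target, tolerance = 5e-4)
})

test_that("AO and MO 6c3e chains agree (change of representation)", {
  for (nm in c("he", "h2")) {
    sys <- fix_sys(nm)
    ref <- fix_ref(nm)
    g <- build_grid(sys$molecule, "g0", 0)
    batch <- list(points = g$points, w = g$w)
    nocc <- ref$nocc
    Cocc <- ref$C[, seq_len(nocc), drop = FALSE]
    P <- tcrossprod(Cocc)
    blkF <- grid_3c1e(kernel_spec("F", 1.3), batch, sys$obs)
    blkG <- grid_3c1e(kernel_spec("G"), batch, sys$obs)
    amps <- eval_aos(batch, sys$obs)
    e_ao <- contract_6c3e_ao(P, P, P, blkF, blkG, amps, g$w, "exchange")
    Fm <- mo_transform_3c1e(blkF, Cocc, Cocc)
    Gm <- mo_transform_3c1e(blkG, Cocc, Cocc)
    phi <- list(i = amps %*% Cocc, j = amps %*% Cocc)
    e_mo <- contract_6c3e_mo(Fm, Gm, phi, g$w)
    expect_lt(abs(e_ao - e_mo), 1e-11)
    # annihilating dressing
    expect_equal(contract_6c3e_ao(P, P, 0 * P, blkF, blkG, amps, g$w,
                                  "exchange"), 0)
  }
})

test_that("DF fitting: scalar fit, completeness on exact product spaces", {
  he <- molecule("He", matrix(0, 1, 3))
  bs <- basis_set(list(list(l = 0L, center = 1L, exponents = 0.9,
                            coefficients = 1),
                       list(l = 0L, center = 1L, exponents = 0.35,
                            coefficients = 1)), he)
  # auxiliary spanning the product space of the two s functions exactly
  aux <- basis_set(list(list(l = 0L, center = 1L, exponents = 1.8,
                             coefficients = 1),
                        list(l = 0L, center = 1L, exponents = 1.25,
                             coefficients = 1),
                        list(l = 0L, center = 1L, exponents = 0.7,
                             coefficients = 1)), he, role = "df_aux")
  for (op in c("F", "G", "FG", "F2")) {
    kern <- kernel_spec(op, 1.3)
    met <- df_2c2e(kern, aux)
    raw <- df_3c2e(kern, bs, bs, aux)
    fit <- df_fit_pairs(kern, raw, met$Yinv)
    fitted <- array(matrix(fit$coef, 4, 3) %*% t(matrix(raw, 4, 3)),
                    c(2, 2, 2, 2))                  # (ab|O|cd) Mulliken
    exact <- aperm(eri_4c2e(kern, bs), c(1, 3, 2, 4))
    expect_lt(max(abs(fitted - exact)), 1e-8)
    # fit invariant: coef . Y reproduces the raw integrals
    rec <- array(matrix(fit$coef, 4, 3) %*% met$Y, c(2, 2, 3))
    expect_lt(max(abs(rec - raw)), 1e-8)
  }
  # single-function fit is the scalar ratio
  one <- basis_set(list(list(l = 0L, center = 1L, exponents = 1.1,
                             coefficients = 1)), he, role = "df_aux")
  kern <- kernel_spec("G")
  m1 <- df_2c2e(kern, one)
  r1 <- df_3c2e(kern, bs, bs, one)
  f1 <- df_fit_pairs(kern, r1, m1$Yinv)
  expect_equal(f1$coef, r1 / m1$Y[1, 1], tolerance = 1e-12)
  # zero block gives zero coefficients
  f0 <- df_fit_pairs(kern, 0 * r1, m1$Yinv)
  expect_true(all(f0$coef == 0))
})

test_that("DF-only and hybrid NQ/DF products agree with the dense product", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  sp <- fix_spaces("he")
  cfg <- run_config()
  ctx <- f12quad:::.f12_ctx(sp, sys$df_aux, cfg)
  idx <- sp$idx
  # exact product sum_(ijkl) <ij|F|kl><kl|G|ji> from dense tensors
  C_occ <- ref$C[, 1, drop = FALSE]
  TF <- f12quad:::.mo4(eri_4c2e(ctx$kF, sys$obs), C_occ, C_occ, C_occ, C_occ)
  TG <- f12quad:::.mo4(eri_4c2e(ctx$kG, sys$obs), C_occ, C_occ, C_occ, C_occ)
  exact <- sum(TF[1, 1, , ] * TG[1, 1, , ])
  # DF-only comparator (F factor fitted, G factor fitted)
  aoG <- df_3c2e(ctx$kG, sp$union_basis, sp$union_basis, sys$df_aux)
  rawG <- f12quad:::.ctr_dim(f12quad:::.ctr_dim(aoG, sp$C, 1), sp$C, 2)
  metG <- df_2c2e(ctx$kG, sys$df_aux)
  Wfit <- structure(list(coef = ctx$fit3[idx$occ, idx$occ, , drop = FALSE],
                         raw = ctx$raw3[idx$occ, idx$occ, , drop = FALSE]),
                    class = "f12_dffit")
  fitG <- df_fit_pairs(ctx$kG, rawG, metG$Yinv)$coef
  Yfit <- structure(list(coef = fitG[idx$occ, idx$occ, , drop = FALSE],
                         raw = rawG[idx$occ, idx$occ, , drop = FALSE]),
                    class = "f12_dffit")
  e_df <- product_4c2e_df(Wfit, Yfit, "exchange")
  expect_equal(e_df, exact, tolerance = 1e-6)
  # single-MO system: exchange and direct patterns coincide
  expect_equal(product_4c2e_df(Wfit, Yfit, "direct"), e_df,
               tolerance = 1e-12)

  # hybrid path on a fine grid approaches the same value
  g <- build_grid(sys$molecule, "g3", 0)
  batch <- list(points = g$points, w = g$w)
  blkG <- grid_3c1e(ctx$kG, batch, sys$obs)
  Gm <- mo_transform_3c1e(blkG, C_occ, C_occ)
  amps <- eval_aos(batch, sys$obs)
  phi <- list(i = amps %*% C_occ, k = amps %*% C_occ)
  e_nq16 <- product_4c2e_nq_df(Gm, Wfit, phi, g$w, 16L, "exchange")
  expect_equal(e_nq16, e_df, tolerance = 1e-6)
  # auxiliary batching invariance
  e_nq_all <- product_4c2e_nq_df(Gm, Wfit, phi, g$w, 10000L, "exchange")
  expect_lt(abs(e_nq16 - e_nq_all), 1e-12)
  expect_error(product_4c2e_nq_df(Gm, Wfit, phi, g$w, 0L), "aux_batch")
  # zero grid factor gives zero
  expect_equal(product_4c2e_nq_df(0 * Gm, Wfit, phi, g$w, 16L, "exchange"), 0)
})

test_that("the quadrature may sit on either factor (placement regression)", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  sp <- fix_spaces("he")
  ctx <- f12quad:::.f12_ctx(sp, sys$df_aux, run_config())
  C_occ <- ref$C[, 1, drop = FALSE]
  idx <- sp$idx
  aoG <- df_3c2e(ctx$kG, sp$union_basis, sp$union_basis, sys$df_aux)
  rawG <- f12quad:::.ctr_dim(f12quad:::.ctr_dim(aoG, sp$C, 1), sp$C, 2)
  fitG <- df_fit_pairs(ctx$kG, rawG, df_2c2e(ctx$kG, sys$df_aux)$Yinv)$coef
  Wfit <- structure(list(coef = ctx$fit3[idx$occ, idx$occ, , drop = FALSE],
                         raw = ctx$raw3[idx$occ, idx$occ, , drop = FALSE]),
                    class = "f12_dffit")
  Yfit <- structure(list(coef = fitG[idx$occ, idx$occ, , drop = FALSE],
                         raw = rawG[idx$occ, idx$occ, , drop = FALSE]),
                    class = "f12_dffit")
  vals <- sapply(c("g1", "g3"), function(lev) {
    g <- build_grid(sys$molecule, lev, 0)
    batch <- list(points = g$points, w = g$w)
    amps <- eval_aos(batch, sys$obs)
    phi <- list(i = amps %*% C_occ, k = amps %*% C_occ)
    Gm <- mo_transform_3c1e(grid_3c1e(ctx$kG, batch, sys$obs), C_occ, C_occ)
    Fm <- mo_transform_3c1e(grid_3c1e(ctx$kF, batch, sys$obs), C_occ, C_occ)
    c(onG = product_4c2e_nq_df(Gm, Wfit, phi, g$w, 16L, "exchange"),
      onF = product_4c2e_nq_df(Fm, Yfit, phi, g$w, 16L, "exchange"))
  })
  # both placements converge to the same limit as the grid refines
  expect_lt(abs(vals["onG", "g3"] - vals["onF", "g3"]),
            abs(vals["onG", "g1"] - vals["onF", "g1"]) + 1e-9)
  expect_lt(abs(vals["onG", "g3"] - vals["onF", "g3"]), 2e-5)
})
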