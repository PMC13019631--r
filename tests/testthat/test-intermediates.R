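# Intermediate builders: seminumerical FG/F2 terms, projector reduction,
# V/X/B assembly against the dense brute-force reference.

.batches_for <- function(nm, level, cap = 64L) {
  sys <- fix_sys(nm)
  g <- build_grid(sys$molecule, level, 0)
  make_batches(g, sys$obs, cap)
}

test_that("the FG term matches the exact 4c2e integral on a fine grid", {
  sys <- fix_sys("he")
  sp <- fix_spaces("he")
  bat <- .batches_for("he", "g3")
  a1 <- algorithm1_fg(sp, bat, theta_nq = 0)
  C1 <- fix_ref("he")$C[, 1, drop = FALSE]
  exact <- f12quad:::.mo4(eri_4c2e(kernel_spec("FG", 1.3), sys$obs),
                          C1, C1, C1, C1)[1, 1, 1, 1]
  expect_equal(a1$x, exact, tolerance = 1e-6)
  expect_equal(a1$d, exact, tolerance = 1e-6)    # single pair
  # zero density annihilates the term
  z <- matrix(0, sys$obs$nao, sys$obs$nao)
  a0 <- algorithm1_fg(sp, bat, theta_nq = 0, P_i = z, P_j = z)
  expect_equal(a0$x, 0)
  # batch-cap invariance of a single term
  a64 <- algorithm1_fg(sp, .batches_for("he", "g1", 64L), theta_nq = 0)
  aall <- algorithm1_fg(sp, .batches_for("he", "g1", 100000L), theta_nq = 0)
  expect_lt(abs(a64$x - aall$x), 1e-11)
})

test_that("Algorithm 2 satisfies the gradient-square identity", {
  sys <- fix_sys("h2")
  sp <- fix_spaces("h2")
  ctx <- f12quad:::.f12_ctx(sp, sys$df_aux, run_config())
  bat <- .batches_for("h2", "g1")
  a2 <- algorithm2_f2(sp, bat, 1e-10, run_config(), ctx)
  # the gradient-square term is exactly gamma^2 times the F2 term
  expect_equal(a2$grad_sq$x, 1.3^2 * a2$f2$x, tolerance = 1e-12)
  expect_equal(a2$grad_sq$d, 1.3^2 * a2$f2$d, tolerance = 1e-12)
})

test_that("projector reduction equals Q f Q on random model spaces", {
  set.seed(42)
  qfq <- reduce_qfq()
  expect_equal(sum(!qfq$expansion$annihilated), 19L)
  for (rep in 1:10) {
    Qm <- qr.Q(qr(matrix(rnorm(64), 8)))
    o <- tcrossprod(Qm[, 1:2]); v <- tcrossprod(Qm[, 3:5])
    f0 <- matrix(rnorm(64), 8); f0 <- (f0 + t(f0)) / 2
    f <- f0 - o %*% f0 %*% v - v %*% f0 %*% o
    expect_lt(max(abs(qfq_eval_terms(qfq, f, o, v) - qfq_direct(f, o, v))),
              1e-12)
  }
  # degenerate projectors
  z <- matrix(0, 8, 8)
  f0 <- matrix(rnorm(64), 8); f <- (f0 + t(f0)) / 2
  o <- tcrossprod(qr.Q(qr(matrix(rnorm(64), 8)))[, 1:3])
  expect_lt(max(abs(qfq_eval_terms(qfq, f, o, z) - qfq_direct(f, o, z))),
            1e-12)
  expect_lt(max(abs(qfq_eval_terms(qfq, f, z, z) - f12quad:::.kron2(f, diag(8)))),
            1e-12)
})

test_that("V/X assembly: empty virtual space and kernel substitution", {
  sys <- fix_sys("he_min")
  sp <- fix_spaces("he_min")
  cfg <- run_config()
  ctx <- f12quad:::.f12_ctx(sp, sys$df_aux, cfg)
  bat <- .batches_for("he_min", "g1")
  vx <- build_vx(sp, bat, ctx, 1e-10, cfg)
  expect_equal(vx$terms$term_vv_prod_x, 0)   # no virtuals: both vv products vanish
  expect_equal(vx$terms$term_x_vv_prod_x, 0)
  # X with unit energy weights is the (F,F) kernel substitution of V:
  # compare against the dense X (same formulas, exact integrals)
  dn <- fix_dense("he_min", "g2")
  nq <- fix_nq("he_min", "g2")
  expect_equal(nq$parts[["X_x"]], sum(dn$X_x), tolerance = 2e-6)
})

test_that("production V, X, B match the dense oracle (He, H2)", {
  for (nm in c("he", "h2")) {
    dn <- fix_dense(nm, "g3")
    nq <- fix_nq(nm, "g3")
    expect_lt(abs(nq$parts[["V_x"]] - sum(dn$V_x)), 2e-6)
    expect_lt(abs(nq$parts[["X_x"]] - sum(dn$X_x)), 2e-6)
    expect_lt(abs(nq$parts[["B_x"]] - sum(dn$B_x)), 2e-6)
    expect_lt(abs(nq$parts[["V_d"]] - sum(dn$V_d)), 2e-6)
    expect_lt(abs(nq$parts[["B_d"]] - sum(dn$B_d)), 2e-6)
    expect_lt(abs(nq$parts[["X_eps_x"]] -
                    sum(outer(dn$eps_act, dn$eps_act, `+`) * dn$X_x)), 2e-6)
  }
})

test_that("B is linear in the Fock operator and tracks its dressings", {
  sys <- fix_sys("he")
  sp <- fix_spaces("he")
  cfg <- run_config()
  bat <- .batches_for("he", "g1")
  ctx <- f12quad:::.f12_ctx(sp, sys$df_aux, cfg)
  a2 <- algorithm2_f2(sp, bat, 1e-10, cfg, ctx)
  b1 <- build_b(sp, bat, ctx, 1e-10, cfg, alg2 = a2)
  # doubled Fock and exchange operators double every ingredient
  sp2 <- sp
  sp2$f_mo <- 2 * sp$f_mo; sp2$k_mo <- 2 * sp$k_mo
  sp2$f_ao <- 2 * sp$f_ao; sp2$k_ao <- 2 * sp$k_ao
  ctx2 <- f12quad:::.f12_ctx(sp2, sys$df_aux, cfg)
  a2b <- algorithm2_f2(sp2, bat, 1e-10, cfg, ctx2)
  a2b$grad_sq$x <- 2 * a2$grad_sq$x      # the kinetic-commutator part of f
  a2b$grad_sq$d <- 2 * a2$grad_sq$d
  b2 <- build_b(sp2, bat, ctx2, 1e-10, cfg, alg2 = a2b)
  expect_equal(b2$B_x, 2 * b1$B_x, tolerance = 1e-10)
  expect_equal(b2$B_d, 2 * b1$B_d, tolerance = 1e-10)
})

test_that("commutator level none omits exactly the two add-on terms", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  cfg_full <- run_config(grid_level = "g1")
  cfg_none <- run_config(grid_level = "g1", commutator_level = "none")
  r1 <- f12_energy(sys$molecule, sys, cfg_full, reference = ref)
  r0 <- f12_energy(sys$molecule, sys, cfg_none, reference = ref)
  expect_equal(r1$parts[["B_x"]] - r0$parts[["B_x"]],
               r1$commutator_delta, tolerance = 1e-12)
  expect_equal(r0$commutator_delta, 0)
})

test_that("scaling separation shows on a small chain pair", {
  pr <- flop_probe(c(4, 8))
  expect_lt(pr$hybrid_exponents[1], 4.2)
  expect_gt(pr$df_only_exponents[1], 4.6)
  # dominant counter of the hybrid B pass is the p' contraction
  expect_identical(flop_probe(4)$hybrid_exponents, numeric(0))
})
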