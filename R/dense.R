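# Dense brute-force reference: pair-resolved V, X, B exchange- and
# direct-pattern intermediates from exact (non-fitted, non-DF) MO 4c2e
# integrals, with the genuinely three-electron contributions evaluated on an
# extensive unscreened quadrature grid.  This is an independent code path
# from the production engine (MO-picture tensor algebra versus AO-picture
# batched/screened/density-fitted contractions); only the primitive integral
# kernels are shared.

#' Dense reference evaluation of the exchange-type intermediates
#'
#' @param molecule closed-shell molecule
#' @param bases list with `obs` and `cabs_aux` (`df_aux` is ignored: the
#'   oracle uses exact integrals)
#' @param config `f12_config`; `oracle_level` selects the reference grid and
#'   the projector is the exact one unless `approx_projector`
#' @param approx_projector evaluate V (and X) with the approximate
#'   strong-orthogonality projector `1 - p1 p2 - o1 p2" - p1" o2` instead of
#'   the exact operator (two-protocol comparisons)
#' @param reference optional precomputed `f12_reference`
#' @return object of class `f12_dense` with pair-resolved intermediates and
#'   the assembled correction
#' @export
dense_reference <- function(molecule, bases, config = run_config(),
                            approx_projector = FALSE, reference = NULL) {
  obs <- bases$obs
  if (obs$nao > 40L)
    stop("oracle unavailable: dense reference is guarded to <= 40 AOs (got ",
         obs$nao, ")")
  ref <- if (is.null(reference)) compute_reference(molecule, obs) else reference
  cab <- build_cabs(obs, bases$cabs_aux, ref)
  sp <- assemble_spaces(ref, cab, frozen_core = config$frozen_core,
                        gbc_ebc = config$gbc_ebc)
  g <- config$gamma
  kF <- kernel_spec("F", g, config$n_stg)
  kG <- kernel_spec("G", g, config$n_stg)
  kFG <- kernel_spec("FG", g, config$n_stg)
  kF2 <- kernel_spec("F2", g, config$n_stg)

  idx <- sp$idx
  nact <- length(idx$act); nocc <- length(idx$occ); nvirt <- length(idx$virt)
  nu <- length(idx$all)
  C_act <- .coef_block_obs(sp, "act")
  C_occ <- .coef_block_obs(sp, "occ")
  C_virt <- .coef_block_obs(sp, "virt")
  C_all <- sp$C
  ub <- sp$union_basis
  eps_act <- sp$eps[idx$act]
  kl_idx <- if (identical(config$occ_products, "active")) idx$act else idx$occ
  C_kl <- .coef_block_obs(sp, if (identical(config$occ_products, "active"))
    "act" else "occ")
  nkl <- ncol(C_kl)

  # ---- exact MO tensors --------------------------------------------------
  eriFG <- eri_4c2e(kFG, obs)
  T_FG <- .mo4(eriFG, C_act, C_act, C_act, C_act)
  eriG <- eri_4c2e(kG, obs)
  TG_o <- .mo4(eriG, C_act, C_act, C_kl, C_kl)
  TG_v <- if (nvirt > 0) .mo4(eriG, C_act, C_act, C_virt, C_virt) else NULL
  eriF <- eri_4c2e(kF, obs)
  TF_o <- .mo4(eriF, C_act, C_act, C_kl, C_kl)
  TF_v <- if (nvirt > 0) .mo4(eriF, C_act, C_act, C_virt, C_virt) else NULL
  rm(eriFG)

  eriF_u <- eri_4c2e(kF, ub)
  C_act_u <- .coef_block(sp, "act")
  C_occ_u <- .coef_block(sp, "occ")
  C_virt_u <- .coef_block(sp, "virt")
  TF_u1 <- .mo4(eriF_u, C_act_u, C_act_u, C_all, C_occ_u)   # <ij|F|p'm>
  TF_u2 <- if (nvirt > 0)
    .mo4(eriF_u, C_act_u, C_act_u, C_all, C_virt_u) else NULL  # <ij|F|p'c>
  rm(eriF_u)
  eriF2_u <- eri_4c2e(kF2, ub)
  TF2_a <- .mo4(eriF2_u, C_all, C_act_u, C_act_u, C_act_u)  # <p'j|F2|xy>
  rm(eriF2_u)

  pairx <- function(T4) {  # T[i,j,j,i]
    m <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) m[i, j] <- T4[i, j, j, i]
    m
  }
  paird <- function(T4) {
    m <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) m[i, j] <- T4[i, j, i, j]
    m
  }

  FG_x <- pairx(T_FG); FG_d <- paird(T_FG)
  u_act <- idx$act
  F2_x <- matrix(0, nact, nact); F2_d <- matrix(0, nact, nact)
  for (i in seq_len(nact)) for (j in seq_len(nact)) {
    F2_x[i, j] <- TF2_a[u_act[i], j, j, i]
    F2_d[i, j] <- TF2_a[u_act[i], j, i, j]
  }

  prod_pair <- function(TA, TB) {
    # sum_kl <ij|A|kl><kl|B|ji> and <ij|A|kl><kl|B|ij>
    ex <- matrix(0, nact, nact); dr <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      ex[i, j] <- sum(TA[i, j, , ] * TB[j, i, , ])
      dr[i, j] <- sum(TA[i, j, , ] * TB[i, j, , ])
    }
    list(x = ex, d = dr)
  }
  oo_FG <- prod_pair(TF_o, TG_o)
  vv_FG <- if (nvirt > 0) prod_pair(TF_v, TG_v) else
    list(x = matrix(0, nact, nact), d = matrix(0, nact, nact))
  oo_FF <- prod_pair(TF_o, TF_o)
  vv_FF <- if (nvirt > 0) prod_pair(TF_v, TF_v) else
    list(x = matrix(0, nact, nact), d = matrix(0, nact, nact))

  # ---- fine-grid 6c3e contributions -------------------------------------
  grid <- build_grid(molecule, config$oracle_level, 0)
  z <- function() matrix(0, nact, nact)
  V6 <- z(); V6d <- z(); X6 <- z(); X6d <- z()
  B62 <- z(); B62d <- z(); B63 <- z(); B63d <- z(); B64 <- z(); B64d <- z()
  f_u <- sp$f_mo; k_u <- sp$k_mo
  f_occ_cols <- f_u[, idx$occ, drop = FALSE]
  f_oo <- f_u[idx$occ, idx$occ, drop = FALSE]
  sl <- function(A, i) matrix(A[, i, ], nrow = dim(A)[1])  # keep 2-d shape
  chunks <- split(seq_len(grid$n_kept), ceiling(seq_len(grid$n_kept) / 2048))
  for (ii in chunks) {
    pts <- grid$points[ii, , drop = FALSE]
    w <- grid$w[ii]
    amps <- cpp_eval_aos(obs$cpp, pts) * rep(obs$norm, each = length(ii))
    amps_u <- cpp_eval_aos(ub$cpp, pts) * rep(ub$norm, each = length(ii))
    phi_a <- amps %*% C_act
    aoF <- grid_3c1e(kF, list(points = pts), obs, ub, 0)
    Fu <- .ctr3(.ctr3(aoF, C_act, 2), C_all, 3)        # (g, act, p')
    Fk <- Fu[, , kl_idx, drop = FALSE]                 # (g, act, occ/kl)
    aoG <- grid_3c1e(kG, list(points = pts), obs, obs, 0)
    Gk <- .ctr3(.ctr3(aoG, C_act, 2), C_kl, 3)
    H62 <- .ctr3(Fu, k_u, 3)
    H63 <- .ctr3(Fu, f_occ_cols, 3)
    Foc <- Fu[, , idx$occ, drop = FALSE]
    H64 <- .ctr3(Foc, f_oo, 3)
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      pij <- w * phi_a[, i] * phi_a[, j]
      pjj <- w * phi_a[, j]^2
      V6[i, j] <- V6[i, j] + sum(pij * rowSums(sl(Fk, i) * sl(Gk, j)))
      V6d[i, j] <- V6d[i, j] + sum(pjj * rowSums(sl(Fk, i) * sl(Gk, i)))
      X6[i, j] <- X6[i, j] + sum(pij * rowSums(sl(Fk, i) * sl(Fk, j)))
      X6d[i, j] <- X6d[i, j] + sum(pjj * rowSums(sl(Fk, i) * sl(Fk, i)))
      B62[i, j] <- B62[i, j] + sum(pij * rowSums(sl(H62, i) * sl(Fu, j)))
      B62d[i, j] <- B62d[i, j] + sum(pjj * rowSums(sl(H62, i) * sl(Fu, i)))
      B63[i, j] <- B63[i, j] + sum(pij * rowSums(sl(Foc, i) * sl(H63, j)))
      B63d[i, j] <- B63d[i, j] + sum(pjj * rowSums(sl(Foc, i) * sl(H63, i)))
      B64[i, j] <- B64[i, j] + sum(pij * rowSums(sl(Foc, i) * sl(H64, j)))
      B64d[i, j] <- B64d[i, j] + sum(pjj * rowSums(sl(Foc, i) * sl(H64, i)))
    }
  }

  # ---- U / T sub-intermediates from exact tensors ------------------------
  ut_pair <- function(T1, fmat, rows, cols) {
    # T1 = <ij|F|s1 s2>; returns pair-resolved
    #   ex[i,j] = sum_{s1 in rows, r in cols, s2} T1[i,j,s1,s2] f[s1,r] T1[j,i,r,s2]
    #   dr[i,j] = same with T1[i,j,r,s2]
    Ts <- T1[, , rows, , drop = FALSE]
    A <- .ctr_dim(Ts, fmat[rows, cols, drop = FALSE], 3)  # (i,j,cols,s2)
    Tr <- T1[, , cols, , drop = FALSE]
    ex <- z(); dr <- z()
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      ex[i, j] <- sum(A[i, j, , ] * Tr[j, i, , ])
      dr[i, j] <- sum(A[i, j, , ] * Tr[i, j, , ])
    }
    list(x = ex, d = dr)
  }
  U65 <- ut_pair(TF_u1, f_u, idx$all, idx$all)
  U66 <- ut_pair(TF_u1, f_u, idx$all, idx$occ)
  U67 <- ut_pair(TF_u1, f_u, idx$occ, idx$occ)
  if (nvirt > 0) {
    T68 <- ut_pair(TF_u2, f_u, idx$all, idx$virt)
    T69 <- ut_pair(TF_u2, f_u, idx$virt, idx$virt)
  } else {
    T68 <- T69 <- list(x = z(), d = z())
  }

  # ---- single-RI (f+k) F^2 term ------------------------------------------
  fk <- f_u + k_u
  E61x <- z(); E61d <- z()
  for (i in seq_len(nact)) for (j in seq_len(nact)) {
    E61x[i, j] <- sum(fk[u_act[i], ] * TF2_a[, j, j, i])
    E61d[i, j] <- sum(fk[u_act[i], ] * TF2_a[, j, i, j])
  }

  # ---- assemble pair-resolved intermediates ------------------------------
  sym6 <- function(m) m + t(m)
  V_x <- FG_x + oo_FG$x - vv_FG$x - sym6(V6)
  V_d <- FG_d + oo_FG$d - vv_FG$d - (V6d + t(V6d))
  X_x <- F2_x + oo_FF$x - vv_FF$x - sym6(X6)
  X_d <- F2_d + oo_FF$d - vv_FF$d - (X6d + t(X6d))

  commut <- config$commutator_level == "full"
  b_half <- function(F2m, B62m, E61m, U65m, E63m, E63t, U66m, U66t,
                     T68m, T68t, B64m, U67m, T69m) {
    f1 <- -B62m + if (commut) 0.5 * g^2 * F2m + E61m else 0
    f1 - U65m - (E63m + E63t) + (U66m + U66t) - (T68m + T68t) +
      B64m - U67m + T69m
  }
  B_half_x <- b_half(F2_x, B62, E61x, U65$x, B63, t(B63), U66$x, t(U66$x),
                     T68$x, t(T68$x), B64, U67$x, T69$x)
  B_half_d <- b_half(F2_d, B62d, E61d, U65$d, B63d, B63d, U66$d, U66$d,
                     T68$d, T68$d, B64d, U67$d, T69$d)
  B_x <- B_half_x + t(B_half_x)
  B_d <- B_half_d + t(B_half_d)

  # ---- optional approximate-projector V/X --------------------------------
  approx <- NULL
  if (approx_projector) {
    eriG_u <- eri_4c2e(kG, ub)
    TGp <- .mo4(eriG_u, C_act_u, C_act_u, C_all, C_all)
    TFp <- .mo4(eri_4c2e(kF, ub), C_act_u, C_act_u, C_all, C_all)
    Vx_a <- z()
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      s_pp <- sum(TFp[i, j, idx$p, idx$p] * TGp[j, i, idx$p, idx$p])
      s_oc <- if (length(idx$cabs))
        sum(TFp[i, j, idx$occ, idx$cabs] * TGp[j, i, idx$occ, idx$cabs]) +
        sum(TFp[i, j, idx$cabs, idx$occ] * TGp[j, i, idx$cabs, idx$occ]) else 0
      Vx_a[i, j] <- FG_x[i, j] - s_pp - s_oc
    }
    approx <- list(V_x = Vx_a)
  }

  terms <- list(
    FG_x = sum(FG_x), FG_d = sum(FG_d),
    oo_FG_x = sum(oo_FG$x), vv_FG_x = sum(vv_FG$x),
    six_V_x = sum(sym6(V6)), six_X_x = sum(sym6(X6)),
    F2_x = sum(F2_x), E61_x = sum(E61x), B62_x = sum(sym6(B62)),
    B63_x = sum(B63 + t(B63)), B64_x = sum(sym6(B64)),
    U65_x = sum(U65$x), U66_x = sum(U66$x), U67_x = sum(U67$x),
    T68_x = sum(T68$x), T69_x = sum(T69$x))

  res <- structure(list(
    spaces = sp, config = config, grid_level = config$oracle_level,
    V_x = V_x, V_d = V_d, X_x = X_x, X_d = X_d, B_x = B_x, B_d = B_d,
    eps_act = eps_act, terms = terms, approx = approx,
    pair6 = list(V6 = V6, X6 = X6)),
    class = "f12_dense")
  res$energy <- .assemble_eq10(res$V_d, res$V_x, res$X_d, res$X_x,
                               res$B_d, res$B_x, eps_act,
                               config$b_direct_fix)
  res
}

# Energy assembly: E = sum over active pairs of
#   -5/4 V_dir + 1/4 V_x + 7/32 B_first + 1/32 B_x
#   - (eps_i + eps_j) (7/32 X_first + 1/32 X_x)
# with the "first" pattern direct under b_direct_fix, exchange otherwise.
# The V coefficients are the spin-summed linear terms of the fixed-amplitude
# functional with the s/p-wave coalescence amplitudes (-3/8, -1/8) that
# belong to the positive-defined correlation factor exp(-g r)/g; the B and X
# coefficients are the corresponding quadratic terms.
.assemble_eq10 <- function(V_d, V_x, X_d, X_x, B_d, B_x, eps_act,
                           b_direct_fix = TRUE) {
  epm <- outer(eps_act, eps_act, `+`)
  B_first <- if (b_direct_fix) B_d else B_x
  X_first <- if (b_direct_fix) X_d else X_x
  pair_e <- -5 / 4 * V_d + 1 / 4 * V_x + 7 / 32 * B_first + 1 / 32 * B_x -
    epm * (7 / 32 * X_first + 1 / 32 * X_x)
  list(total = sum(pair_e), pair = pair_e,
       parts = c(V_d = sum(V_d), V_x = sum(V_x), X_d = sum(X_d),
                 X_x = sum(X_x), B_d = sum(B_d), B_x = sum(B_x),
                 X_eps_d = sum(epm * X_d), X_eps_x = sum(epm * X_x)))
}
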