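# Assembly of the exchange-type V, X and B intermediates from the engine
# contraction paths.  Each builder loops over the grid batches, evaluates
# its terms through the generic 6c3e / product paths, and accumulates
# per-batch partial sums with compensated summation so the results are
# invariant under the batch partition.
#
# Term bookkeeping (all quantities are pair sums over active pairs):
#   V = FG-term + occ-occ product - virt-virt product - two 6c3e terms
#   X = same with (F,F) kernels and F^2 in place of FG
#   B = 2 x [ 1/2 g^2 F2-term + (f+k) single-RI term   (commutator relation)
#             - k-dressed 6c3e - 2 f-dressed 6c3e + occ-Fock 6c3e
#             + U intermediate + T intermediate ]
# where the U/T dressing matrices fold the coefficients (-1, +2, -1) and
# (-2, +1) of the shared-subspace variants.

# shared evaluation context: densities, dressings, DF blocks
.f12_ctx <- function(spaces, df_aux, config) {
  sp <- spaces
  kF <- kernel_spec("F", config$gamma, config$n_stg)
  ctx <- new.env(parent = emptyenv())
  ctx$spaces <- sp
  ctx$config <- config
  ctx$kF <- kF
  ctx$kG <- kernel_spec("G", config$gamma, config$n_stg)
  ctx$kFG <- kernel_spec("FG", config$gamma, config$n_stg)
  ctx$kF2 <- kernel_spec("F2", config$gamma, config$n_stg)
  ctx$df_aux <- df_aux
  nao <- sp$obs$nao
  ctx$C_act <- .coef_block_obs(sp, "act")
  ctx$C_occ <- .coef_block_obs(sp, "occ")
  ctx$C_kl <- if (identical(config$occ_products, "active")) ctx$C_act else
    ctx$C_occ
  ctx$idx_kl <- if (identical(config$occ_products, "active")) sp$idx$act else
    sp$idx$occ
  ctx$C_virt <- .coef_block_obs(sp, "virt")
  ctx$C_all <- sp$C
  ctx$eps_act <- sp$eps[sp$idx$act]
  ctx$P_act <- tcrossprod(ctx$C_act)
  ctx$P_occ <- tcrossprod(ctx$C_occ)
  ctx$P_kl <- tcrossprod(ctx$C_kl)
  ctx$P_act_eps <- ctx$C_act %*% (ctx$eps_act * t(ctx$C_act))
  ctx$Pi <- sp$Pi
  # AO representations consistent with the (possibly GBC/EBC-zeroed) union
  # MO Fock: f_eff = S' C f_mo C^T S' reproduces the MO matrix elements
  SC <- sp$S_union %*% sp$C
  f_eff <- SC %*% sp$f_mo %*% t(SC)
  fk_eff <- SC %*% (sp$f_mo + sp$k_mo) %*% t(SC)
  ctx$PiKPi <- sp$Pi %*% sp$k_ao %*% sp$Pi
  ctx$C63 <- ctx$P_occ %*% f_eff[seq_len(nao), , drop = FALSE] %*% sp$Pi
  ctx$D63 <- sp$Pi %*% f_eff[, seq_len(nao), drop = FALSE] %*% ctx$P_occ
  ctx$C64 <- ctx$P_occ %*%
    f_eff[seq_len(nao), seq_len(nao), drop = FALSE] %*% ctx$P_occ
  ctx$fk_ao_ou <- fk_eff[seq_len(nao), , drop = FALSE]
  # U / T dressing matrices over the union MO basis
  f_mo <- sp$f_mo
  nu <- length(sp$idx$all)
  sU <- matrix(-1, nu, nu)                 # s(p', r') for the U pass
  sU[, sp$idx$occ] <- sU[, sp$idx$occ] + 2
  sU[sp$idx$occ, sp$idx$occ] <- sU[sp$idx$occ, sp$idx$occ] - 1
  ctx$fU <- f_mo * sU
  if (length(sp$idx$virt)) {
    sT <- matrix(-2, nu, length(sp$idx$virt))
    sT[sp$idx$virt, ] <- sT[sp$idx$virt, ] + 1
    ctx$fT <- f_mo[, sp$idx$virt, drop = FALSE] * sT
  }
  # density fitting of the F kernel over union MO pairs
  met <- df_2c2e(kF, df_aux)
  ctx$metricF <- met
  ao3 <- df_3c2e(kF, sp$union_basis, sp$union_basis, df_aux)
  raw3 <- .ctr_dim(.ctr_dim(ao3, ctx$C_all, 1), ctx$C_all, 2)
  ctx$raw3 <- raw3
  ctx$fit3 <- df_fit_pairs(kF, raw3, met$Yinv)$coef
  ctx
}

.fit_block <- function(ctx, rows, cols, kind = c("fit", "raw")) {
  kind <- match.arg(kind)
  src <- if (kind == "fit") ctx$fit3 else ctx$raw3
  src[rows, cols, , drop = FALSE]
}

# batch-level AO kernel block with the batch's significant-pair screening
.batch_block <- function(kern, batch, basA, basB, theta) {
  grid_3c1e(kern, batch, basA, basB, theta)
}

#' FG exchange contribution (Algorithm 1)
#'
#' Accumulates the seminumerical 4c2e term
#' `sum_g w_g P P chi chi (g|F g|la si)` batchwise; equals
#' `sum_ij <ij|F12 g12|ji>` (exchange) and `<ij|F12 g12|ij>` (direct) in the
#' fine-grid limit.
#'
#' @param spaces `f12_spaces`
#' @param batches batch list from [make_batches()]
#' @param theta_nq screening threshold
#' @param config `f12_config`
#' @param kern kernel (FG by default; the F2 kernel reuses this path)
#' @param P_i,P_j AO density dressings of the two pair chains
#' @return list with pair-summed `x` (exchange) and `d` (direct) values
#' @export
algorithm1_fg <- function(spaces, batches, theta_nq = 1e-10,
                          config = run_config(), kern = NULL,
                          P_i = NULL, P_j = NULL) {
  obs <- spaces$obs
  if (is.null(kern)) kern <- kernel_spec("FG", config$gamma, config$n_stg)
  C_act <- .coef_block_obs(spaces, "act")
  if (is.null(P_i)) P_i <- tcrossprod(C_act)
  if (is.null(P_j)) P_j <- P_i
  accx <- .kahan_new(); accd <- .kahan_new()
  for (b in batches) {
    chi <- eval_aos(b, obs)
    blk <- .batch_block(kern, b, obs, obs, theta_nq)
    ng <- length(b$w)
    chia <- chi %*% P_i
    chib <- chi %*% P_j
    tg <- matrix(0, ng, obs$nao)
    for (l in seq_len(obs$nao))
      tg <- tg + chib[, l] * matrix(blk[, l, ], ng)
    accx <- .kahan_add(accx, sum(b$w * rowSums(tg * chia)))
    rho <- rowSums(chib * chi)
    s <- matrix(blk, ng) %*% as.vector(P_i)
    accd <- .kahan_add(accd, sum(b$w * rho * s))
    ctr_add("alg1", ng * obs$nao^2 * 2)
  }
  list(x = accx$s, d = accd$s)
}

#' F^2 contributions and commutator add-ons (Algorithm 2)
#'
#' Evaluates the F^2-kernel analogue of the FG term (used by the X
#' intermediate, with energy-weighted densities where the X-Fock contraction
#' demands them) together with the two commutator add-on terms of the B
#' assembly: the gradient-square term (gamma^2 times the F^2 term with unit
#' weights) and the (f+k) single full-RI insertion.
#'
#' @inheritParams algorithm1_fg
#' @param ctx evaluation context (internal); created on the fly if missing
#' @return list with `f2` (x/d/eps_x/eps_d), `grad_sq` (x/d), `fk_ri_term`
#'   (x/d) components
#' @export
algorithm2_f2 <- function(spaces, batches, theta_nq = 1e-10,
                          config = run_config(), ctx = NULL) {
  if (is.null(ctx)) stop("algorithm2_f2 requires the evaluation context")
  obs <- spaces$obs
  ub <- spaces$union_basis
  nao <- obs$nao
  kF2 <- ctx$kF2
  g2 <- config$gamma^2
  acc <- lapply(1:8, function(i) .kahan_new())
  names(acc) <- c("f2x", "f2d", "f2ex", "f2ed", "d2x", "d2d", "fkx", "fkd")
  M2 <- ctx$P_act %*% ctx$fk_ao_ou %*% ctx$Pi      # direct (f+k) RI dressing
  for (b in batches) {
    chi <- eval_aos(b, obs)
    chiu <- .eval_aos_union(b, ub)
    ng <- length(b$w)
    blk_ou <- .batch_block(kF2, b, obs, ub, theta_nq)
    blk <- blk_ou[, , seq_len(nao), drop = FALSE]
    pair_chain <- function(P_i, P_j) {
      chia <- chi %*% P_i
      chib <- chi %*% P_j
      tg <- matrix(0, ng, nao)
      for (l in seq_len(nao))
        tg <- tg + chib[, l] * matrix(blk[, l, ], ng)
      ex <- sum(b$w * rowSums(tg * chia))
      rho <- rowSums(chib * chi)
      dr <- sum(b$w * rho * (matrix(blk, ng) %*% as.vector(P_i)))
      c(ex, dr)
    }
    v_pp <- pair_chain(ctx$P_act, ctx$P_act)
    v_ep <- pair_chain(ctx$P_act_eps, ctx$P_act)
    v_pe <- pair_chain(ctx$P_act, ctx$P_act_eps)
    acc$f2x <- .kahan_add(acc$f2x, v_pp[1]); acc$f2d <- .kahan_add(acc$f2d, v_pp[2])
    acc$f2ex <- .kahan_add(acc$f2ex, v_ep[1] + v_pe[1])
    acc$f2ed <- .kahan_add(acc$f2ed, v_ep[2] + v_pe[2])
    acc$d2x <- .kahan_add(acc$d2x, g2 * v_pp[1])
    acc$d2d <- .kahan_add(acc$d2d, g2 * v_pp[2])
    # (f+k) single full-RI insertion, exchange chain:
    #   w P P chi_mu chi_e' (g|F2|nu la) (f+k)_{si d'} Pi_{d' e'}
    chia <- chi %*% ctx$P_act
    tg <- matrix(0, ng, nao)
    for (l in seq_len(nao))
      tg <- tg + chia[, l] * matrix(blk[, , l], ng)   # t_nu = sum_la (g|F2|nu la) chia_la
    u <- tg %*% ctx$P_act
    v <- u %*% (ctx$fk_ao_ou %*% ctx$Pi)
    acc$fkx <- .kahan_add(acc$fkx, sum(b$w * rowSums(v * chiu)))
    # direct form with the quadrature on the same electron as the exchange
    # chain: E_d = sum_g w [chi (P_act (f+k) Pi) chi_u] [sum P_act (g|F2|..)]
    s1 <- rowSums((chi %*% M2) * chiu)
    s2 <- matrix(blk, ng) %*% as.vector(ctx$P_act)
    acc$fkd <- .kahan_add(acc$fkd, sum(b$w * s1 * s2))
    ctr_add("alg2", ng * nao * (nao + ncol(chiu)))
  }
  list(f2 = list(x = acc$f2x$s, d = acc$f2d$s, eps_x = acc$f2ex$s,
                 eps_d = acc$f2ed$s),
       grad_sq = list(x = acc$d2x$s, d = acc$d2d$s),
       fk_ri_term = list(x = acc$fkx$s, d = acc$fkd$s))
}

.eval_aos_union <- function(batch, ub) {
  ng <- nrow(batch$points)
  cpp_eval_aos(ub$cpp, batch$points) * rep(ub$norm, each = ng)
}

#' V and X exchange/direct pair sums (hybrid NQ/DF, CABS-free)
#'
#' Assembles V (FG term + occupied-occupied product - virtual-virtual
#' product - 6c3e terms) and X (F^2 analogue, including the energy-weighted
#' variants used by the X-Fock contraction) entirely without CABS indices:
#' products via the hybrid DF+NQ path with the Coulomb factor on the grid,
#' 6c3e terms via the AO chain with occupied-density dressings.
#'
#' @param spaces `f12_spaces`
#' @param batches grid batches
#' @param df_blocks evaluation context from the energy driver
#' @param theta_nq screening threshold
#' @param config `f12_config`
#' @return list of pair-summed components and intermediates
#' @export
build_vx <- function(spaces, batches, df_blocks, theta_nq = 1e-10,
                     config = run_config()) {
  ctx <- df_blocks
  obs <- spaces$obs
  nao <- obs$nao
  idx <- spaces$idx
  nvirt <- length(idx$virt)
  eps <- ctx$eps_act
  nms <- c("oo_x", "oo_d", "vv_x", "vv_d", "six_x", "six_d",
           "Xoo_x", "Xoo_d", "Xoo_ex", "Xoo_ed",
           "Xvv_x", "Xvv_d", "Xvv_ex", "Xvv_ed",
           "Xsix_x", "Xsix_d", "Xsix_ex", "Xsix_ed")
  acc <- lapply(nms, function(i) .kahan_new()); names(acc) <- nms
  fit_ao_ <- .fit_block(ctx, idx$act, ctx$idx_kl)      # (act, kl, R)
  raw_ao_ <- .fit_block(ctx, idx$act, ctx$idx_kl, "raw")
  if (nvirt) {
    fit_av <- .fit_block(ctx, idx$act, idx$virt)
    raw_av <- .fit_block(ctx, idx$act, idx$virt, "raw")
  }
  for (b in batches) {
    chi <- eval_aos(b, obs)
    ng <- length(b$w)
    Fb <- .batch_block(ctx$kF, b, obs, obs, theta_nq)
    Gb <- .batch_block(ctx$kG, b, obs, obs, theta_nq)
    Gm_ka <- mo_transform_3c1e(Gb, ctx$C_kl, ctx$C_act, config$batch_mo)
    Fm_ka <- mo_transform_3c1e(Fb, ctx$C_kl, ctx$C_act, config$batch_mo)
    phi_act <- chi %*% ctx$C_act
    phi_kl <- chi %*% ctx$C_kl
    phi_act_e <- phi_act * rep(eps, each = ng)
    # ---- occupied-occupied products (grid factor on the right kernel) ----
    # eps recycles along dim 1 (the active index) of an (act, *, R) array
    run_oo <- function(Wb, fit, raw, lab_x, lab_d, weight = "none") {
      fit_x <- if (weight == "i") fit * eps else fit
      phij <- if (weight == "j") phi_act_e else phi_act
      ex <- product_4c2e_nq_df(Wb, structure(list(coef = fit_x, raw = raw),
                                             class = "f12_dffit"),
                               list(i = phi_kl, k = phij), b$w,
                               config$batch_aux, "exchange")
      # direct: coef over (I=act i, K=kl k); raw over (J=act j, L=kl l)
      raw_dir <- if (weight == "j") raw * eps else raw
      dr <- product_4c2e_nq_df(aperm(Wb, c(1, 3, 2)),
                               structure(list(coef = fit_x, raw = raw_dir),
                                         class = "f12_dffit"),
                               list(i = phi_act, k = phi_kl), b$w,
                               config$batch_aux, "direct")
      acc[[lab_x]] <<- .kahan_add(acc[[lab_x]], ex)
      acc[[lab_d]] <<- .kahan_add(acc[[lab_d]], dr)
    }
    run_oo(Gm_ka, fit_ao_, raw_ao_, "oo_x", "oo_d")
    run_oo(Fm_ka, fit_ao_, raw_ao_, "Xoo_x", "Xoo_d")
    run_oo(Fm_ka, fit_ao_, raw_ao_, "Xoo_ex", "Xoo_ed", weight = "i")
    run_oo(Fm_ka, fit_ao_, raw_ao_, "Xoo_ex", "Xoo_ed", weight = "j")
    # ---- virtual-virtual products ---------------------------------------
    if (nvirt) {
      Gm_va <- mo_transform_3c1e(Gb, ctx$C_virt, ctx$C_act, config$batch_mo)
      Fm_va <- mo_transform_3c1e(Fb, ctx$C_virt, ctx$C_act, config$batch_mo)
      phi_virt <- chi %*% ctx$C_virt
      run_vv <- function(Wb, fit, raw, lab_x, lab_d, weight = "none") {
        fit_x <- if (weight == "i") fit * eps else fit
        phij <- if (weight == "j") phi_act_e else phi_act
        ex <- product_4c2e_nq_df(Wb, structure(list(coef = fit_x, raw = raw),
                                               class = "f12_dffit"),
                                 list(i = phi_virt, k = phij), b$w,
                                 config$batch_aux, "exchange")
        raw_dir <- if (weight == "j") raw * eps else raw
        dr <- product_4c2e_nq_df(aperm(Wb, c(1, 3, 2)),
                                 structure(list(coef = fit_x, raw = raw_dir),
                                           class = "f12_dffit"),
                                 list(i = phi_act, k = phi_virt), b$w,
                                 config$batch_aux, "direct")
        acc[[lab_x]] <<- .kahan_add(acc[[lab_x]], ex)
        acc[[lab_d]] <<- .kahan_add(acc[[lab_d]], dr)
      }
      run_vv(Gm_va, fit_av, raw_av, "vv_x", "vv_d")
      run_vv(Fm_va, fit_av, raw_av, "Xvv_x", "Xvv_d")
      run_vv(Fm_va, fit_av, raw_av, "Xvv_ex", "Xvv_ed", weight = "i")
      run_vv(Fm_va, fit_av, raw_av, "Xvv_ex", "Xvv_ed", weight = "j")
    }
    # ---- 6c3e terms (AO chain, A = j-chain, B = i-chain, C = kl) --------
    six <- function(Wt, Yt, A, B, pat)
      contract_6c3e_ao(A, B, ctx$P_kl, Wt, Yt, chi, b$w, pat)
    acc$six_x <- .kahan_add(acc$six_x, 2 * six(Fb, Gb, ctx$P_act, ctx$P_act,
                                               "exchange"))
    acc$six_d <- .kahan_add(acc$six_d, 2 * six(Fb, Gb, ctx$P_act, ctx$P_act,
                                               "direct"))
    acc$Xsix_x <- .kahan_add(acc$Xsix_x, 2 * six(Fb, Fb, ctx$P_act,
                                                 ctx$P_act, "exchange"))
    acc$Xsix_d <- .kahan_add(acc$Xsix_d, 2 * six(Fb, Fb, ctx$P_act,
                                                 ctx$P_act, "direct"))
    acc$Xsix_ex <- .kahan_add(acc$Xsix_ex,
      2 * (six(Fb, Fb, ctx$P_act_eps, ctx$P_act, "exchange") +
           six(Fb, Fb, ctx$P_act, ctx$P_act_eps, "exchange")))
    acc$Xsix_ed <- .kahan_add(acc$Xsix_ed,
      2 * (six(Fb, Fb, ctx$P_act_eps, ctx$P_act, "direct") +
           six(Fb, Fb, ctx$P_act, ctx$P_act_eps, "direct")))
  }
  a1 <- algorithm1_fg(spaces, batches, theta_nq, config, kern = ctx$kFG)
  a2 <- algorithm2_f2(spaces, batches, theta_nq, config, ctx)
  V_x <- a1$x + acc$oo_x$s - acc$vv_x$s - acc$six_x$s
  V_d <- a1$d + acc$oo_d$s - acc$vv_d$s - acc$six_d$s
  X_x <- a2$f2$x + acc$Xoo_x$s - acc$Xvv_x$s - acc$Xsix_x$s
  X_d <- a2$f2$d + acc$Xoo_d$s - acc$Xvv_d$s - acc$Xsix_d$s
  X_eps_x <- a2$f2$eps_x + acc$Xoo_ex$s - acc$Xvv_ex$s - acc$Xsix_ex$s
  X_eps_d <- a2$f2$eps_d + acc$Xoo_ed$s - acc$Xvv_ed$s - acc$Xsix_ed$s
  list(V_x = V_x, V_d = V_d, X_x = X_x, X_d = X_d,
       X_eps_x = X_eps_x, X_eps_d = X_eps_d, alg2 = a2,
       terms = list(term_fg_x = a1$x, term_fg_d = a1$d,
                    term_oo_prod_x = acc$oo_x$s, term_vv_prod_x = acc$vv_x$s,
                    term_six_x = acc$six_x$s,
                    term_f2_x = a2$f2$x, term_x_oo_prod_x = acc$Xoo_x$s,
                    term_x_vv_prod_x = acc$Xvv_x$s, term_x_six_x = acc$Xsix_x$s))
}

#' B exchange/direct pair sums (Algorithm 3: hybrid NQ/DF/CABS-RI)
#'
#' Assembles the B intermediate from the reduced projector term list: the
#' commutator add-ons (from Algorithm 2), the k- and Fock-dressed 6c3e AO
#' contractions, and the U/T sub-intermediates whose shared subspaces ride
#' along through scaled dressing matrices.  The union-space index is
#' contracted out first; the (g|F|i p") block is never formed.
#'
#' @inheritParams build_vx
#' @param alg2 optional precomputed result of [algorithm2_f2()]
#' @return list with pair-summed `B_x`, `B_d` and the term breakdown
#' @export
build_b <- function(spaces, batches, df_blocks, theta_nq = 1e-10,
                    config = run_config(), alg2 = NULL) {
  ctx <- df_blocks
  if (length(spaces$idx$cabs) == 0L && is.null(spaces$Pi))
    stop("configuration error: B requires the union space")
  obs <- spaces$obs
  ub <- spaces$union_basis
  nao <- obs$nao
  idx <- spaces$idx
  nvirt <- length(idx$virt)
  if (is.null(alg2)) alg2 <- algorithm2_f2(spaces, batches, theta_nq,
                                           config, ctx)
  nms <- c("b62x", "b62d", "b63x", "b63d", "b64x", "b64d",
           "ux", "ud", "tx", "td")
  acc <- lapply(nms, function(i) .kahan_new()); names(acc) <- nms
  fit_ua <- .fit_block(ctx, idx$all, idx$act)          # (union, act, R)
  raw_oa <- .fit_block(ctx, idx$occ, idx$act, "raw")   # (occ, act, R)
  if (nvirt) {
    fit_va <- .fit_block(ctx, idx$virt, idx$act)
    raw_va <- .fit_block(ctx, idx$virt, idx$act, "raw")
  }
  for (b in batches) {
    chi <- eval_aos(b, obs)
    chiu <- .eval_aos_union(b, ub)
    ng <- length(b$w)
    Fb_ou <- .batch_block(ctx$kF, b, obs, ub, theta_nq)
    Fb <- Fb_ou[, , seq_len(nao), drop = FALSE]
    Y_uo <- aperm(Fb_ou, c(1, 3, 2))
    # k-dressed and Fock-dressed 6c3e contractions (shared pass)
    acc$b62x <- .kahan_add(acc$b62x, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$PiKPi, Fb_ou, Y_uo, chi, b$w, "exchange"))
    acc$b62d <- .kahan_add(acc$b62d, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$PiKPi, Fb_ou, Fb_ou, chi, b$w, "direct"))
    acc$b63x <- .kahan_add(acc$b63x, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$C63, Fb, Y_uo, chi, b$w, "exchange"))
    acc$b63d <- .kahan_add(acc$b63d, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$D63, Fb_ou, Fb, chi, b$w, "direct"))
    acc$b64x <- .kahan_add(acc$b64x, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$C64, Fb, Fb, chi, b$w, "exchange"))
    acc$b64d <- .kahan_add(acc$b64d, contract_6c3e_ao(
      ctx$P_act, ctx$P_act, ctx$C64, Fb, Fb, chi, b$w, "direct"))
    # U / T sub-intermediates
    phi_act <- chi %*% ctx$C_act
    phi_u <- chiu %*% ctx$C_all
    Fm_am <- mo_transform_3c1e(Fb, ctx$C_act,
                               .coef_block_obs(spaces, "occ"),
                               config$batch_mo)       # (g, act, occ)
    acc$ux <- .kahan_add(acc$ux, .contract_ut(
      Fm_am, phi_act, phi_u, ctx$fU, fit_ua, raw_oa, b$w,
      config$batch_aux, "exchange"))
    acc$ud <- .kahan_add(acc$ud, .contract_ut(
      Fm_am, phi_act, phi_u, ctx$fU, fit_ua, raw_oa, b$w,
      config$batch_aux, "direct"))
    if (nvirt) {
      Fm_av <- mo_transform_3c1e(Fb, ctx$C_act, ctx$C_virt, config$batch_mo)
      acc$tx <- .kahan_add(acc$tx, .contract_ut(
        Fm_av, phi_act, phi_u, ctx$fT, fit_va, raw_va, b$w,
        config$batch_aux, "exchange"))
      acc$td <- .kahan_add(acc$td, .contract_ut(
        Fm_av, phi_act, phi_u, ctx$fT, fit_va, raw_va, b$w,
        config$batch_aux, "direct"))
    }
  }
  commut <- config$commutator_level == "full"
  f1_x <- -acc$b62x$s + if (commut)
    0.5 * alg2$grad_sq$x + alg2$fk_ri_term$x else 0
  f1_d <- -acc$b62d$s + if (commut)
    0.5 * alg2$grad_sq$d + alg2$fk_ri_term$d else 0
  half_x <- f1_x - 2 * acc$b63x$s + acc$b64x$s + acc$ux$s + acc$tx$s
  half_d <- f1_d - 2 * acc$b63d$s + acc$b64d$s + acc$ud$s + acc$td$s
  list(B_x = 2 * half_x, B_d = 2 * half_d,
       commutator_level = config$commutator_level,
       commutator_delta_x = if (commut)
         2 * (0.5 * alg2$grad_sq$x + alg2$fk_ri_term$x) else 0,
       terms = list(term_del2f_x = alg2$grad_sq$x,
                    term_fk_ri_x = alg2$fk_ri_term$x,
                    term_k_six_x = acc$b62x$s, term_fo_six_x = acc$b63x$s,
                    term_ofo_six_x = acc$b64x$s,
                    term_U_x = acc$ux$s, term_U_d = acc$ud$s,
                    term_T_x = acc$tx$s, term_T_d = acc$td$s))
}
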