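# Energy assembly: orchestrates reference, orbital spaces, grid, engine
# context and the intermediate builders, and combines the pair sums into the
# explicitly correlated correction.

#' Explicitly correlated F12 correction (3C, fixed amplitudes)
#'
#' Computes the exchange- and direct-pattern V, X, B pair sums with the mode
#' selected in `config` and assembles
#' `E = -5/4 V_d + 1/4 V_x + 7/32 B_1 + 1/32 B_x
#'      - sum_(ij) (eps_i + eps_j) (7/32 X_1 + 1/32 X_x)`
#' over active pairs (the first-pattern choice is governed by
#' `config$b_direct_fix`).
#'
#' @param molecule closed-shell `f12_molecule`
#' @param bases list with `obs`, `cabs_aux`, `df_aux`
#' @param config `f12_config`
#' @param reference optional precomputed `f12_reference`
#' @return `f12_report`
#' @export
f12_energy <- function(molecule, bases, config = run_config(),
                       reference = NULL) {
  t0 <- Sys.time()
  if (config$mode == "dense") {
    dn <- dense_reference(molecule, bases, config, reference = reference)
    return(.report_from_parts(dn$energy$parts, dn$terms, config,
                              dn$spaces, grid = NULL, t0 = t0))
  }
  ref <- if (is.null(reference)) compute_reference(molecule, bases$obs) else
    reference
  cab <- build_cabs(bases$obs, bases$cabs_aux, ref)
  sp <- assemble_spaces(ref, cab, frozen_core = config$frozen_core,
                        gbc_ebc = config$gbc_ebc)
  ctx <- .f12_ctx(sp, bases$df_aux, config)
  if (config$mode == "df_only") {
    parts <- .df_only_parts(sp, ctx, config)
    return(.report_from_parts(parts$parts, parts$terms, config, sp,
                              grid = NULL, t0 = t0))
  }
  grid <- build_grid(molecule, config$grid_level, config$weight_threshold,
                     bases$obs)
  batches <- make_batches(grid, bases$obs, config$batch_grid)
  alg2 <- algorithm2_f2(sp, batches, config$theta_nq, config, ctx)
  vx <- build_vx(sp, batches, ctx, config$theta_nq, config)
  bb <- build_b(sp, batches, ctx, config$theta_nq, config, alg2 = alg2)
  parts <- c(V_d = vx$V_d, V_x = vx$V_x, X_d = vx$X_d, X_x = vx$X_x,
             B_d = bb$B_d, B_x = bb$B_x,
             X_eps_d = vx$X_eps_d, X_eps_x = vx$X_eps_x)
  .report_from_parts(parts, c(vx$terms, bb$terms), config, sp, grid, t0,
                     commutator_delta = bb$commutator_delta_x)
}

# combine pair-summed parts into the final correction
.energy_from_parts <- function(parts, b_direct_fix) {
  B1 <- if (b_direct_fix) parts[["B_d"]] else parts[["B_x"]]
  X1 <- if (b_direct_fix) parts[["X_eps_d"]] else parts[["X_eps_x"]]
  unname(-5 / 4 * parts[["V_d"]] + 1 / 4 * parts[["V_x"]] +
           7 / 32 * B1 + 1 / 32 * parts[["B_x"]] -
           (7 / 32 * X1 + 1 / 32 * parts[["X_eps_x"]]))
}

.report_from_parts <- function(parts, terms, config, spaces, grid, t0,
                               commutator_delta = NA_real_) {
  # the dense path reports pair-resolved sums; recompute X_eps if present
  if (!("X_eps_x" %in% names(parts)))
    stop("internal error: missing X_eps parts")
  total <- .energy_from_parts(parts, config$b_direct_fix)
  structure(list(
    total = total, parts = parts, terms = terms,
    coefficients = c(V_d = -5 / 4, V_x = 1 / 4, B_first = 7 / 32,
                     B_x = 1 / 32, X_first = -7 / 32, X_x = -1 / 32),
    config = config,
    dims = spaces$dims, n_cabs_dropped = spaces$n_dropped,
    scf_energy = spaces$reference$scf_energy,
    grid = if (!is.null(grid))
      c(n_kept = grid$n_kept, n_dropped = grid$n_dropped) else NULL,
    counters = counters_get(),
    commutator_delta = commutator_delta,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "f12_report")
}

#' @export
print.f12_report <- function(x, ...) {
  cat("F12(3C/FIX) correction [", x$config$mode, " mode, grid ",
      x$config$grid_level, "]\n", sep = "")
  cat(sprintf("  E_F12      = %.12f hartree\n", x$total))
  cat(sprintf("  E_SCF      = %.12f hartree\n", x$scf_energy))
  p <- x$parts
  for (nm in names(p)) cat(sprintf("  %-9s = % .12f\n", nm, p[[nm]]))
  if (!is.null(x$grid))
    cat("  grid points kept/dropped:", x$grid["n_kept"], "/",
        x$grid["n_dropped"], "\n")
  invisible(x)
}

#' @export
summary.f12_report <- function(object, ...) {
  cat("Term breakdown (hartree):\n")
  for (nm in names(object$terms))
    cat(sprintf("  %-14s % .12e\n", nm, object$terms[[nm]]))
  cat("Dominant operation counters:\n")
  cn <- object$counters
  for (nm in names(cn)) cat(sprintf("  %-22s %.3e\n", nm, cn[[nm]]))
  invisible(object)
}

# ---------------------------------------------------------------------------
# DF-only comparator: every term through density-fitted 4c2e products with
# CABS-RI insertions turning the three-electron integrals into products
# (the conventional fifth-order route).  Shares the pair-algebra structure
# with the dense oracle but consumes fitted tensors.

.df_only_parts <- function(sp, ctx, config) {
  idx <- sp$idx
  nact <- length(idx$act)
  u_act <- idx$act
  kl <- ctx$idx_kl
  nvirt <- length(idx$virt)
  cfg_g <- config$gamma
  # fitted Dirac tensors <ab|O|cd> = Mulliken (ac|O|bd)
  dir4 <- function(m) aperm(m, c(1, 3, 2, 4))
  # separate fits for the G, FG and F2 kernels over the needed spaces
  aoG <- df_3c2e(ctx$kG, sp$union_basis, sp$union_basis, ctx$df_aux)
  rawG <- .ctr_dim(.ctr_dim(aoG, ctx$C_all, 1), ctx$C_all, 2)
  metG <- df_2c2e(ctx$kG, ctx$df_aux)
  fitG <- df_fit_pairs(ctx$kG, rawG, metG$Yinv)$coef
  aoFG <- df_3c2e(ctx$kFG, sp$union_basis, sp$union_basis, ctx$df_aux)
  rawFG <- .ctr_dim(.ctr_dim(aoFG, ctx$C_all, 1), ctx$C_all, 2)
  metFG <- df_2c2e(ctx$kFG, ctx$df_aux)
  fitFG <- df_fit_pairs(ctx$kFG, rawFG, metFG$Yinv)$coef
  aoF2 <- df_3c2e(ctx$kF2, sp$union_basis, sp$union_basis, ctx$df_aux)
  rawF2 <- .ctr_dim(.ctr_dim(aoF2, ctx$C_all, 1), ctx$C_all, 2)
  metF2 <- df_2c2e(ctx$kF2, ctx$df_aux)
  fitF2 <- df_fit_pairs(ctx$kF2, rawF2, metF2$Yinv)$coef
  fit_of <- function(op) switch(op, F = ctx$fit3, G = fitG, FG = fitFG,
                                F2 = fitF2)
  raw_of <- function(op) switch(op, F = ctx$raw3, G = rawG, FG = rawFG,
                                F2 = rawF2)
  mull <- function(op, r1, c1, r2, c2) {
    cf <- fit_of(op)[r1, c1, , drop = FALSE]
    rw <- raw_of(op)[r2, c2, , drop = FALSE]
    d1 <- dim(cf); d2 <- dim(rw)
    ctr_add("df_only_dominant", prod(as.numeric(c(d1[3], d1[1], d1[2], d2[1], d2[2]))))
    array(matrix(cf, d1[1] * d1[2], d1[3]) %*%
            t(matrix(rw, d2[1] * d2[2], d2[3])), c(d1[1:2], d2[1:2]))
  }
  dirac <- function(op, s1, s2, s3, s4) dir4(mull(op, s1, s3, s2, s4))
  # tensors consumed by the shared pair algebra
  T_FG <- dirac("FG", u_act, u_act, u_act, u_act)
  TG_o <- dirac("G", u_act, u_act, kl, kl)
  TF_o <- dirac("F", u_act, u_act, kl, kl)
  TG_v <- if (nvirt) dirac("G", u_act, u_act, idx$virt, idx$virt) else NULL
  TF_v <- if (nvirt) dirac("F", u_act, u_act, idx$virt, idx$virt) else NULL
  TF_u1 <- dirac("F", u_act, u_act, idx$all, idx$occ)
  TF_u2 <- if (nvirt) dirac("F", u_act, u_act, idx$all, idx$virt) else NULL
  TF2_a <- dirac("F2", idx$all, u_act, u_act, u_act)
  # RI resolution of the 6c3e terms on the shared electron:
  #   <ijk|W12 Y23|kij> = sum_p' <ij|W|k p'> <p' k|Y|i j>
  TW_kp <- dirac("F", u_act, u_act, kl, idx$all)
  TYg_pk <- dirac("G", idx$all, kl, u_act, u_act)
  TYf_pk <- dirac("F", idx$all, kl, u_act, u_act)
  six_V <- six_ri_eval(TW_kp, TYg_pk, nact)
  six_X <- six_ri_eval(TW_kp, TYf_pk, nact)
  pairx <- function(T4) {
    m <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) m[i, j] <- T4[i, j, j, i]
    m
  }
  paird <- function(T4) {
    m <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) m[i, j] <- T4[i, j, i, j]
    m
  }
  prod_pair <- function(TA, TB) {
    ex <- matrix(0, nact, nact); dr <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      ex[i, j] <- sum(TA[i, j, , ] * TB[j, i, , ])
      dr[i, j] <- sum(TA[i, j, , ] * TB[i, j, , ])
    }
    list(x = ex, d = dr)
  }
  FG_x <- pairx(T_FG); FG_d <- paird(T_FG)
  oo_FG <- prod_pair(TF_o, TG_o); oo_FF <- prod_pair(TF_o, TF_o)
  zz <- matrix(0, nact, nact)
  vv_FG <- if (nvirt) prod_pair(TF_v, TG_v) else list(x = zz, d = zz)
  vv_FF <- if (nvirt) prod_pair(TF_v, TF_v) else list(x = zz, d = zz)
  V_x <- FG_x + oo_FG$x - vv_FG$x - (six_V$x + t(six_V$x))
  V_d <- FG_d + oo_FG$d - vv_FG$d - (six_V$d + t(six_V$d))
  F2_x <- matrix(0, nact, nact); F2_d <- matrix(0, nact, nact)
  for (i in seq_len(nact)) for (j in seq_len(nact)) {
    F2_x[i, j] <- TF2_a[u_act[i], j, j, i]
    F2_d[i, j] <- TF2_a[u_act[i], j, i, j]
  }
  X_x <- F2_x + oo_FF$x - vv_FF$x - (six_X$x + t(six_X$x))
  X_d <- F2_d + oo_FF$d - vv_FF$d - (six_X$d + t(six_X$d))
  # ---- B through RI-resolved products ------------------------------------
  f_u <- sp$f_mo; k_u <- sp$k_mo
  TF_pr <- dirac("F", u_act, u_act, idx$all, idx$all)  # <ij|F|p' r'>
  mid_pair <- function(M) {
    # sum_{p'q'r'} <ij|F|p' r'> M[p',q'] <q' r'|F|ji> and |ij>
    A <- .ctr_dim(TF_pr, M, 3)
    ex <- matrix(0, nact, nact); dr <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      ex[i, j] <- sum(A[i, j, , ] * TF_pr[j, i, , ])
      dr[i, j] <- sum(A[i, j, , ] * TF_pr[i, j, , ])
    }
    list(x = ex, d = dr)
  }
  B62 <- mid_pair(k_u)
  B63 <- mid_pair(.embed_f(f_u, idx$occ, length(idx$all), side = "cols"))
  B64 <- mid_pair(.embed_f(f_u, idx$occ, length(idx$all), side = "both"))
  ut_pair <- function(T1, fmat, rows, cols) {
    Ts <- T1[, , rows, , drop = FALSE]
    A <- .ctr_dim(Ts, fmat[rows, cols, drop = FALSE], 3)
    Tr <- T1[, , cols, , drop = FALSE]
    ex <- matrix(0, nact, nact); dr <- matrix(0, nact, nact)
    for (i in seq_len(nact)) for (j in seq_len(nact)) {
      ex[i, j] <- sum(A[i, j, , ] * Tr[j, i, , ])
      dr[i, j] <- sum(A[i, j, , ] * Tr[i, j, , ])
    }
    list(x = ex, d = dr)
  }
  U65 <- ut_pair(TF_u1, f_u, idx$all, idx$all)
  U66 <- ut_pair(TF_u1, f_u, idx$all, idx$occ)
  U67 <- ut_pair(TF_u1, f_u, idx$occ, idx$occ)
  if (nvirt) {
    T68 <- ut_pair(TF_u2, f_u, idx$all, idx$virt)
    T69 <- ut_pair(TF_u2, f_u, idx$virt, idx$virt)
  } else T68 <- T69 <- list(x = zz, d = zz)
  fk <- f_u + k_u
  E61x <- zz; E61d <- zz
  for (i in seq_len(nact)) for (j in seq_len(nact)) {
    E61x[i, j] <- sum(fk[u_act[i], ] * TF2_a[, j, j, i])
    E61d[i, j] <- sum(fk[u_act[i], ] * TF2_a[, j, i, j])
  }
  commut <- config$commutator_level == "full"
  half <- function(F2m, B62m, E61m, U65m, B63m, B63t, U66m, U66t, T68m,
                   T68t, B64m, U67m, T69m) {
    f1 <- -B62m + if (commut) 0.5 * cfg_g^2 * F2m + E61m else 0
    f1 - U65m - (B63m + B63t) + (U66m + U66t) - (T68m + T68t) +
      B64m - U67m + T69m
  }
  Bhx <- half(F2_x, B62$x, E61x, U65$x, B63$x, t(B63$x), U66$x, t(U66$x),
              T68$x, t(T68$x), B64$x, U67$x, T69$x)
  Bhd <- half(F2_d, B62$d, E61d, U65$d, B63$d, B63$d, U66$d, U66$d,
              T68$d, T68$d, B64$d, U67$d, T69$d)
  B_x <- Bhx + t(Bhx); B_d <- Bhd + t(Bhd)
  epm <- outer(ctx$eps_act, ctx$eps_act, `+`)
  parts <- c(V_d = sum(V_d), V_x = sum(V_x), X_d = sum(X_d), X_x = sum(X_x),
             B_d = sum(B_d), B_x = sum(B_x),
             X_eps_d = sum(epm * X_d), X_eps_x = sum(epm * X_x))
  list(parts = parts,
       terms = list(term_FG_x = sum(FG_x), term_oo_x = sum(oo_FG$x),
                    term_vv_x = sum(vv_FG$x),
                    term_six_V_x = sum(six_V$x + t(six_V$x))))
}

# embed an f block restricted to given rows/cols into a union-sized matrix
.embed_f <- function(f_u, occ, nu, side = c("cols", "both")) {
  side <- match.arg(side)
  M <- matrix(0, nu, nu)
  if (side == "cols") M[, occ] <- f_u[, occ]
  else M[occ, occ] <- f_u[occ, occ]
  M
}

# RI resolution of <ijk|W12 Y23|k..> on the shared electron:
#   exchange <ijk|W12 Y23|kij> -> sum TW[i,j,k,p'] TY[p',k,i,j]
#   direct   <ijk|W12 Y23|kji> -> sum TW[i,j,k,p'] TY[p',k,j,i]
six_ri_eval <- function(TW_kp, TY_pk, nact) {
  ex <- matrix(0, nact, nact); dr <- matrix(0, nact, nact)
  for (i in seq_len(nact)) for (j in seq_len(nact)) {
    ex[i, j] <- sum(TW_kp[i, j, , ] * t(TY_pk[, , i, j]))
    dr[i, j] <- sum(TW_kp[i, j, , ] * t(TY_pk[, , j, i]))
  }
  list(x = ex, d = dr)
}
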