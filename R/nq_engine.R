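# Generic contraction paths: six-center three-electron integrals in the MO
# and AO pictures, density-fitted products of 4c2e integrals (the fifth-order
# comparator), and the hybrid DF+NQ product path that reduces those products
# to fourth order.  All routines operate on one grid batch and are
# accumulated by the callers; auxiliary indices are processed in batches.

#' MO-picture 6c3e contraction
#'
#' Pair-summed energy of `<ijk|W12 Y23|kij>` over one grid batch:
#' `E = sum_g w_g W_k^g Y_k^g` with `W_k^g = phi_i^g (g|W|ik)` and
#' `Y_k^g = phi_j^g (g|Y|kj)`.
#'
#' @param W_block array (ng, n_i, n_k) of MO 3c1e integrals (g|W|ik)
#' @param Y_block array (ng, n_k, n_j) of MO 3c1e integrals (g|Y|kj)
#' @param phi list with `i` (ng x n_i) and `j` (ng x n_j) MO amplitudes
#' @param w grid weights (length ng)
#' @return pair-summed scalar contribution
#' @export
contract_6c3e_mo <- function(W_block, Y_block, phi, w) {
  dW <- dim(W_block); dY <- dim(Y_block)
  if (dW[1] != dY[1] || dW[1] != length(w) || dW[3] != dY[2])
    stop("contract violation: 6c3e blocks disagree on batch or k dimension")
  ng <- as.numeric(dW[1]); nk <- dW[3]
  Wg <- matrix(0, ng, nk); Yg <- matrix(0, ng, nk)
  for (i in seq_len(dW[2])) Wg <- Wg + phi$i[, i] * matrix(W_block[, i, ], ng)
  for (k in seq_len(nk))
    Yg[, k] <- rowSums(matrix(Y_block[, k, ], ng) * phi$j)
  ctr_add("mo6c3e", ng * nk * (dW[2] + dim(phi$j)[2] + 1))
  sum(w * rowSums(Wg * Yg))
}

#' AO-picture 6c3e contraction with density dressings
#'
#' Exchange pattern (the stepwise AO chain): `chiA = chi A`, `chiB = chi B`,
#' `tW_s = chiB_l (g|W|l s)`, `tY_d = chiA_e (g|Y|d e)`,
#' `E = sum_g w_g tW C tY^T`.
#' Direct pattern: `E = sum_g w_g rho_g * sum D1 W^g D2 Y^g` with
#' `rho_g = chi Arho chi`.
#'
#' @param A,B,C density dressings (exchange pattern); for the direct pattern
#'   `A` is the rho-dressing and `B`, `C` are the two trace dressings
#' @param W_tensor,Y_tensor AO 3c1e blocks (ng, n1, n2)
#' @param chi AO amplitudes on the batch (ng x nao)
#' @param w weights
#' @param pattern "exchange" or "direct"
#' @export
contract_6c3e_ao <- function(A, B, C, W_tensor, Y_tensor, chi, w,
                             pattern = c("exchange", "direct")) {
  pattern <- match.arg(pattern)
  ng <- as.numeric(length(w))
  dW <- dim(W_tensor); dY <- dim(Y_tensor)
  if (dW[1] != ng || dY[1] != ng)
    stop("contract violation: batch size mismatch")
  if (pattern == "exchange") {
    if (nrow(A) != ncol(chi) || nrow(B) != ncol(chi))
      stop("contract violation: dressing does not match the grid basis")
    if (ncol(B) != dW[2] || ncol(A) != dY[3] ||
        nrow(C) != dW[3] || ncol(C) != dY[2])
      stop("contract violation: dressing/index-family mismatch")
    chiA <- chi %*% A
    chiB <- chi %*% B
    tW <- matrix(0, ng, dW[3])
    for (l in seq_len(dW[2]))
      tW <- tW + chiB[, l] * matrix(W_tensor[, l, ], ng)
    tY <- matrix(0, ng, dY[2])
    for (d in seq_len(dY[2]))
      tY[, d] <- rowSums(matrix(Y_tensor[, d, ], ng) * chiA)
    ctr_add("ao6c3e", ng * (dW[2] * dW[3] + dY[2] * dY[3] +
                              dW[3] * dY[2]))
    sum(w * rowSums((tW %*% C) * tY))
  } else {
    rho <- rowSums((chi %*% A) * chi)
    # S_g = sum_{s,l,d,e} B_{s l} W[g,l,d] C_{d e} Y[g,s,e]
    Wd <- .ctr3(W_tensor, t(B), 2)        # (g, s, d)
    Yd <- .ctr3(Y_tensor, t(C), 3)        # (g, s, d)
    ctr_add("ao6c3e", ng * (dW[2] * dW[3] * nrow(B) +
                              dY[2] * dY[3] * nrow(C)))
    sum(w * rho * rowSums(matrix(Wd, ng) * matrix(Yd, ng)))
  }
}

#' Density-fitting coefficients for MO pairs
#'
#' Step 1 of the stepwise product evaluation: `C_R^{li} = Yinv_SR (li|O|S)`.
#'
#' @param op `f12_kernel` (bookkeeping only)
#' @param mo_pair_3c2e array (n1, n2, naux) of raw (pair|O|S) integrals
#' @param metric_inverse (pseudo)inverse metric from [df_2c2e()]
#' @return `f12_dffit` object with `coef` (n1, n2, naux) and `raw`
#' @export
df_fit_pairs <- function(op, mo_pair_3c2e, metric_inverse) {
  d <- dim(mo_pair_3c2e)
  if (d[3] != nrow(metric_inverse))
    stop("contract violation: auxiliary dimension mismatch")
  cf <- array(matrix(mo_pair_3c2e, d[1] * d[2], d[3]) %*% metric_inverse, d)
  ctr_add("df_fit", prod(d) * d[3])
  structure(list(op = op$op, coef = cf, raw = mo_pair_3c2e), class = "f12_dffit")
}

#' Purely density-fitted product of two 4c2e integrals (fifth-order path)
#'
#' Evaluates `sum <ij|W|kl><kl|Y|ji>` (exchange) or `sum <ij|W|kl><kl|Y|ij>`
#' (direct) with both factors density-fitted.  The reconstruction of the
#' fitted pair-pair matrices is the rate-determining O(N_P n_pair^2) step and
#' is recorded in the `df_only_dominant` counter.
#'
#' @param W_fit `f12_dffit` whose `coef` covers the (i,k) pairs and `raw` the
#'   (j,l) pairs of the Mulliken factor (ik|W|jl)
#' @param Y_fit `f12_dffit` for (kj|Y|li) (exchange) or (ki|Y|lj) (direct)
#' @param pattern index pattern
#' @export
product_4c2e_df <- function(W_fit, Y_fit, pattern = c("exchange", "direct")) {
  pattern <- match.arg(pattern)
  dW <- dim(W_fit$coef); dY <- dim(Y_fit$coef)
  naux <- dW[3]
  MW <- matrix(W_fit$coef, dW[1] * dW[2], naux) %*%
    t(matrix(W_fit$raw, dim(W_fit$raw)[1] * dim(W_fit$raw)[2], naux))
  MY <- matrix(Y_fit$coef, dY[1] * dY[2], naux) %*%
    t(matrix(Y_fit$raw, dim(Y_fit$raw)[1] * dim(Y_fit$raw)[2], naux))
  ctr_add("df_only_dominant",
          as.numeric(naux) * (as.numeric(nrow(MW)) * ncol(MW) + as.numeric(nrow(MY)) * ncol(MY)))
  dWr <- dim(W_fit$raw); dYr <- dim(Y_fit$raw)
  AW <- array(MW, c(dW[1], dW[2], dWr[1], dWr[2]))  # (i,k,j,l)
  AY <- array(MY, c(dY[1], dY[2], dYr[1], dYr[2]))
  if (pattern == "exchange") {
    # sum_{ijkl} AW[i,k,j,l] * AY[k,j,l,i]
    sum(AW * aperm(AY, c(4, 1, 2, 3)))
  } else {
    # sum_{ijkl} AW[i,k,j,l] * AY[k,i,l,j]
    sum(AW * aperm(AY, c(2, 1, 4, 3)))
  }
}

#' Hybrid NQ+DF product of two 4c2e integrals (fourth-order path)
#'
#' Stepwise evaluation over one grid batch with the quadrature on the W
#' factor and density fitting on the Y factor; the auxiliary index is
#' processed in batches of `aux_batch` functions and the result is
#' independent of that batching.
#'
#' Exchange: `E = sum_g w_g (g|W|J L) sum_R [phiI C^R]_{Lg} [phiK raw_R]_{gJ}`.
#' Direct:   `E = sum_g w_g (g|W|J L) sum_R [sum_IK phiI phiK C_R] raw_R^{JL}`.
#'
#' @param W_mo_3c1e array (ng, nJ, nL): MO 3c1e block of the grid factor
#' @param Y_fit `f12_dffit`: `coef` over (nL, nI, naux), `raw` over
#'   (nK, nJ, naux) for the exchange pattern; for the direct pattern `coef`
#'   over (nI, nK, naux) and `raw` over (nJ, nL, naux)
#' @param phi list with grid MO amplitude matrices `i` (ng x nI) and
#'   `k` (ng x nK)
#' @param w weights
#' @param aux_batch auxiliary batch size
#' @param pattern index pattern
#' @export
product_4c2e_nq_df <- function(W_mo_3c1e, Y_fit, phi, w, aux_batch = 16L,
                               pattern = c("exchange", "direct")) {
  pattern <- match.arg(pattern)
  if (aux_batch < 1L) stop("configuration error: aux_batch must be >= 1")
  ng <- as.numeric(length(w))
  dW <- dim(W_mo_3c1e)
  cf <- Y_fit$coef; rw <- Y_fit$raw
  dc <- dim(cf); dr <- dim(rw)
  naux <- dc[3]
  chunks <- split(seq_len(naux), ceiling(seq_len(naux) / aux_batch))
  if (pattern == "exchange") {
    nJ <- dW[2]; nL <- dW[3]
    if (dr[2] != nJ || dc[1] != nL)
      stop("contract violation: fit blocks do not match the grid factor")
    E <- 0
    for (rs in chunks) {
      nR <- length(rs)
      # step 2: C[g, L, R] = sum_I phiI[g, I] coef[L, I, R]
      Cg <- phi$i %*% matrix(aperm(cf[, , rs, drop = FALSE], c(2, 1, 3)),
                             dc[2], nL * nR)
      # step 3: D[g, J, R] = sum_K phiK[g, K] raw[K, J, R]
      Dg <- phi$k %*% matrix(rw[, , rs, drop = FALSE], dr[1], nJ * nR)
      ctr_add("nqdf_steps", ng * nR * (nL * dc[2] + nJ * dr[1]))
      # steps 4-5: E += sum_g w sum_R sum_JL W[g,J,L] D[g,J,R] C[g,L,R]
      E <- E + cpp_prod_exchange(W_mo_3c1e, Dg, Cg, w, nJ, nL, nR)
      ctr_add("nqdf_step4", ng * nR * nJ * nL)
    }
    ctr_add("nqdf_dominant", ng * naux * max(nL * dc[2], nJ * dr[1]))
    E
  } else {
    nJ <- dW[2]; nL <- dW[3]
    if (dr[1] != nJ || dr[2] != nL)
      stop("contract violation: raw block does not match the grid factor")
    E <- 0
    for (rs in chunks) {
      nR <- length(rs)
      # a[g, R] = sum_{I,K} phiI[g,I] phiK[g,K] coef[I,K,R]
      a <- matrix(0, ng, nR)
      for (r in seq_len(nR))
        a[, r] <- rowSums((phi$i %*% cf[, , rs[r]]) * phi$k)
      ctr_add("nqdf_steps", ng * nR * dc[1] * dc[2])
      # b[g, J, L] = sum_R a[g, R] raw[J, L, R]
      b <- a %*% t(matrix(rw[, , rs, drop = FALSE], nJ * nL, nR))
      ctr_add("nqdf_step4", ng * nR * nJ * nL)
      E <- E + sum(w * rowSums(matrix(W_mo_3c1e, ng) * b))
    }
    ctr_add("nqdf_dominant", ng * naux * dc[1] * dc[2])
    E
  }
}

# ---------------------------------------------------------------------------
# U / T sub-intermediates (per batch).  The approximated complete space p' is
# contracted out first (the rate-determining O(Ng NP Np' Ni) step), so the
# (g|F|i p") block is never formed.
#
# exchange: E = sum_g w phiI_i phiP_p' (g|F|j m) C_R^{r' j} raw_R^{m i} fd[p', r']
# direct:   E = sum_g w phiI_i phiP_p' (g|F|j m) C_R^{r' i} raw_R^{m j} fd[p', r']
# fd is the (scaled) dressing matrix over (p' x r'); sub-space variants ride
# along through its scaling structure.
.contract_ut <- function(W_block, phiI, phiP, fd, fit_coef, raw, w,
                         aux_batch = 16L, pattern = "exchange") {
  ng <- as.numeric(length(w))
  dW <- dim(W_block)                      # (ng, n_act, nM)
  nact <- dW[2]; nM <- dW[3]
  dc <- dim(fit_coef)                     # (n_union, n_act, naux)
  dr <- dim(raw)                          # (nM, n_act, naux)
  naux <- dc[3]
  A <- phiP %*% fd                        # (ng, n_union): p' contracted out
  ctr_add("ut_scale", ng * ncol(phiP) * ncol(fd))
  chunks <- split(seq_len(naux), ceiling(seq_len(naux) / aux_batch))
  E <- 0
  if (pattern == "exchange") {
    for (rs in chunks) {
      nR <- length(rs)
      Q <- A %*% matrix(fit_coef[, , rs, drop = FALSE],
                        dc[1], nact * nR)            # (g, act[j] * R)
      ctr_add("u_pprime_contraction", ng * nR * dc[1] * nact)
      Z <- phiI %*% matrix(aperm(raw[, , rs, drop = FALSE], c(2, 1, 3)),
                           dr[2], nM * nR)           # (g, m * R)
      ctr_add("ut_steps", ng * nR * nM * dr[2])
      E <- E + cpp_prod_exchange(W_block, Q, Z, w, nact, nM, nR)
      ctr_add("ut_steps", ng * nR * nact * nM)
    }
  } else {
    for (rs in chunks) {
      nR <- length(rs)
      B <- A %*% matrix(fit_coef[, , rs, drop = FALSE],
                        dc[1], nact * nR)            # (g, act[i] * R)
      ctr_add("u_pprime_contraction", ng * nR * dc[1] * nact)
      b <- matrix(0, ng, nR)
      for (r in seq_len(nR))
        b[, r] <- rowSums(B[, (r - 1) * nact + seq_len(nact), drop = FALSE] *
                            phiI)
      W2 <- b %*% t(matrix(raw[, , rs, drop = FALSE], nM * dr[2], nR))
      ctr_add("ut_steps", ng * nR * (nact + nM * dr[2]))
      # E += sum_g w sum_{j,m} W[g,j,m] W2[g,m,j]
      W2a <- array(W2, c(ng, nM, dr[2]))
      E <- E + sum(w * rowSums(matrix(W_block, ng) *
                                 matrix(aperm(W2a, c(1, 3, 2)), ng)))
    }
  }
  E
}
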