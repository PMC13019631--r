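# R-level integral interfaces over the compiled McMurchie-Davidson engine.
# All results are normalized-AO quantities in atomic units.

.scale1 <- function(m, na, nb) m * outer(na, nb)

.scale4 <- function(t4, n1, n2, n3, n4) {
  d <- dim(t4)
  t4 * outer(outer(n1, n2), outer(n3, n4))
}

.kernel_comp <- function(kernel) {
  stopifnot(inherits(kernel, "f12_kernel"))
  kernel$components
}

#' One-electron core integrals
#'
#' Overlap, kinetic and nuclear-attraction matrices between two basis sets on
#' the same molecule.
#' @param basA,basB `f12_basis` objects
#' @return list with S, T, V (and H = T + V)
#' @export
core_hamiltonian <- function(basA, basB = basA) {
  ok <- cpp_overlap_kinetic(basA$cpp, basB$cpp)
  S <- .scale1(ok$S, basA$norm, basB$norm)
  T_ <- .scale1(ok$T, basA$norm, basB$norm)
  mol <- basA$molecule
  pts <- mol$coords
  blk <- cpp_grid3c1e(basA$cpp, basB$cpp, pts, matrix(c(0, 0, 1), 1), NULL)
  V <- matrix(0, basA$nao, basB$nao)
  for (a in seq_len(nrow(pts)))
    V <- V - mol$charges[a] * blk[a, , ]
  V <- .scale1(matrix(V, basA$nao, basB$nao), basA$norm, basB$norm)
  list(S = S, T = T_, V = V, H = T_ + V)
}

#' Four-center two-electron integrals (Dirac convention)
#'
#' Returns the full tensor `<mu nu | O | la si>` in physicists' notation:
#' element `[m, n, l, s]` integrates `mu(r1) nu(r2) O(r12) la(r1) si(r2)`.
#'
#' @param op an `f12_kernel`
#' @param obs orbital basis (bra/ket electron-1 and electron-2 functions)
#' @param ket optional second basis for the ket pair (defaults to `obs`)
#' @return 4-index array in Dirac order
#' @export
eri_4c2e <- function(op, obs, ket = obs) {
  m <- cpp_eri(obs$cpp, ket$cpp, obs$cpp, ket$cpp, .kernel_comp(op))
  m <- .scale4(m, obs$norm, ket$norm, obs$norm, ket$norm)
  # Mulliken (ab|cd) -> Dirac <ac|bd>: <ij|O|kl> = (ik|O|jl)
  aperm(m, c(1, 3, 2, 4))
}

# Mulliken-order chemist tensor (ab|O|cd); used internally
.eri_mulliken <- function(op, basA, basB, basC, basD) {
  m <- cpp_eri(basA$cpp, basB$cpp, basC$cpp, basD$cpp, .kernel_comp(op))
  .scale4(m, basA$norm, basB$norm, basC$norm, basD$norm)
}

#' Two-center two-electron metric and its (pseudo)inverse
#'
#' @param op `f12_kernel` used as fitting metric
#' @param df_aux auxiliary basis
#' @param drop_tol relative eigenvalue drop threshold for the pseudo-inverse
#' @return list(Y, Yinv, n_dropped)
#' @export
df_2c2e <- function(op, df_aux, drop_tol = 1e-10) {
  if (df_aux$nao < 1) stop("empty auxiliary basis")
  m <- cpp_eri(df_aux$cpp, .dummy_cpp(), df_aux$cpp, .dummy_cpp(),
               .kernel_comp(op))
  Y <- matrix(m, df_aux$nao, df_aux$nao) * outer(df_aux$norm, df_aux$norm)
  Y <- 0.5 * (Y + t(Y))
  e <- eigen(Y, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("integral-engine error: DF metric has a significantly negative ",
         "eigenvalue (", signif(min(e$values), 3), ")")
  keep <- e$values > drop_tol * max(e$values)
  Yinv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(Y = Y, Yinv = Yinv, n_dropped = sum(!keep))
}

#' Three-center two-electron integrals (mu nu | O | R)
#'
#' @param op `f12_kernel`
#' @param basA,basB bases of the orbital-product side (electron 1)
#' @param df_aux auxiliary basis (electron 2)
#' @return array (naoA, naoB, naux)
#' @export
df_3c2e <- function(op, basA, basB, df_aux) {
  if (basA$nao == 0L || basB$nao == 0L)
    return(array(0, c(basA$nao, basB$nao, df_aux$nao)))
  m <- cpp_eri(basA$cpp, basB$cpp, df_aux$cpp, .dummy_cpp(), .kernel_comp(op))
  m <- array(m, c(basA$nao, basB$nao, df_aux$nao))
  m * outer(outer(basA$norm, basB$norm), df_aux$norm)
}

#' Grid-point one-electron kernel integrals (g | O_1g | mu nu)
#'
#' Evaluates the operator centered at each grid point against AO pairs, with
#' optional conservative distance screening of shell pairs.
#'
#' @param op `f12_kernel` (F, G, FG or F2)
#' @param batch list with `points` (n x 3) and optionally `w` weights
#' @param basA,basB AO bases of the pair
#' @param theta_nq screening threshold; 0 disables screening
#' @return array (npoints, naoA, naoB); screened-out shell-pair blocks are 0
#' @export
grid_3c1e <- function(op, batch, basA, basB = basA, theta_nq = 0) {
  pts <- batch$points
  pairs <- NULL
  n_skipped <- 0L
  if (theta_nq > 0) {
    sp <- .screen_pairs(op, batch, basA, basB, theta_nq)
    pairs <- sp$pairs
    n_skipped <- sp$n_skipped
    if (nrow(pairs) == 0L) {
      out <- array(0, c(nrow(pts), basA$nao, basB$nao))
      attr(out, "n_skipped") <- n_skipped
      return(out)
    }
  }
  m <- cpp_grid3c1e(basA$cpp, basB$cpp, pts, .kernel_comp(op), pairs)
  m <- array(m, c(nrow(pts), basA$nao, basB$nao))
  m <- m * rep(outer(basA$norm, basB$norm), each = nrow(pts))
  attr(m, "n_skipped") <- n_skipped
  m
}

# Conservative screening bound for a (batch, shell pair, operator):
#   bound = max batch weight * pair magnitude bound * radial kernel envelope
# The pair bound uses the Gaussian-product prefactor; the envelope is the
# kernel evaluated at the closest approach of the batch to the pair center
# minus the pair extent (soundness enforced by the audit tests).
.screen_pairs <- function(op, batch, basA, basB, theta) {
  wmax <- if (!is.null(batch$w)) max(batch$w) else 1
  pts <- batch$points
  ctr <- colMeans(pts)
  brad <- sqrt(max(rowSums((pts - rep(ctr, each = nrow(pts)))^2)))
  g <- op$gamma
  env_fun <- switch(op$op,
    G = function(R) ifelse(R <= 0, Inf, 1 / R),
    F = function(R) exp(-g * pmax(R, 0)) / g,
    FG = function(R) ifelse(R <= 0, Inf, exp(-g * R) / (g * R)),
    F2 = function(R) exp(-2 * g * pmax(R, 0)) / g^2,
    DEL2F = function(R) exp(-2 * g * pmax(R, 0)))
  pd <- .pair_table(basA, basB)
  R <- pmax(0, sqrt((pd$mx - ctr[1])^2 + (pd$my - ctr[2])^2 +
                      (pd$mz - ctr[3])^2) - brad - pd$ext)
  ok <- wmax * pd$mag * env_fun(R) >= theta
  list(pairs = cbind(pd$ia[ok], pd$ib[ok]), n_skipped = sum(!ok))
}

# static shell-pair screening data (centers, extents, Gaussian prefactors)
.pair_table <- function(basA, basB) {
  cA <- cbind(basA$cpp$cx, basA$cpp$cy, basA$cpp$cz)
  cB <- cbind(basB$cpp$cx, basB$cpp$cy, basB$cpp$cz)
  eA <- vapply(basA$shells, function(s) min(s$exponents), numeric(1))
  eB <- vapply(basB$shells, function(s) min(s$exponents), numeric(1))
  nA <- length(eA); nB <- length(eB)
  ia <- rep(seq_len(nA), times = nB); ib <- rep(seq_len(nB), each = nA)
  d2 <- (cA[ia, 1] - cB[ib, 1])^2 + (cA[ia, 2] - cB[ib, 2])^2 +
    (cA[ia, 3] - cB[ib, 3])^2
  pmin_ <- eA[ia] + eB[ib]
  mu <- eA[ia] * eB[ib] / pmin_
  list(ia = ia - 1L, ib = ib - 1L,
       mx = (cA[ia, 1] + cB[ib, 1]) / 2, my = (cA[ia, 2] + cB[ib, 2]) / 2,
       mz = (cA[ia, 3] + cB[ib, 3]) / 2,
       mag = exp(-mu * d2), ext = sqrt(d2) / 2 + sqrt(38 / pmin_))
}

#' AO-to-MO transformation of grid 3c1e blocks
#'
#' Two-sided transformation performed in sub-batches of grid points so only
#' one AO sub-block is resident at a time; the result is independent of the
#' sub-batch size.
#'
#' @param tensor array (ng, naoA, naoB)
#' @param C_left,C_right coefficient blocks (naoA x nL), (naoB x nR)
#' @param sub_batch grid sub-batch size (default 16)
#' @return array (ng, nL, nR)
#' @export
mo_transform_3c1e <- function(tensor, C_left, C_right, sub_batch = 16L) {
  d <- dim(tensor)
  if (d[2] != nrow(C_left) || d[3] != nrow(C_right))
    stop("shape mismatch in MO transformation")
  ng <- d[1]
  nL <- ncol(C_left); nR <- ncol(C_right)
  out <- array(0, c(ng, nL, nR))
  idx <- split(seq_len(ng), ceiling(seq_len(ng) / sub_batch))
  for (ii in idx) {
    blk <- tensor[ii, , , drop = FALSE]
    # contract AO index 2 with C_left
    m <- matrix(aperm(blk, c(1, 3, 2)), length(ii) * d[3], d[2]) %*% C_left
    m <- aperm(array(m, c(length(ii), d[3], nL)), c(1, 3, 2))
    # contract AO index 3 with C_right
    m <- matrix(m, length(ii) * nL, d[3]) %*% C_right
    out[ii, , ] <- array(m, c(length(ii), nL, nR))
  }
  out
}

# contract AO dim k (2 or 3) of (ng, n2, n3) with matrix M (n_k x m)
.ctr3 <- function(arr, M, k) {
  d <- dim(arr)
  if (k == 2L) {
    m <- matrix(aperm(arr, c(1, 3, 2)), d[1] * d[3], d[2]) %*% M
    aperm(array(m, c(d[1], d[3], ncol(M))), c(1, 3, 2))
  } else {
    array(matrix(arr, d[1] * d[2], d[3]) %*% M, c(d[1], d[2], ncol(M)))
  }
}
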