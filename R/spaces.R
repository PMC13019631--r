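# Orbital-space bookkeeping: CABS construction by Loewdin orthogonalization of
# the orbital/auxiliary union basis with projection of the Hartree-Fock span,
# and assembly of the index families (active occupied i,j / occupied k,l /
# virtual a,b / occ+virt p,q / CABS p" / union p') with Fock and exchange
# matrices over the union space.

#' Build the complementary auxiliary basis set (CABS)
#'
#' The union basis {mu} u {mu"} is Loewdin-orthogonalized with truncation of
#' small overlap eigenvalues; the HF MO span is projected out via an SVD of
#' the overlap between the orthonormalized union functions and the MOs,
#' keeping singular values < 0.5 as CABS.
#'
#' @param obs orbital basis
#' @param cabs_aux CABS auxiliary basis
#' @param reference `f12_reference`
#' @param drop_tol union-overlap eigenvalue drop threshold
#' @return list with the union basis, CABS coefficients over the union AO
#'   basis, the union overlap S', the RI projector Pi = S'^-1 (pseudo-inverse
#'   on the retained subspace), and truncation counters
#' @export
build_cabs <- function(obs, cabs_aux, reference, drop_tol = 1e-8) {
  if (length(cabs_aux$shells) == 0L) stop("degenerate input: empty CABS auxiliary basis")
  union_bas <- .basis_union(obs, cabs_aux)
  Su <- core_hamiltonian(union_bas)$S
  es <- eigen(Su, symmetric = TRUE)
  keep <- es$values > drop_tol
  n_dropped <- sum(!keep)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Pi <- tcrossprod(X)                     # S'^-1 on the retained subspace
  # HF MOs embedded in the union AO basis (orbital AOs come first)
  n_mo <- ncol(reference$C)
  C_u <- rbind(reference$C, matrix(0, union_bas$nao - obs$nao, n_mo))
  O <- t(X) %*% Su %*% C_u                # overlap of Loewdin set with MOs
  sv <- svd(O)
  cab_idx <- which(c(sv$d, rep(0, ncol(X) - length(sv$d))) < 0.5)
  Ufull <- sv$u
  if (ncol(Ufull) < ncol(X)) {
    # complete the left singular basis
    Q <- qr.Q(qr(cbind(Ufull, diag(ncol(X)))))[, seq_len(ncol(X)), drop = FALSE]
    Ufull <- Q
  }
  C_cabs <- X %*% Ufull[, cab_idx, drop = FALSE]
  list(union_basis = union_bas, C_cabs = C_cabs, S_union = Su, Pi = Pi,
       n_dropped = n_dropped, n_cabs = length(cab_idx), obs = obs,
       cabs_aux = cabs_aux, reference = reference)
}

#' Assemble the orbital-space index families
#'
#' Transforms Fock and exchange matrices to the union MO basis p' and records
#' the coefficient blocks of every index family over the union AO basis.
#' With `gbc_ebc = TRUE` the Fock blocks between the occupied/virtual space
#' and the CABS space are set to zero, as assumed by the generalized and
#' extended Brillouin conditions.
#'
#' @param reference `f12_reference`
#' @param cabs result of [build_cabs()]
#' @param frozen_core number of frozen core orbitals
#' @param gbc_ebc apply GBC/EBC zeroing of Fock p-CABS blocks
#' @return object of class `f12_spaces`
#' @export
assemble_spaces <- function(reference, cabs, frozen_core = 0L,
                            gbc_ebc = TRUE) {
  nocc <- reference$nocc
  if (frozen_core >= nocc)
    stop("invalid configuration: frozen_core (", frozen_core,
         ") must be smaller than the occupied count (", nocc, ")")
  obs <- reference$obs
  ub <- cabs$union_basis
  n_mo <- ncol(reference$C)
  C_u <- rbind(reference$C, matrix(0, ub$nao - obs$nao, n_mo))
  C_all <- cbind(C_u, cabs$C_cabs)        # p' = (p, p")
  # union-basis Fock and exchange in AO representation
  Hu <- core_hamiltonian(ub)$H
  P <- reference$P
  eriJ <- .eri_mulliken(kernel_spec("G"), ub, ub, obs, obs)
  nu <- ub$nao; no <- obs$nao
  Jm <- matrix(array(eriJ, c(nu * nu, no * no)) %*% as.vector(P), nu, nu)
  eriK <- .eri_mulliken(kernel_spec("G"), ub, obs, ub, obs)
  Km <- matrix(array(aperm(eriK, c(1, 3, 2, 4)), c(nu * nu, no * no)) %*%
                 as.vector(P), nu, nu)
  f_ao <- Hu + 2 * Jm - Km
  k_ao <- Km
  f_mo <- t(C_all) %*% f_ao %*% C_all
  k_mo <- t(C_all) %*% k_ao %*% C_all
  nvirt <- n_mo - nocc
  n_cabs <- ncol(cabs$C_cabs)
  idx <- list(occ = seq_len(nocc),
              act = seq.int(frozen_core + 1L, nocc),
              virt = if (nvirt > 0) nocc + seq_len(nvirt) else integer(0),
              p = seq_len(n_mo),
              cabs = if (n_cabs > 0) n_mo + seq_len(n_cabs) else integer(0),
              all = seq_len(n_mo + n_cabs))
  if (gbc_ebc && n_cabs > 0) {
    f_mo[idx$p, idx$cabs] <- 0
    f_mo[idx$cabs, idx$p] <- 0
  }
  eps_p <- reference$eps
  sp <- structure(list(
    molecule = reference$molecule, obs = obs, cabs_aux = cabs$cabs_aux,
    union_basis = ub, reference = reference,
    C = C_all, idx = idx, eps = eps_p,
    S_union = cabs$S_union, Pi = cabs$Pi,
    f_mo = f_mo, k_mo = k_mo, f_ao = f_ao, k_ao = k_ao,
    frozen_core = as.integer(frozen_core), gbc_ebc = gbc_ebc,
    n_dropped = cabs$n_dropped,
    dims = c(n_ao = obs$nao, n_union_ao = ub$nao, n_occ = nocc,
             n_act = nocc - frozen_core, n_virt = nvirt, n_cabs = n_cabs,
             n_union = n_mo + n_cabs)),
    class = "f12_spaces")
  .validate_spaces(sp)
  sp
}

.validate_spaces <- function(sp, tol = 1e-8) {
  # occupied orthogonal to CABS in the union metric
  if (length(sp$idx$cabs)) {
    ov <- t(sp$C[, sp$idx$occ, drop = FALSE]) %*% sp$S_union %*%
      sp$C[, sp$idx$cabs, drop = FALSE]
    if (max(abs(ov)) > tol)
      stop("orbital-space invariant violated: occupied/CABS overlap ",
           signif(max(abs(ov)), 3))
  }
  d <- sp$Pi %*% sp$S_union %*% sp$Pi - sp$Pi
  if (max(abs(d)) > tol * max(1, max(abs(sp$Pi))))
    stop("orbital-space invariant violated: Pi S' Pi != Pi (",
         signif(max(abs(d)), 3), " relative to |Pi| = ",
         signif(max(abs(sp$Pi)), 3), ")")
  invisible(sp)
}

#' @export
print.f12_spaces <- function(x, ...) {
  d <- x$dims
  cat("Orbital spaces: ", d["n_occ"], " occ (", d["n_act"], " active), ",
      d["n_virt"], " virt, ", d["n_cabs"], " CABS, union dim ", d["n_union"],
      " over ", d["n_union_ao"], " AOs (", x$n_dropped,
      " union-overlap vectors dropped)\n", sep = "")
  invisible(x)
}

# coefficient blocks over the union AO basis
.coef_block <- function(sp, fam) sp$C[, sp$idx[[fam]], drop = FALSE]

# blocks over the orbital AO basis only (valid for occ/act/virt/p families)
.coef_block_obs <- function(sp, fam)
  sp$C[seq_len(sp$obs$nao), sp$idx[[fam]], drop = FALSE]
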