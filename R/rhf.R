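# Minimal closed-shell restricted Hartree-Fock with DIIS, using the package's
# own Coulomb integrals.  Only intended for the small fixture systems; an
# external reference provider satisfying the same contract may replace it.

.eigen_asc <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  o <- order(e$values)
  list(values = e$values[o], vectors = e$vectors[, o, drop = FALSE])
}

.jk_matrices <- function(eri_m, P) {
  n <- dim(eri_m)[1]
  Jm <- matrix(array(eri_m, c(n * n, n * n)) %*% as.vector(P), n, n)
  Km <- matrix(array(aperm(eri_m, c(1, 3, 2, 4)), c(n * n, n * n)) %*%
                 as.vector(P), n, n)
  list(J = Jm, K = Km)
}

#' Compute a closed-shell RHF reference state
#'
#' @param molecule `f12_molecule` (closed shell)
#' @param obs orbital basis
#' @param backend `"internal"` for the built-in RHF, or a function
#'   `(molecule, obs) -> list(C, eps, scf_energy)` supplying converged
#'   canonical orbitals; the returned state is validated either way
#' @param conv_tol DIIS commutator-norm convergence criterion
#' @param max_iter iteration cap
#' @return object of class `f12_reference` with MO coefficients `C`, orbital
#'   energies `eps`, occupied density `P` (P = C_occ C_occ^T, spinless),
#'   AO Fock `f`, AO exchange `k`, overlap `S` and `scf_energy`
#' @export
compute_reference <- function(molecule, obs, backend = "internal",
                              conv_tol = 1e-9, max_iter = 200L) {
  if (molecule$multiplicity != 1L)
    stop("unsupported system: only closed-shell references are available")
  core <- core_hamiltonian(obs)
  S <- core$S
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10 * max(es$values))
    stop("conditioning error: orbital basis is numerically linearly dependent")
  X <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  nocc <- molecule$nelec %/% 2L
  if (nocc > obs$nao) stop("basis too small for the electron count")
  eri_m <- .eri_mulliken(kernel_spec("G"), obs, obs, obs, obs)

  if (is.function(backend)) {
    ext <- backend(molecule, obs)
    C <- ext$C; eps <- ext$eps
    P <- tcrossprod(C[, seq_len(nocc), drop = FALSE])
    jk <- .jk_matrices(eri_m, P)
    f <- core$H + 2 * jk$J - jk$K
    e_scf <- if (!is.null(ext$scf_energy)) ext$scf_energy else
      sum(P * (core$H + f)) + nuclear_repulsion(molecule)
    conv <- NA_real_
    trace <- numeric(0)
  } else {
    # core guess
    hx <- t(X) %*% core$H %*% X
    ev <- .eigen_asc(hx)
    C <- X %*% ev$vectors
    P <- tcrossprod(C[, seq_len(nocc), drop = FALSE])
    err_list <- list(); f_list <- list()
    conv <- Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      jk <- .jk_matrices(eri_m, P)
      f <- core$H + 2 * jk$J - jk$K
      err <- f %*% P %*% S - S %*% P %*% f
      conv <- sqrt(sum(err^2))
      trace <- c(trace, conv)
      if (conv <= conv_tol) break
      # DIIS
      err_list[[length(err_list) + 1L]] <- err
      f_list[[length(f_list) + 1L]] <- f
      if (length(err_list) > 8L) {
        err_list <- err_list[-1L]; f_list <- f_list[-1L]
      }
      m <- length(err_list)
      if (m >= 2L) {
        B <- matrix(0, m + 1, m + 1)
        for (i in 1:m) for (j in 1:m)
          B[i, j] <- sum(err_list[[i]] * err_list[[j]])
        B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
        if (!is.null(cf)) {
          f <- Reduce(`+`, Map(`*`, f_list, cf))
        }
      }
      fx <- t(X) %*% f %*% X
      ev <- .eigen_asc(fx)
      C <- X %*% ev$vectors
      P <- tcrossprod(C[, seq_len(nocc), drop = FALSE])
    }
    if (conv > conv_tol)
      stop("SCF convergence error: commutator norm ", signif(conv, 3),
           " after ", max_iter, " iterations (trace: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "), ")")
    jk <- .jk_matrices(eri_m, P)
    f <- core$H + 2 * jk$J - jk$K
    fx <- t(X) %*% f %*% X
    ev <- .eigen_asc(fx)
    C <- X %*% ev$vectors
    eps <- ev$values
    P <- tcrossprod(C[, seq_len(nocc), drop = FALSE])
    e_scf <- sum(P * (core$H + f)) + nuclear_repulsion(molecule)
  }

  jk <- .jk_matrices(eri_m, P)
  k_ao <- jk$K
  f <- core$H + 2 * jk$J - k_ao
  ref <- structure(list(C = C, eps = eps, P = P, f = f, k = k_ao, S = S,
                        H = core$H, nocc = nocc, scf_energy = e_scf,
                        conv = conv, molecule = molecule, obs = obs),
                   class = "f12_reference")
  .validate_reference(ref)
  ref
}

.validate_reference <- function(ref, tol_orth = 1e-9, tol_idem = 1e-8,
                                tol_canon = 1e-7) {
  d1 <- max(abs(t(ref$C) %*% ref$S %*% ref$C - diag(ncol(ref$C))))
  if (d1 > tol_orth)
    stop("reference state invalid: C^T S C deviates from identity by ",
         signif(d1, 3))
  psp <- ref$P %*% ref$S %*% ref$P
  d2 <- max(abs(psp - ref$P))
  if (d2 > tol_idem)
    stop("reference state invalid: density not idempotent through S (",
         signif(d2, 3), ")")
  fmo <- t(ref$C) %*% ref$f %*% ref$C
  d3 <- max(abs(fmo - diag(diag(fmo), nrow(fmo))))
  if (d3 > tol_canon)
    stop("non-canonical reference: off-diagonal MO Fock element ",
         signif(d3, 3), "; canonical orbitals are required")
  invisible(ref)
}

#' @export
print.f12_reference <- function(x, ...) {
  cat("RHF reference: E_SCF =", format(x$scf_energy, digits = 12),
      "hartree,", x$nocc, "occupied of", ncol(x$C), "orbitals\n")
  invisible(x)
}
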