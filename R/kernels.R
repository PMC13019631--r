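# Operator kernels of F12 theory and the Gaussian expansion of the Slater
# correlation factor.
#
# Closed r12 forms:
#   F    = exp(-g r)/g          (correlation factor, g = gamma)
#   G    = 1/r                  (Coulomb)
#   FG   = exp(-g r)/(g r)
#   F2   = exp(-2 g r)/g^2
#   DEL2F= exp(-2 g r) = g^2 * F2   (gradient-square of F)
#
# F, F2 and DEL2F are evaluated through an STG-nG expansion
# exp(-z r) ~ sum_k c_k exp(-beta_k r^2); FG keeps the exact Coulomb
# singularity by damping 1/r with each Gaussian of the exp(-g r) fit.

.stg_cache <- new.env(parent = emptyenv())

#' Fit a Slater function by Gaussians
#'
#' Deterministic weighted least-squares fit of exp(-zeta r) by
#' sum_k c_k exp(-beta_k r^2) on a logarithmic mesh with weight r^2.  The
#' Gaussian exponents form a fixed even-tempered ladder scaled by zeta^2, so
#' fits of increasing n are nested and the stored residual is non-increasing
#' in n.
#'
#' @param target_exponent Slater exponent zeta (bohr^-1)
#' @param n number of Gaussians (3..12); a single Gaussian is also accepted
#'   for degenerate one-point fits
#' @param fit_domain c(r_min, r_max) in bohr
#' @param n_mesh number of mesh points
#' @param fit_tol weighted-RMS residual tolerance
#' @return object of class `f12_stg` with fields `coef`, `beta`, `residual`,
#'   `max_abs_dev`
#' @export
fit_stg <- function(target_exponent, n = 6L, fit_domain = c(1e-3, 10),
                    n_mesh = 240L, fit_tol = 5e-3) {
  zeta <- target_exponent
  if (zeta <= 0) stop("target exponent must be positive")
  if (n < 1L || n > 12L) stop("n must be between 1 and 12")
  key <- paste(signif(zeta, 14), n, signif(fit_domain[1], 10),
               signif(fit_domain[2], 10), n_mesh, sep = "|")
  if (!is.null(.stg_cache[[key]])) return(.stg_cache[[key]])
  if (fit_domain[1] <= 0 || fit_domain[2] <= fit_domain[1])
    stop("fit domain must be positive and increasing")
  beta <- zeta^2 * 0.16 * 5.2^(seq_len(n) - 1)
  r <- exp(seq(log(fit_domain[1]), log(fit_domain[2]), length.out = n_mesh))
  w <- r^2
  A <- exp(-outer(r^2, beta))
  y <- exp(-zeta * r)
  Ws <- sqrt(w)
  sv <- svd(A * Ws)
  keep <- sv$d > 1e-12 * sv$d[1]
  if (!any(keep)) stop("STG fit is ill-conditioned; try a smaller n")
  cf <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y * Ws)) / sv$d[keep])
  cf <- drop(cf)
  dev <- drop(A %*% cf) - y
  res <- sqrt(sum(w * dev^2) / sum(w))
  if (res > fit_tol)
    stop("STG fit residual ", signif(res, 3), " exceeds tolerance ",
         fit_tol, "; try a smaller n or a narrower domain")
  out <- structure(list(target_exponent = zeta, n = n, coef = cf, beta = beta,
                        fit_domain = fit_domain, residual = res,
                        max_abs_dev = max(abs(dev))),
                   class = "f12_stg")
  .stg_cache[[key]] <- out
  out
}

#' Evaluate an STG expansion
#' @param stg `f12_stg` object
#' @param r radii (bohr)
#' @export
stg_value <- function(stg, r) {
  drop(exp(-outer(r^2, stg$beta)) %*% stg$coef)
}

#' Kernel specification
#'
#' @param op one of "F", "G", "FG", "F2", "DEL2F"
#' @param gamma correlation-factor exponent (bohr^-1)
#' @param n_stg number of Gaussians in the Slater expansion
#' @return `f12_kernel` with the component table used by the integral engine
#' @export
kernel_spec <- function(op = c("F", "G", "FG", "F2", "DEL2F"), gamma = 1.3,
                        n_stg = 6L) {
  op <- match.arg(op)
  if (gamma <= 0) stop("gamma must be positive")
  comp <- switch(op,
    G = matrix(c(0, 0, 1), 1),
    F = {
      s <- fit_stg(gamma, n_stg)
      cbind(1, s$beta, s$coef / gamma)
    },
    FG = {
      s <- fit_stg(gamma, n_stg)
      cbind(2, s$beta, s$coef / gamma)
    },
    F2 = {
      s <- fit_stg(2 * gamma, n_stg)
      cbind(1, s$beta, s$coef / gamma^2)
    },
    DEL2F = {
      s <- fit_stg(2 * gamma, n_stg)
      cbind(1, s$beta, s$coef)
    })
  structure(list(op = op, gamma = gamma, n_stg = as.integer(n_stg),
                 components = unname(comp)),
            class = "f12_kernel")
}

#' Closed-form kernel value
#'
#' Exact r12 dependence of the operator (not the Gaussian expansion).
#' @param kernel `f12_kernel`
#' @param r radii (bohr)
#' @export
kernel_value <- function(kernel, r) {
  g <- kernel$gamma
  switch(kernel$op,
    F = exp(-g * r) / g,
    G = 1 / r,
    FG = exp(-g * r) / (g * r),
    F2 = exp(-2 * g * r) / g^2,
    DEL2F = exp(-2 * g * r))
}

#' Fitted kernel value (Gaussian expansion, exact 1/r factors kept)
#' @inheritParams kernel_value
#' @export
kernel_fitted_value <- function(kernel, r) {
  cm <- kernel$components
  v <- numeric(length(r))
  for (i in seq_len(nrow(cm))) {
    base <- if (cm[i, 1] == 0) 1 / r
            else if (cm[i, 1] == 1) exp(-cm[i, 2] * r^2)
            else exp(-cm[i, 2] * r^2) / r
    v <- v + cm[i, 3] * base
  }
  v
}

#' @export
print.f12_kernel <- function(x, ...) {
  cat("F12 kernel ", x$op, " (gamma = ", x$gamma, ", ",
      nrow(x$components), " radial components)\n", sep = "")
  invisible(x)
}
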