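# Pruned atom-centered molecular quadrature grids with Becke partitioning.
#
# Radial: Mura-Knowles log mapping r = -alpha log(1 - x^3).
# Angular: spherical product rules (Gauss-Legendre in cos(theta) x uniform
# phi) matched to the polynomial exactness degree of the nominal angular
# order of each pruning region; angular grids are generated in the molecule's
# principal-axis frame so that rigid rotations leave all results invariant.
# Pruning regions are split at {0.35, 1.0} x Bragg-Slater radius.

.grid_table <- list(
  g0 = list(nrad = 15L, ang = c(14L, 38L, 74L)),
  g1 = list(nrad = 20L, ang = c(14L, 50L, 110L)),
  g2 = list(nrad = 25L, ang = c(26L, 74L, 194L)),
  g3 = list(nrad = 35L, ang = c(38L, 110L, 302L)),
  g4 = list(nrad = 45L, ang = c(50L, 194L, 434L)),
  g7 = list(nrad = 65L, ang = c(110L, 434L, 1454L))
)

# polynomial exactness degree of the nominal (Lebedev) angular orders
.ang_degree <- c(`6` = 3, `14` = 5, `26` = 7, `38` = 9, `50` = 11, `74` = 13,
                 `86` = 15, `110` = 17, `146` = 19, `170` = 21, `194` = 23,
                 `302` = 29, `350` = 31, `434` = 35, `590` = 41, `770` = 47,
                 `974` = 53, `1202` = 59, `1454` = 65)

.gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  o <- order(e$values)
  list(x = e$values[o], w = 2 * e$vectors[1, o]^2)
}

# unit sphere rule for a nominal angular order
.angular_rule <- function(order) {
  deg <- .ang_degree[as.character(order)]
  if (is.na(deg)) stop("configuration error: unknown angular order ", order)
  nt <- ceiling((deg + 1) / 2)
  np <- 2L * nt
  gl <- .gauss_legendre(nt)
  phi <- 2 * pi * (seq_len(np) - 0.5) / np
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  pts <- cbind(rep(st, each = np) * cos(phi),
               rep(st, each = np) * sin(phi),
               rep(ct, each = np))
  w <- rep(gl$w, each = np) * (2 * pi / np)
  list(pts = pts, w = w)
}

# deterministic principal-axis frame of the nuclear charge distribution
.molecular_frame <- function(mol) {
  n <- nrow(mol$coords)
  if (n == 1L) return(diag(3))
  z <- mol$charges
  c0 <- colSums(mol$coords * z) / sum(z)
  d <- sweep(mol$coords, 2, c0)
  M <- t(d * z) %*% d
  e <- eigen(M, symmetric = TRUE)
  R <- e$vectors
  for (k in 1:3) {
    j <- which.max(abs(R[, k]))
    if (R[j, k] < 0) R[, k] <- -R[, k]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

.becke_weights <- function(mol, pts, parent) {
  n_at <- nrow(mol$coords)
  if (n_at == 1L) return(rep(1, nrow(pts)))
  rb <- bragg_radius_bohr(mol$symbols)
  ng <- nrow(pts)
  dist <- matrix(0, ng, n_at)
  for (a in seq_len(n_at))
    dist[, a] <- sqrt(rowSums((pts - rep(mol$coords[a, ], each = ng))^2))
  Rij <- as.matrix(stats::dist(mol$coords))
  P <- matrix(1, ng, n_at)
  for (a in seq_len(n_at)) for (b in seq_len(n_at)) {
    if (a == b) next
    mu <- (dist[, a] - dist[, b]) / Rij[a, b]
    chi <- rb[a] / rb[b]
    u <- (chi - 1) / (chi + 1)
    aab <- u / (u^2 - 1)
    aab <- max(min(aab, 0.5), -0.5)
    nu <- mu + aab * (1 - mu^2)
    f <- nu
    for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
    P[, a] <- P[, a] * 0.5 * (1 - f)
  }
  tot <- rowSums(P)
  P[cbind(seq_len(ng), parent)] / tot
}

#' Build a pruned molecular quadrature grid
#'
#' @param molecule `f12_molecule`
#' @param level grid level tag: "g0".."g4" or "g7"
#' @param weight_threshold relative point-screening threshold; a point g is
#'   dropped when `w_g * max_mu chi_mu(g)^2` falls below `weight_threshold`
#'   times the global maximum of that quantity (with `obs = NULL` the bare
#'   weights are compared instead); 0 disables screening
#' @param obs optional orbital basis used for the amplitude factor of the
#'   screening criterion
#' @return object of class `f12_grid` with points, weights (bohr^3), parent
#'   atoms and layout metadata
#' @export
build_grid <- function(molecule, level = "g2", weight_threshold = 1e-5,
                       obs = NULL) {
  tab <- .grid_table[[level]]
  if (is.null(tab)) stop("configuration error: unknown grid level '", level, "'")
  frame <- .molecular_frame(molecule)
  rules <- lapply(tab$ang, .angular_rule)
  alpha <- 5.0
  nrad <- tab$nrad
  x <- seq_len(nrad) / (nrad + 1)
  r_rad <- -alpha * log(1 - x^3)
  w_rad <- r_rad^2 * alpha * 3 * x^2 / (1 - x^3) / (nrad + 1)
  pts <- NULL; w <- NULL; parent <- integer(0); region <- integer(0)
  rb <- bragg_radius_bohr(molecule$symbols)
  for (a in seq_along(molecule$symbols)) {
    bounds <- c(0.35, 1.0) * rb[a]
    reg <- findInterval(r_rad, bounds) + 1L
    for (i in seq_len(nrad)) {
      rule <- rules[[reg[i]]]
      p <- rule$pts %*% t(frame)
      pts <- rbind(pts, p * r_rad[i] +
                     rep(molecule$coords[a, ], each = nrow(p)))
      w <- c(w, rule$w * w_rad[i])
      parent <- c(parent, rep(a, nrow(p)))
      region <- c(region, rep(reg[i], nrow(p)))
    }
  }
  bw <- .becke_weights(molecule, pts, parent)
  w <- w * bw
  n_total <- length(w)
  keep <- rep(TRUE, n_total)
  if (weight_threshold > 0) {
    crit <- if (!is.null(obs)) {
      amps <- cpp_eval_aos(obs$cpp, pts) * rep(obs$norm, each = n_total)
      w * apply(abs(amps), 1, max)^2
    } else w
    keep <- crit >= weight_threshold * max(crit)
  }
  structure(list(
    molecule = molecule, level = level,
    points = pts[keep, , drop = FALSE], w = w[keep],
    parent = parent[keep], region = region[keep],
    weight_threshold = weight_threshold,
    n_total = n_total, n_kept = sum(keep), n_dropped = n_total - sum(keep),
    nrad = nrad, ang_orders = tab$ang, frame = frame),
    class = "f12_grid")
}

#' @export
print.f12_grid <- function(x, ...) {
  cat("Molecular grid ", x$level, ": ", x$n_kept, " points kept / ",
      x$n_total, " constructed (radial ", x$nrad, ", angular orders ",
      paste(x$ang_orders, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

# Morton (Z-order) key for spatial batch locality
.morton_key <- function(pts) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  span <- pmax(hi - lo, 1e-12)
  q <- floor(sweep(sweep(pts, 2, lo), 2, span, "/") * 1023.999)
  key <- numeric(nrow(pts))
  for (b in 0:9) {
    bit <- q %/% 2^b %% 2
    key <- key + bit[, 1] * 2^(3 * b + 2) + bit[, 2] * 2^(3 * b + 1) +
      bit[, 3] * 2^(3 * b)
  }
  key
}

#' Partition a grid into batches with per-batch significant AOs
#'
#' @param grid `f12_grid`
#' @param obs orbital basis used for AO significance
#' @param batch_cap maximum points per batch
#' @param ao_threshold absolute AO amplitude threshold; an AO is listed for a
#'   batch when its maximum amplitude on the batch exceeds it (0 lists all)
#' @return list of batches: each has points, w, ao_idx, shell_idx
#' @export
make_batches <- function(grid, obs, batch_cap = 64L, ao_threshold = 1e-10) {
  if (batch_cap < 1L) stop("configuration error: batch_cap must be >= 1")
  ord <- order(.morton_key(grid$points), seq_len(grid$n_kept))
  n <- length(ord)
  starts <- seq(1L, n, by = batch_cap)
  lapply(starts, function(s) {
    ii <- ord[s:min(s + batch_cap - 1L, n)]
    pts <- grid$points[ii, , drop = FALSE]
    amps <- cpp_eval_aos(obs$cpp, pts) * rep(obs$norm, each = length(ii))
    mx <- apply(abs(amps), 2, max)
    ao_idx <- if (ao_threshold > 0) which(mx > ao_threshold) else
      seq_len(obs$nao)
    shell_idx <- sort(unique(obs$ao_shell[ao_idx]))
    list(points = pts, w = grid$w[ii], ao_idx = ao_idx,
         shell_idx = shell_idx, amps = amps)
  })
}

#' AO amplitudes on a batch
#'
#' Amplitudes are returned for the batch's significant AO list only; all
#' other columns are zero.
#'
#' @param batch a batch from [make_batches()] (or any list with `points` and
#'   optionally `ao_idx`)
#' @param obs orbital basis
#' @return matrix (npoints x nao)
#' @export
eval_aos <- function(batch, obs) {
  ng <- nrow(batch$points)
  amps <- cpp_eval_aos(obs$cpp, batch$points) * rep(obs$norm, each = ng)
  if (!is.null(batch$ao_idx) && length(batch$ao_idx) < obs$nao) {
    z <- matrix(0, ng, obs$nao)
    z[, batch$ao_idx] <- amps[, batch$ao_idx, drop = FALSE]
    return(z)
  }
  amps
}
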