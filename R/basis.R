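# Gaussian basis sets: container, Gaussian94-format reader, embedded fixture
# library, and the flattened shell layout handed to the compiled integral
# kernels.  Cartesian components are used throughout (6 d functions); each
# contracted AO is normalized to unit self-overlap.

.l_codes <- c(S = 0L, P = 1L, D = 2L)

#' Construct a basis set for a molecule
#'
#' @param shells list of shells; each shell is a list with fields
#'   `center` (atom index), `l` (0, 1 or 2), `exponents`, `coefficients`
#' @param molecule the `f12_molecule` the shells refer to
#' @param role one of "orbital", "cabs_aux", "df_aux"
#' @return an `f12_basis` object with per-AO normalization folded in
#' @export
basis_set <- function(shells, molecule, role = c("orbital", "cabs_aux", "df_aux")) {
  role <- match.arg(role)
  for (s in shells) {
    if (any(s$exponents <= 0)) stop("basis exponents must be positive")
    if (s$l > 2L) stop("angular momentum above d is not supported")
    if (length(s$exponents) != length(s$coefficients))
      stop("exponent/coefficient length mismatch")
  }
  b <- structure(list(shells = shells, molecule = molecule, role = role),
                 class = "f12_basis")
  b$cpp <- .shells_to_cpp(b)
  b$nao <- .basis_nao(b)
  b$norm <- rep(1, b$nao)
  raw_s <- cpp_overlap_kinetic(b$cpp, b$cpp)$S
  d <- diag(raw_s)
  if (any(d <= 0)) stop("degenerate basis function (zero self-overlap)")
  b$norm <- 1 / sqrt(d)
  b$ao_shell <- .basis_ao_shell(b)
  b
}

.basis_nao <- function(b) sum(vapply(b$shells, function(s)
  as.integer((s$l + 1L) * (s$l + 2L) / 2L), integer(1)))

.basis_ao_shell <- function(b) {
  rep(seq_along(b$shells), vapply(b$shells, function(s)
    as.integer((s$l + 1L) * (s$l + 2L) / 2L), integer(1)))
}

.shells_to_cpp <- function(b) {
  sh <- b$shells
  mol <- b$molecule
  np <- vapply(sh, function(s) length(s$exponents), integer(1))
  list(
    l = vapply(sh, function(s) as.integer(s$l), integer(1)),
    cx = vapply(sh, function(s) mol$coords[s$center, 1], numeric(1)),
    cy = vapply(sh, function(s) mol$coords[s$center, 2], numeric(1)),
    cz = vapply(sh, function(s) mol$coords[s$center, 3], numeric(1)),
    pstart = as.integer(cumsum(c(0L, np[-length(np)]))),
    pnum = as.integer(np),
    pexp = unlist(lapply(sh, function(s) s$exponents)),
    pcoef = unlist(lapply(sh, function(s) s$coefficients))
  )
}

# dummy unit s "function" (zero exponent) used to reduce 3c2e/2c2e integrals
# to the 4c2e code path; it carries no normalization
.dummy_cpp <- function() list(l = 0L, cx = 0, cy = 0, cz = 0, pstart = 0L,
                              pnum = 1L, pexp = 0, pcoef = 1)

#' @export
print.f12_basis <- function(x, ...) {
  lc <- table(factor(vapply(x$shells, function(s) s$l, integer(1)),
                     levels = 0:2, labels = c("s", "p", "d")))
  cat("Basis (", x$role, "): ", length(x$shells), " shells, ", x$nao,
      " Cartesian AOs [", paste(lc, names(lc), collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' Read a Gaussian94-style basis set text
#'
#' Accepts the common dialect: blocks per element separated by `****`, each
#' block starting with `<symbol> 0` followed by `<shell-type> <nprim> <scale>`
#' headers and primitive rows `exponent coefficient` (SP shells are split into
#' an S and a P shell).
#'
#' @param text character scalar or vector of lines
#' @param molecule molecule whose atoms the basis is instantiated on
#' @param role basis role
#' @export
read_basis_g94 <- function(text, molecule, role = "orbital") {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1L; next }
    head <- strsplit(lines[i], "\\s+")[[1]]
    sym <- head[1]
    i <- i + 1L
    shl <- list()
    while (i <= length(lines) && lines[i] != "****") {
      h <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(h[1])
      nprim <- as.integer(h[2])
      if (is.na(nprim)) stop("basis format error near: ", lines[i])
      rows <- lines[(i + 1L):(i + nprim)]
      mat <- do.call(rbind, lapply(rows, function(r)
        as.numeric(gsub("[dD]", "e", strsplit(r, "\\s+")[[1]]))))
      if (type == "SP") {
        shl[[length(shl) + 1L]] <- list(l = 0L, exponents = mat[, 1],
                                        coefficients = mat[, 2])
        shl[[length(shl) + 1L]] <- list(l = 1L, exponents = mat[, 1],
                                        coefficients = mat[, 3])
      } else {
        if (!type %in% names(.l_codes))
          stop("unsupported shell type '", type, "' (s, p, d only)")
        shl[[length(shl) + 1L]] <- list(l = .l_codes[[type]],
                                        exponents = mat[, 1],
                                        coefficients = mat[, 2])
      }
      i <- i + nprim + 1L
    }
    blocks[[sym]] <- shl
  }
  shells <- list()
  for (a in seq_along(molecule$symbols)) {
    sym <- molecule$symbols[a]
    if (is.null(blocks[[sym]]))
      stop("basis does not cover element ", sym)
    for (s in blocks[[sym]]) {
      s$center <- a
      shells[[length(shells) + 1L]] <- s
    }
  }
  basis_set(shells, molecule, role = role)
}

# ---------------------------------------------------------------------------
# Embedded fixture basis library: small synthetic even-tempered sets so the
# test suite and examples need no external files.  These are deliberately
# compact stand-ins for production F12 basis families, not published sets.

.et <- function(base, ratio, n) base * ratio^(seq_len(n) - 1)

# one uncontracted shell per exponent
.unc <- function(l, exps) lapply(exps, function(e)
  list(l = as.integer(l), exponents = e, coefficients = 1))

.fixture_shell_table <- list(
  # orbital sets
  `H:fix-obs` = c(
    .unc(0, .et(0.1220, 3.6, 4)),
    .unc(1, 1.10)),
  `H:fix-obs-s` = .unc(0, .et(0.1400, 3.8, 3)),   # s-only variant (chains)
  `He:fix-obs` = c(
    .unc(0, .et(0.2500, 3.6, 5)),
    .unc(1, 1.50)),
  `He:fix-min` = list(                       # minimal: occ spans the basis
    list(l = 0L, exponents = c(12.3100, 2.2430, 0.6070),
         coefficients = c(0.15432897, 0.53532814, 0.44463454))),
  `O:fix-obs` = c(
    .unc(0, .et(0.3000, 4.2, 4)),
    .unc(1, c(0.50, 1.90))),
  `H:fix-obs-h2o` = .unc(0, c(0.17, 0.85)),
  # CABS auxiliary sets (span beyond the orbital sets)
  `H:fix-cabs` = c(
    .unc(0, 0.0550),
    .unc(1, c(0.40, 2.2)),
    .unc(2, 1.00)),
  `He:fix-cabs` = c(
    .unc(0, 0.1100),
    .unc(1, c(0.60, 3.0)),
    .unc(2, 1.40)),
  `O:fix-cabs` = c(
    .unc(0, 0.1200),
    .unc(1, 0.90),
    .unc(2, 1.20)),
  `H:fix-cabs-h2o` = c(
    .unc(0, 0.0700),
    .unc(1, 0.75)),
  # density-fitting auxiliary sets (cover orbital and orbital*CABS products)
  `H:fix-df` = c(
    .unc(0, .et(0.1100, 2.6, 10)),
    .unc(1, .et(0.2200, 2.8, 6)),
    .unc(2, .et(0.4000, 2.8, 4))),
  `He:fix-df` = c(
    .unc(0, .et(0.1800, 2.6, 10)),
    .unc(1, .et(0.3000, 2.8, 6)),
    .unc(2, .et(0.5000, 2.8, 4))),
  `O:fix-df` = c(
    .unc(0, .et(0.2000, 2.8, 10)),
    .unc(1, .et(0.3000, 2.9, 6)),
    .unc(2, .et(0.4500, 2.9, 4))),
  # minimal s/p sets for pseudo-peptide chains (scaling probes)
  `C:fix-min` = list(
    list(l = 0L, exponents = c(71.62, 13.05, 3.53), coefficients = c(0.154, 0.535, 0.445)),
    list(l = 0L, exponents = c(2.94, 0.683, 0.222), coefficients = c(-0.100, 0.399, 0.700)),
    list(l = 1L, exponents = c(2.94, 0.683, 0.222), coefficients = c(0.156, 0.608, 0.392))),
  `N:fix-min` = list(
    list(l = 0L, exponents = c(99.11, 18.05, 4.89), coefficients = c(0.154, 0.535, 0.445)),
    list(l = 0L, exponents = c(3.78, 0.878, 0.286), coefficients = c(-0.100, 0.399, 0.700)),
    list(l = 1L, exponents = c(3.78, 0.878, 0.286), coefficients = c(0.156, 0.608, 0.392))),
  `O:fix-min` = list(
    list(l = 0L, exponents = c(130.7, 23.81, 6.44), coefficients = c(0.154, 0.535, 0.445)),
    list(l = 0L, exponents = c(5.03, 1.17, 0.380), coefficients = c(-0.100, 0.399, 0.700)),
    list(l = 1L, exponents = c(5.03, 1.17, 0.380), coefficients = c(0.156, 0.608, 0.392))),
  `H:fix-min` = list(
    list(l = 0L, exponents = c(3.43, 0.624, 0.169), coefficients = c(0.154, 0.535, 0.445))),
  # chain auxiliaries (s/p only, keeps probes lean)
  `H:fix-cabs-s` = c(
    .unc(0, 0.0600),
    .unc(1, 0.70)),
  `H:fix-df-s` = c(
    .unc(0, .et(0.2500, 3.2, 5)),
    .unc(1, c(0.50, 1.80)))
)

#' Instantiate an embedded fixture basis on a molecule
#'
#' @param molecule the target molecule
#' @param name fixture set name, e.g. "fix-obs", "fix-cabs", "fix-df",
#'   "fix-min"; looked up per element
#' @param role basis role recorded on the result
#' @export
fixture_basis <- function(molecule, name, role = "orbital") {
  shells <- list()
  for (a in seq_along(molecule$symbols)) {
    key <- paste0(molecule$symbols[a], ":", name)
    tmpl <- .fixture_shell_table[[key]]
    if (is.null(tmpl))
      stop("no embedded fixture basis '", name, "' for element ",
           molecule$symbols[a])
    for (s in tmpl) {
      s$center <- a
      shells[[length(shells) + 1L]] <- s
    }
  }
  basis_set(shells, molecule, role = role)
}

# union of two basis sets on the same molecule (orbital + CABS aux)
.basis_union <- function(obs, aux) {
  basis_set(c(obs$shells, aux$shells), obs$molecule, role = "orbital")
}
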