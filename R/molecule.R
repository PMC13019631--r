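# Molecule container and XYZ input.

#' Create a molecule
#'
#' @param symbols character vector of element symbols
#' @param coords_bohr numeric matrix (n x 3) of positions in bohr
#' @param charge total charge
#' @param multiplicity spin multiplicity; only closed-shell singlets are
#'   supported
#' @return an object of class `f12_molecule`
#' @export
molecule <- function(symbols, coords_bohr, charge = 0L, multiplicity = 1L) {
  coords_bohr <- matrix(as.numeric(coords_bohr), ncol = 3)
  if (length(symbols) != nrow(coords_bohr))
    stop("symbols and coordinates disagree in length")
  unknown <- setdiff(symbols, names(.elements))
  if (length(unknown))
    stop("unrecognized element symbol: ", paste(unknown, collapse = ", "))
  if (!all(is.finite(coords_bohr))) stop("non-finite coordinates")
  if (multiplicity != 1L)
    stop("unsupported system: only closed-shell singlets (multiplicity 1) ",
         "are handled")
  z <- unname(.elements[symbols])
  nelec <- sum(z) - charge
  if (nelec %% 2 != 0)
    stop("unsupported system: odd electron count (", nelec, ")")
  structure(list(symbols = symbols, charges = z, coords = coords_bohr,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 nelec = as.integer(nelec)),
            class = "f12_molecule")
}

#' Parse an XYZ document
#'
#' Standard two-header-line XYZ dialect with coordinates in Angstrom;
#' positions are converted to bohr internally.
#'
#' @param xyz_text character scalar (whole document) or character vector of
#'   lines
#' @param charge,multiplicity system charge and multiplicity
#' @return an `f12_molecule`
#' @export
load_molecule <- function(xyz_text, charge = 0L, multiplicity = 1L) {
  lines <- if (length(xyz_text) == 1L) strsplit(xyz_text, "\n")[[1]] else xyz_text
  if (length(lines) < 1L) stop("XYZ format error: empty document")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ format error at line 1: expected an atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("XYZ format error: ", n, " atoms declared but only ",
         length(body), " coordinate lines found")
  sym <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("XYZ format error at line ", i + 2L, ": need symbol + 3 coordinates")
    sym[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      stop("XYZ format error at line ", i + 2L, ": non-numeric coordinate")
    xyz[i, ] <- v
  }
  if (!all(sym %in% names(.elements)))
    stop("XYZ format error: unrecognized element symbol '",
         setdiff(sym, names(.elements))[1], "'")
  molecule(sym, xyz * BOHR_PER_ANGSTROM, charge = charge,
           multiplicity = multiplicity)
}

#' @export
print.f12_molecule <- function(x, ...) {
  cat("Molecule:", length(x$symbols), "atoms,", x$nelec, "electrons, charge",
      x$charge, "\n")
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$symbols[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

nuclear_repulsion <- function(mol) {
  e <- 0
  n <- length(x <- mol$charges)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    e <- e + x[i] * x[j] / sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
  e
}
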