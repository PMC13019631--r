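# Programmatic test fixtures: small closed-shell systems and linear chains
# (the chain series emulates growing peptide-like systems for scaling
# probes).  All geometries are deterministic; bases come from the embedded
# fixture library.

.fixture_basis_map <- function(mol, map, role) {
  shells <- list()
  for (a in seq_along(mol$symbols)) {
    key <- paste0(mol$symbols[a], ":", map[[mol$symbols[a]]])
    tmpl <- .fixture_shell_table[[key]]
    if (is.null(tmpl)) stop("no fixture basis ", key)
    for (s in tmpl) {
      s$center <- a
      shells[[length(shells) + 1L]] <- s
    }
  }
  basis_set(shells, mol, role = role)
}

#' Generate a named fixture system with its basis bundle
#'
#' Available generators:
#' \describe{
#'   \item{he}{helium atom, even-tempered s+p orbital basis}
#'   \item{he_min}{helium in a minimal contracted s basis (occupied spans
#'     the basis; no virtuals)}
#'   \item{h2}{hydrogen dimer; `d_ang` bond length in Angstrom (0.74)}
#'   \item{h2o}{water at the standard experimental geometry, compact bases}
#'   \item{linear_hn_chain}{`n` collinear H atoms at `spacing` bohr;
#'     `n` must be even (closed shell)}
#'   \item{pseudo_glycine_chain}{planar zig-zag peptide-like chain of `n`
#'     CNOH units (4 n + 2 atoms, affine in n)}
#' }
#'
#' @param fixture generator name
#' @param ... generator parameters (see above)
#' @return list with `molecule`, `obs`, `cabs_aux`, `df_aux`
#' @export
generate_fixture <- function(fixture, ...) {
  args <- list(...)
  switch(fixture,
    he = {
      mol <- molecule("He", matrix(0, 1, 3))
      list(molecule = mol,
           obs = fixture_basis(mol, "fix-obs"),
           cabs_aux = fixture_basis(mol, "fix-cabs", "cabs_aux"),
           df_aux = fixture_basis(mol, "fix-df", "df_aux"))
    },
    he_min = {
      mol <- molecule("He", matrix(0, 1, 3))
      list(molecule = mol,
           obs = fixture_basis(mol, "fix-min"),
           cabs_aux = fixture_basis(mol, "fix-cabs", "cabs_aux"),
           df_aux = fixture_basis(mol, "fix-df", "df_aux"))
    },
    h2 = {
      d <- if (is.null(args$d_ang)) 0.74 else args$d_ang
      mol <- molecule(c("H", "H"),
                      rbind(c(0, 0, 0), c(0, 0, d * BOHR_PER_ANGSTROM)))
      list(molecule = mol,
           obs = fixture_basis(mol, "fix-obs"),
           cabs_aux = fixture_basis(mol, "fix-cabs", "cabs_aux"),
           df_aux = fixture_basis(mol, "fix-df", "df_aux"))
    },
    h2o = {
      r <- 0.9572 * BOHR_PER_ANGSTROM
      th <- 104.52 / 2 * pi / 180
      mol <- molecule(c("O", "H", "H"),
                      rbind(c(0, 0, 0),
                            c(0, r * sin(th), r * cos(th)),
                            c(0, -r * sin(th), r * cos(th))))
      map_obs <- c(O = "fix-obs", H = "fix-obs-h2o")
      map_cabs <- c(O = "fix-cabs", H = "fix-cabs-h2o")
      map_df <- c(O = "fix-df", H = "fix-df")
      list(molecule = mol,
           obs = .fixture_basis_map(mol, map_obs, "orbital"),
           cabs_aux = .fixture_basis_map(mol, map_cabs, "cabs_aux"),
           df_aux = .fixture_basis_map(mol, map_df, "df_aux"))
    },
    linear_hn_chain = {
      n <- args$n
      spacing <- if (is.null(args$spacing)) 1.4 else args$spacing
      if (is.null(n) || n < 2 || n %% 2 != 0)
        stop("configuration error: linear_hn_chain needs an even n >= 2")
      mol <- molecule(rep("H", n),
                      cbind(0, 0, spacing * (seq_len(n) - 1)))
      list(molecule = mol,
           obs = fixture_basis(mol, "fix-obs-s"),
           cabs_aux = fixture_basis(mol, "fix-cabs-s", "cabs_aux"),
           df_aux = fixture_basis(mol, "fix-df-s", "df_aux"))
    },
    pseudo_glycine_chain = {
      n <- args$n
      if (is.null(n) || n < 1) stop("configuration error: n must be >= 1")
      sym <- character(0); xyz <- NULL
      for (k in seq_len(n)) {
        x0 <- 5.2 * (k - 1)
        y0 <- 0.8 * (-1)^k
        sym <- c(sym, "C", "N", "O", "H")
        xyz <- rbind(xyz,
                     c(x0, y0, 0),
                     c(x0 + 2.5, -y0, 0),
                     c(x0 + 1.2, y0 + 2.2, 0),
                     c(x0 + 3.9, -y0 + 1.7, 0))
      }
      sym <- c(sym, "H", "H")                     # caps keep the count even
      xyz <- rbind(xyz, c(-1.9, 0, 0), c(5.2 * n - 1.0, 0, 0))
      mol <- molecule(sym, xyz)
      map <- c(C = "fix-min", N = "fix-min", O = "fix-min", H = "fix-min")
      list(molecule = mol,
           obs = .fixture_basis_map(mol, map, "orbital"),
           cabs_aux = NULL, df_aux = NULL)
    },
    stop("configuration error: unknown fixture '", fixture, "'"))
}
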