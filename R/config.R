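# Run configuration for the F12 correction.

#' Create a run configuration
#'
#' @param gamma correlation-factor exponent (bohr^-1)
#' @param grid_level production grid level ("g0".."g4", "g7")
#' @param theta_nq screening threshold for grid 3c1e integrals (0 disables)
#' @param weight_threshold grid point screening threshold
#' @param batch_grid grid batch cap (points)
#' @param batch_aux auxiliary-function batch size for DF contractions
#' @param batch_mo grid sub-batch size of the AO-to-MO transformation
#' @param commutator_level "full" keeps the commutator add-on terms of the
#'   B assembly; "none" omits them
#' @param b_direct_fix TRUE reads the first B coefficient of the energy
#'   formula as the direct pattern (see the methods vignette); FALSE keeps
#'   the literal printed exchange-exchange reading
#' @param frozen_core number of frozen core orbitals
#' @param gbc_ebc apply the generalized/extended Brillouin conditions
#' @param mode "nq" (production hybrid NQ/DF), "df_only" (density-fitting
#'   comparator) or "dense" (brute-force oracle)
#' @param n_stg Gaussians in the Slater-geminal expansion
#' @param oracle_level grid level of the dense reference protocol
#' @param occ_products "occupied" sums the k,l product indices over all
#'   occupied orbitals (default), "active" restricts them under frozen core
#' @export
run_config <- function(gamma = 1.3, grid_level = "g2", theta_nq = 1e-10,
                       weight_threshold = 1e-5, batch_grid = 64L,
                       batch_aux = 16L, batch_mo = 16L,
                       commutator_level = c("full", "none"),
                       b_direct_fix = TRUE, frozen_core = 0L, gbc_ebc = TRUE,
                       mode = c("nq", "df_only", "dense"), n_stg = 6L,
                       oracle_level = "g7", occ_products = "occupied") {
  commutator_level <- match.arg(commutator_level)
  mode <- match.arg(mode)
  stopifnot(gamma > 0, theta_nq >= 0, weight_threshold >= 0,
            batch_grid >= 1, batch_aux >= 1, batch_mo >= 1, frozen_core >= 0)
  structure(list(gamma = gamma, grid_level = grid_level, theta_nq = theta_nq,
                 weight_threshold = weight_threshold,
                 batch_grid = as.integer(batch_grid),
                 batch_aux = as.integer(batch_aux),
                 batch_mo = as.integer(batch_mo),
                 commutator_level = commutator_level,
                 b_direct_fix = b_direct_fix,
                 frozen_core = as.integer(frozen_core), gbc_ebc = gbc_ebc,
                 mode = mode, n_stg = as.integer(n_stg),
                 oracle_level = oracle_level, occ_products = occ_products,
                 seedless = TRUE),
            class = "f12_config")
}
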