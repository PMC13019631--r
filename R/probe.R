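# Scaling probes: formal operation-count growth of the hybrid fourth-order
# path versus the purely density-fitted fifth-order comparator on linear
# chain fixtures.  Counts are exact formulas of the executed contraction
# dimensions, not wall time.

#' Operation-count scaling probe
#'
#' Runs the hybrid NQ/DF B-intermediate pass and the DF-only comparator on a
#' series of linear H-chain fixtures and reports the dominant counters and
#' the pairwise growth exponents `log(c2/c1) / log(n2/n1)`.
#'
#' @param chain_sizes even chain lengths (atom counts), increasing
#' @param level grid level used for the hybrid path (default "g0")
#' @param spacing chain spacing in bohr
#' @return list with per-size counters and pairwise exponents
#' @export
flop_probe <- function(chain_sizes, level = "g0", spacing = 1.4) {
  chain_sizes <- sort(unique(as.integer(chain_sizes)))
  res <- data.frame(n = chain_sizes, nao = NA_real_, hybrid = NA_real_,
                    df_only = NA_real_)
  cfg <- run_config(grid_level = level, weight_threshold = 0,
                    theta_nq = 1e-10)
  for (i in seq_along(chain_sizes)) {
    fx <- generate_fixture("linear_hn_chain", n = chain_sizes[i],
                           spacing = spacing)
    ref <- compute_reference(fx$molecule, fx$obs)
    cab <- build_cabs(fx$obs, fx$cabs_aux, ref)
    sp <- assemble_spaces(ref, cab)
    ctx <- .f12_ctx(sp, fx$df_aux, cfg)
    grid <- build_grid(fx$molecule, level, 0)
    bat <- make_batches(grid, fx$obs, cfg$batch_grid)
    counters_reset()
    alg2 <- algorithm2_f2(sp, bat, cfg$theta_nq, cfg, ctx)
    invisible(build_b(sp, bat, ctx, cfg$theta_nq, cfg, alg2 = alg2))
    c1 <- counters_get()
    counters_reset()
    invisible(.df_only_parts(sp, ctx, cfg))
    c2 <- counters_get()
    res$nao[i] <- fx$obs$nao
    res$hybrid[i] <- c1[["u_pprime_contraction"]]
    res$df_only[i] <- c2[["df_only_dominant"]]
  }
  expo <- function(v) {
    if (length(chain_sizes) < 2) return(numeric(0))
    diff(log(v)) / diff(log(chain_sizes))
  }
  list(table = res, hybrid_exponents = expo(res$hybrid),
       df_only_exponents = expo(res$df_only))
}
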