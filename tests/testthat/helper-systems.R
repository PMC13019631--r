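# Shared fixtures, cached across test files (built once per run).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fix_sys <- function(name) memo(paste0("sys_", name), generate_fixture(name))

fix_ref <- function(name) memo(paste0("ref_", name), {
  s <- fix_sys(name)
  compute_reference(s$molecule, s$obs)
})

fix_spaces <- function(name, frozen_core = 0L, gbc_ebc = TRUE) {
  memo(paste0("sp_", name, "_", frozen_core, "_", gbc_ebc), {
    s <- fix_sys(name)
    cab <- build_cabs(s$obs, s$cabs_aux, fix_ref(name))
    assemble_spaces(fix_ref(name), cab, frozen_core, gbc_ebc)
  })
}

# dense reference at a given oracle level, cached
fix_dense <- function(name, level = "g3", ...) {
  memo(paste0("dense_", name, "_", level), {
    s <- fix_sys(name)
    dense_reference(s$molecule, s, run_config(oracle_level = level, ...),
                    reference = fix_ref(name))
  })
}

# production report, cached
fix_nq <- function(name, level = "g2", ...) {
  memo(paste0("nq_", name, "_", level), {
    s <- fix_sys(name)
    f12_energy(s$molecule, s, run_config(grid_level = level, ...),
               reference = fix_ref(name))
  })
}
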