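# Energy assembly, dense oracle protocol, reporting, and the CLI driver.

test_that("dense oracle: pair symmetry, size guard, projector toggle", {
  dn <- fix_dense("h2", "g3")
  expect_lt(max(abs(dn$X_x - t(dn$X_x))), 1e-11)
  expect_lt(max(abs(dn$V_x - t(dn$V_x))), 1e-11)
  # oracle self-convergence of the V 6c3e ingredient between grid levels
  dn2 <- fix_dense("h2", "g2")
  expect_lt(max(abs(dn$pair6$V6 - dn2$pair6$V6)), 5e-7)

  big <- generate_fixture("linear_hn_chain", n = 16)
  expect_error(dense_reference(big$molecule, big, run_config()),
               "oracle unavailable")

  sys <- fix_sys("he")
  dap <- dense_reference(sys$molecule, sys, run_config(oracle_level = "g2"),
                         approx_projector = TRUE,
                         reference = fix_ref("he"))
  # the approximate projector differs from the exact one by a finite
  # RI-dependent amount (magnitude not asserted)
  expect_gt(abs(sum(dap$approx$V_x) - sum(dap$V_x)), 1e-9)
})

test_that("the report is self-consistent and deterministic", {
  rp <- fix_nq("he", "g1")
  # total equals the coefficient-weighted recombination of its own parts
  co <- rp$coefficients
  B1 <- if (rp$config$b_direct_fix) rp$parts[["B_d"]] else rp$parts[["B_x"]]
  X1 <- if (rp$config$b_direct_fix) rp$parts[["X_eps_d"]] else
    rp$parts[["X_eps_x"]]
  tot <- co[["V_d"]] * rp$parts[["V_d"]] + co[["V_x"]] * rp$parts[["V_x"]] +
    co[["B_first"]] * B1 + co[["B_x"]] * rp$parts[["B_x"]] +
    co[["X_first"]] * X1 + co[["X_x"]] * rp$parts[["X_eps_x"]]
  expect_equal(rp$total, tot, tolerance = 1e-12)

  sys <- fix_sys("he")
  r1 <- f12_energy(sys$molecule, sys, run_config(grid_level = "g0"))
  r2 <- f12_energy(sys$molecule, sys, run_config(grid_level = "g0"))
  expect_identical(r1$total, r2$total)
  expect_identical(r1$parts, r2$parts)

  expect_output(print(rp), "E_F12")
  expect_output(summary(rp), "Term breakdown")
})

test_that("single-pair He collapses to the closed coefficient combination", {
  rp <- fix_nq("he", "g1")
  p <- rp$parts
  expect_lt(abs(p[["V_d"]] - p[["V_x"]]), 1e-12)
  expect_lt(abs(p[["B_d"]] - p[["B_x"]]), 1e-10)
  expect_lt(abs(p[["X_d"]] - p[["X_x"]]), 1e-12)
  eps1 <- fix_ref("he")$eps[1]
  pred <- -p[["V_x"]] + (7 / 32 + 1 / 32) * p[["B_x"]] -
    2 * eps1 * (7 / 32 + 1 / 32) * p[["X_x"]]
  expect_equal(rp$total, pred, tolerance = 1e-10)
})

test_that("the B-pattern flag switches the printed reading", {
  sys <- fix_sys("h2o")
  ref <- fix_ref("h2o")
  cfg1 <- run_config(grid_level = "g0", b_direct_fix = TRUE)
  cfg2 <- run_config(grid_level = "g0", b_direct_fix = FALSE)
  r1 <- f12_energy(sys$molecule, sys, cfg1, reference = ref)
  r2 <- f12_energy(sys$molecule, sys, cfg2, reference = ref)
  expect_identical(r1$parts, r2$parts)
  d_expect <- 7 / 32 * (r1$parts[["B_d"]] - r1$parts[["B_x"]]) -
    7 / 32 * (r1$parts[["X_eps_d"]] - r1$parts[["X_eps_x"]])
  expect_equal(r1$total - r2$total, d_expect, tolerance = 1e-12)
})

test_that("the correction responds smoothly to the geminal exponent", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  e13 <- f12_energy(sys$molecule, sys,
                    run_config(grid_level = "g1", gamma = 1.3),
                    reference = ref)
  e065 <- f12_energy(sys$molecule, sys,
                     run_config(grid_level = "g1", gamma = 0.65),
                     reference = ref)
  expect_true(e13$parts[["V_x"]] > 0 && e065$parts[["V_x"]] > 0)
  expect_true(e13$total < 0 && e065$total < 0)
  expect_lt(abs(e13$total - e065$total), 0.1)
})

test_that("frozen core and product-space flags are honored", {
  sys <- fix_sys("h2o")
  ref <- fix_ref("h2o")
  cfg <- run_config(grid_level = "g0", frozen_core = 1L)
  r <- f12_energy(sys$molecule, sys, cfg, reference = ref)
  expect_true(is.finite(r$total))
  expect_equal(unname(r$dims["n_act"]), 4)
  cfga <- run_config(grid_level = "g0", frozen_core = 1L,
                     occ_products = "active")
  ra <- f12_energy(sys$molecule, sys, cfga, reference = ref)
  expect_false(isTRUE(all.equal(r$parts[["V_x"]], ra$parts[["V_x"]])))
})

test_that("DF-only comparator agrees with the hybrid evaluation", {
  for (nm in c("he", "h2")) {
    sys <- fix_sys(nm)
    ref <- fix_ref(nm)
    rq <- fix_nq(nm, "g2")
    rd <- f12_energy(sys$molecule, sys, run_config(mode = "df_only"),
                     reference = ref)
    expect_lt(abs(rq$total - rd$total), 5e-5)
  }
})

test_that("the command-line driver runs its sub-commands", {
  tmp <- tempfile()
  st <- cli_main(c("compute", "--fixture", "he", "--grid", "g0",
                   "--report", tmp))
  expect_identical(st, 0L)
  lines <- readLines(tmp)
  expect_true(any(grepl("^E_F12_total_hartree", lines)))
  expect_true(any(grepl("config_seedless TRUE", lines)))

  expect_identical(suppressMessages(cli_main(c("compute", "--bogus"))), 1L)
  expect_identical(suppressMessages(cli_main("unknown-cmd")), 1L)
  expect_output(st2 <- cli_main(c("fixtures", "--fixture", "h2")), "H")
  expect_identical(st2, 0L)
  # the oracle guard propagates as a non-zero status
  expect_identical(suppressMessages(
    cli_main(c("oracle", "--fixture", "linear_hn_chain"))), 1L)
})

test_that("XYZ + Gaussian94 files drive the CLI end to end", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines("2\n\nH 0 0 0\nH 0 0 0.74", xyz)
  gbs <- tempfile(fileext = ".gbs")
  writeLines(c("H 0", "S 1 1.00", " 1.20 1.0", "S 1 1.00", " 0.30 1.0",
               "****"), gbs)
  aux <- tempfile(fileext = ".gbs")
  writeLines(c("H 0", "S 1 1.00", " 0.08 1.0", "P 1 1.00", " 0.60 1.0",
               "****"), aux)
  dfb <- tempfile(fileext = ".gbs")
  writeLines(c("H 0", "S 1 1.00", " 2.40 1.0", "S 1 1.00", " 0.90 1.0",
               "S 1 1.00", " 0.35 1.0", "P 1 1.00", " 0.70 1.0", "****"),
             dfb)
  out <- tempfile()
  st <- cli_main(c("compute", "--xyz", xyz, "--obs", gbs, "--cabs", aux,
                   "--df", dfb, "--grid", "g0", "--report", out))
  expect_identical(st, 0L)
  expect_true(file.exists(out))
})
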