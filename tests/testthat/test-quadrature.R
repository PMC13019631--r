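# Molecular grids, pruning, Becke partitioning, batching and AO evaluation.

test_that("grid layout follows the level table and screening semantics", {
  c1 <- molecule("C", matrix(0, 1, 3))
  g <- build_grid(c1, "g0", 0)
  expect_equal(g$nrad, 15L)
  expect_equal(g$ang_orders, c(14L, 38L, 74L))
  expect_equal(g$n_dropped, 0L)              # threshold 0 removes nothing
  expect_equal(g$n_kept, g$n_total)
  expect_true(all(g$w > 0))
  expect_error(build_grid(c1, "g9"), "unknown grid level")

  # two identical far-separated atoms keep equal per-atom counts
  h2far <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 30)))
  gf <- build_grid(h2far, "g1", 1e-5)
  expect_equal(sum(gf$parent == 1), sum(gf$parent == 2))
})

test_that("quadrature integrates fixture densities to the electron count", {
  for (nm in c("h2", "h2o")) {
    sys <- fix_sys(nm)
    ref <- fix_ref(nm)
    g <- build_grid(sys$molecule, "g2", 1e-5, sys$obs)
    amps <- eval_aos(list(points = g$points), sys$obs)
    dens <- 2 * rowSums((amps %*% ref$C[, seq_len(ref$nocc),
                                        drop = FALSE])^2)
    expect_equal(sum(g$w * dens), sys$molecule$nelec, tolerance = 1e-3)
  }
})

test_that("batches respect caps and AO significance", {
  sys <- fix_sys("h2")
  g <- build_grid(sys$molecule, "g0", 1e-5, sys$obs)
  b64 <- make_batches(g, sys$obs, 64L)
  expect_true(all(vapply(b64, function(b) nrow(b$points), numeric(1)) <= 64))
  expect_equal(sum(vapply(b64, function(b) length(b$w), numeric(1))),
               g$n_kept)
  ball <- make_batches(g, sys$obs, g$n_kept)
  expect_equal(length(ball), 1L)
  b0 <- make_batches(g, sys$obs, 64L, ao_threshold = 0)
  expect_true(all(vapply(b0, function(b) length(b$ao_idx) == sys$obs$nao,
                         logical(1))))
  expect_error(make_batches(g, sys$obs, 0L), "batch_cap")

  # far-separated atoms: batches near atom A exclude atom-B AOs
  h2far <- generate_fixture("h2", d_ang = 30 * 0.52917721092)
  gf <- build_grid(h2far$molecule, "g0", 1e-5, h2far$obs)
  bf <- make_batches(gf, h2far$obs, 64L, ao_threshold = 1e-10)
  shell_atom <- vapply(h2far$obs$shells, function(s) s$center, numeric(1))
  ao_atom <- shell_atom[h2far$obs$ao_shell]
  near_a <- bf[[which.min(vapply(bf, function(b)
    min(b$points[, 3]), numeric(1)))]]
  expect_true(all(ao_atom[near_a$ao_idx] == 1))
  # amplitude-bound audit: excluded AOs really are below the threshold
  full <- eval_aos(list(points = near_a$points), h2far$obs)
  excl <- setdiff(seq_len(h2far$obs$nao), near_a$ao_idx)
  expect_lt(max(abs(full[, excl])), 1e-10)
})

test_that("AO amplitudes have the right closed forms", {
  he <- molecule("He", matrix(0, 1, 3))
  a <- 1.7
  bs <- basis_set(list(list(l = 0L, center = 1L, exponents = a,
                            coefficients = 1),
                       list(l = 1L, center = 1L, exponents = 0.9,
                            coefficients = 1)), he)
  amp <- eval_aos(list(points = matrix(0, 1, 3)), bs)
  expect_equal(amp[1, 1], (2 * a / pi)^0.75, tolerance = 1e-12)
  expect_equal(amp[1, 2:4], c(0, 0, 0))     # p functions vanish at center
  ampf <- eval_aos(list(points = matrix(c(0, 0, 50), 1, 3)), bs)
  expect_lt(max(abs(ampf)), 1e-14)
})

test_that("energies are invariant under the batch partition", {
  sys <- fix_sys("he")
  ref <- fix_ref("he")
  es <- vapply(c(16L, 64L, 128L, 100000L), function(cap) {
    cfg <- run_config(grid_level = "g0", batch_grid = cap)
    f12_energy(sys$molecule, sys, cfg, reference = ref)$total
  }, numeric(1))
  expect_lt(diff(range(es)), 1e-11)
})

test_that("rigid rotation leaves the correction invariant", {
  sys <- fix_sys("h2")
  cfg <- run_config(grid_level = "g0")
  e1 <- f12_energy(sys$molecule, sys, cfg)$total
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)), 3,
           byrow = TRUE)
  mrot <- molecule(sys$molecule$symbols, sys$molecule$coords %*% t(R))
  sysr <- list(molecule = mrot,
               obs = fixture_basis(mrot, "fix-obs"),
               cabs_aux = fixture_basis(mrot, "fix-cabs", "cabs_aux"),
               df_aux = fixture_basis(mrot, "fix-df", "df_aux"))
  e2 <- f12_energy(mrot, sysr, cfg)$total
  expect_lt(abs(e2 - e1), 1e-8)
})
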