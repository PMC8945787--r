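env_nosalt <- dielectric_env(eps_protein = 4, eps_water = 80,
                             ionic_strength = 0)
born <- function(q, eps_in, eps_out, R) {
  -332.0636 / 2 * q^2 * (1 / eps_in - 1 / eps_out) / R
}

test_that("zero charges give an identically zero potential", {
  f <- solve_pb(data.frame(x = 0, y = 0, z = 0, q = 0),
                data.frame(x = 0, y = 0, z = 0, radius = 2),
                env_nosalt, grid_spec(0.8, 5))
  expect_equal(max(abs(f$phi)), 0)
})

test_that("uniform-dielectric potential matches Coulomb off-axis", {
  f <- solve_pb(data.frame(x = 0, y = 0, z = 0, q = 1), NULL,
                dielectric_env(4, 4, 0), grid_spec(0.25, 6),
                uniform_eps = 4)
  pts <- matrix(c(1.3, 2.1, 0.7, -2.2, 1.1, 1.9, 0.9, -1.7, 2.3),
                ncol = 3, byrow = TRUE)
  want <- 332.0636 / (4 * sqrt(rowSums(pts^2)))
  expect_lt(max(abs(pb_potential(f, pts) - want) / want), 0.02)
})

test_that("Born-sphere reaction field converges monotonically to the analytic value", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  at <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  env1 <- dielectric_env(eps_protein = 1, eps_water = 80, ionic_strength = 0)
  analytic <- born(1, 1, 80, 2)
  errs <- vapply(c(0.8, 0.4, 0.2), function(h) {
    e <- redoxmc:::rf_energy(redoxmc:::pb_reaction_pair(ch, at, env1,
                                                        grid_spec(h, 5)))
    abs(e - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / abs(analytic), 0.02)
})

test_that("charges outside a fixed grid extent are an error", {
  box <- rbind(c(-6, -6, -6), c(6, 6, 6))
  expect_error(solve_pb(data.frame(x = 9, y = 0, z = 0, q = 1),
                        data.frame(x = 0, y = 0, z = 0, radius = 2),
                        env_nosalt, grid_spec(0.8, 5, extent = box)),
               "outside")
  # the same charge inside the box solves fine
  f <- solve_pb(data.frame(x = 0, y = 0, z = 0, q = 1),
                data.frame(x = 0, y = 0, z = 0, radius = 2),
                env_nosalt, grid_spec(0.8, 5, extent = box))
  expect_s3_class(f, "pb_field")
})

test_that("two-level focusing agrees with the unfocused fine solution", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  at <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  e1 <- redoxmc:::rf_energy(redoxmc:::pb_reaction_pair(
    ch, at, env_nosalt, grid_spec(0.3, 5, focusing_levels = 1)))
  e2 <- redoxmc:::rf_energy(redoxmc:::pb_reaction_pair(
    ch, at, env_nosalt, grid_spec(0.3, 5, focusing_levels = 2)))
  expect_lt(abs(e1 - e2) / abs(e1), 0.01)
})

test_that("desolvation energy matches the two-Born-media difference", {
  # +1 sphere (R = 2) moved from water into an eps = 4 cavity of outer
  # radius 14: ddG = 166.03 * (1/4 - 1/80) * (1/2 - 1/14)
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  rf_aq <- redoxmc:::rf_energy(redoxmc:::pb_reaction_pair(
    ch, data.frame(x = 0, y = 0, z = 0, radius = 2), env_nosalt,
    grid_spec(0.25, 5)))
  rf_prot <- redoxmc:::rf_energy(redoxmc:::pb_reaction_pair(
    ch, data.frame(x = 0, y = 0, z = 0, radius = 14), env_nosalt,
    grid_spec(0.6, 5)))
  want <- 166.0318 * (1 / 4 - 1 / 80) * (1 / 2 - 1 / 14)
  expect_lt(abs((rf_prot - rf_aq) - want) / want, 0.05)
})

test_that("zero-charge conformers desolvate for free; buried ions pay", {
  m <- make_toy_cluster(toy_system_spec(
    n_fe = 1, shell_charges = list(list(charge = 1, distance = 5, count = 1)),
    backbone_dipoles = list(count = 0, distance = 5), seed = 2))
  env <- dielectric_env()
  neutral <- m$conformers[[which(vapply(m$conformers, function(cf)
    cf$charge_state == 0, logical(1)))[1]]]
  expect_equal(reaction_field_energy(neutral, m, env, grid_spec(0.6, 5)), 0)
  fe_red <- m$conformers[[1]]
  expect_gt(reaction_field_energy(fe_red, m, env, grid_spec(0.6, 5)), 0)
})

test_that("backbone energy reduces to the Coulomb sum in a uniform dielectric", {
  m <- make_toy_cluster(toy_system_spec(
    n_fe = 1, shell_charges = list(),
    backbone_dipoles = list(count = 1, distance = 5), seed = 6))
  envu <- dielectric_env(eps_protein = 4, eps_water = 4, ionic_strength = 0)
  fe_ox <- m$conformers[[2]]
  got <- backbone_energy(fe_ox, m, envu, grid_spec(0.4, 5))
  bb <- m$backbone
  r <- sqrt((bb$x - fe_ox$atoms$x)^2 + (bb$y - fe_ox$atoms$y)^2 +
            (bb$z - fe_ox$atoms$z)^2)
  want <- sum(332.0636 * 3 * bb$charge / (4 * r))
  expect_lt(abs(got - want) / abs(want), 0.02)

  # antisymmetry: flipping all backbone charges negates the energy exactly
  m2 <- m
  m2$backbone$charge <- -m2$backbone$charge
  got2 <- backbone_energy(fe_ox, m2, envu, grid_spec(0.4, 5))
  expect_equal(got2, -got)

  # neutral conformer: exactly zero without a solve
  fe_neutral <- fe_ox
  fe_neutral$atoms$charge <- 0
  expect_identical(backbone_energy(fe_neutral, m, envu), 0)
})

test_that("pairwise energies match Coulomb, are symmetric, and respect the sentinel", {
  atoms <- data.frame(
    serial = 1:2, name = "NZ", resname = "LYS", chain = "X",
    resno = c(201, 202), x = c(0, 5), y = 0, z = 0, stringsAsFactors = FALSE)
  m <- redoxmc:::build_structure_model(atoms, default_charge_config())
  # make the second site's charged conformer -1 by flipping its charge
  m$conformers[[3]]$atoms$charge <- -1
  envu <- dielectric_env(eps_protein = 4, eps_water = 4, ionic_strength = 0)
  g <- grid_spec(0.4, 5)
  e12 <- pairwise_energy(m$conformers[[1]], m$conformers[[3]], m, envu, g,
                         include_lj = FALSE)
  expect_lt(abs(e12 - (-332.0636 / 20)) / (332.0636 / 20), 0.02)
  e21 <- pairwise_energy(m$conformers[[3]], m$conformers[[1]], m, envu, g,
                         include_lj = FALSE)
  expect_identical(e12, e21)
  expect_true(is.na(pairwise_energy(m$conformers[[1]], m$conformers[[2]],
                                    m, envu, g)))
  # two neutral conformers: ~0 (Lennard-Jones negligible at 5 A)
  e00 <- pairwise_energy(m$conformers[[2]], m$conformers[[4]], m, envu, g)
  expect_lt(abs(e00), 0.05)
})

test_that("pairwise screening strengthens monotonically with ionic strength", {
  m <- make_toy_cluster(toy_system_spec(
    n_fe = 1, shell_charges = list(list(charge = 1, distance = 5, count = 1)),
    backbone_dipoles = list(count = 0, distance = 5), seed = 2))
  prev <- Inf
  for (I in c(0, 0.05, 0.15, 0.5)) {
    e <- pairwise_energy(m$conformers[[1]], m$conformers[[3]], m,
                         dielectric_env(ionic_strength = I),
                         grid_spec(0.6, 6), include_lj = FALSE)
    expect_lte(abs(e), abs(prev) + 1e-9)
    prev <- e
  }
})

test_that("energy tables match the per-conformer operations element-wise", {
  m <- make_toy_cluster(toy_system_spec(
    n_fe = 1, shell_charges = list(list(charge = 1, distance = 5, count = 2)),
    backbone_dipoles = list(count = 2, distance = 4.5), seed = 5))
  env <- dielectric_env()
  g <- grid_spec(0.6, 6)
  tb <- build_energy_tables(m, env, g)
  ci <- tb$conformers

  expect_true(isSymmetric(unname(dG_pair(tb))))
  expect_equal(unname(diag(dG_pair(tb))), rep(0, nrow(ci)))
  same <- outer(ci$fragment, ci$fragment, "==")
  diag(same) <- FALSE
  expect_true(all(is.na(dG_pair(tb)[same])))
  expect_false(anyNA(dG_pair(tb)[!same]))

  expect_equal(tb$dG_rxn[["FE_X900.2"]],
               reaction_field_energy(m$conformers[[2]], m, env, g),
               tolerance = 1e-8)
  expect_equal(tb$dG_pol[["FE_X900.2"]],
               backbone_energy(m$conformers[[2]], m, env, g),
               tolerance = 1e-8)
  expect_equal(dG_pair(tb)["FE_X900.2", "LYS_X201.1"],
               pairwise_energy(m$conformers[[2]], m$conformers[[3]], m,
                               env, g),
               tolerance = 1e-8)
})

test_that("a zero-charge system yields all-zero electrostatic tables", {
  atoms <- data.frame(
    serial = 1:2, name = "CB", resname = "ALA", chain = c("A", "A"),
    resno = c(1, 2), x = c(0, 6), y = 0, z = 0, stringsAsFactors = FALSE)
  m <- redoxmc:::build_structure_model(atoms, default_charge_config())
  tb <- build_energy_tables(m, dielectric_env(), grid_spec(0.8, 5))
  expect_equal(max(abs(tb$dG_rxn)), 0)
  expect_equal(max(abs(tb$dG_pol)), 0)
  expect_equal(max(abs(tb$pair_elec), na.rm = TRUE), 0)
})

test_that("energy tables survive a TSV round-trip", {
  tb <- random_titration_system(3, 3, seed = 5)
  pre <- file.path(tempdir(), "tbl")
  write_energy_tables(tb, pre)
  tb2 <- read_energy_tables(pre)
  expect_equal(tb2$dG_rxn, tb$dG_rxn)
  expect_equal(tb2$pair_elec, tb$pair_elec)
  expect_equal(tb2$conformers$Em_sol, tb$conformers$Em_sol)
})
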