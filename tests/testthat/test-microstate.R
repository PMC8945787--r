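test_that("microstate energy reproduces hand-evaluated sums", {
  tb <- hand_tables()
  cond <- titration_condition(pH = 7, Eh = -100)
  # redox conformer A.1 (n = 1, Em_sol = -170) + B.1, pair -1.1
  want1 <- 1 * FKCAL * (-100 - (-170)) / 1000 + 1.2 + 0.3 + 0.5 + 0.1 - 1.1
  expect_equal(microstate_energy(c(1, 3), tb, cond), want1)
  # base conformer A.2 (m = +1, pK 9) + B.1, pair +0.7
  want2 <- 2.3 * KT298 * (7 - 9) + 2.0 - 0.5 + 0.5 + 0.1 + 0.7
  expect_equal(microstate_energy(c(2, 3), tb, cond), want2)
  expect_error(microstate_energy(c(1, 2), tb, cond), "one conformer per")
})

test_that("trivial microstates have zero energy", {
  tb0 <- make_titration_system(-170)
  tb0$dG_rxn[] <- 0
  # single redox conformer at Eh = Em_sol
  expect_equal(microstate_energy(1, tb0, titration_condition(Eh = -170)), 0)
  # neutral conformer (m = 0, n = 0), zero tables
  expect_equal(microstate_energy(2, tb0, titration_condition(Eh = 0)), 0)
})

test_that("enumeration reproduces Boltzmann statistics exactly", {
  tb <- make_titration_system(c(-170, -170))
  cond <- titration_condition(Eh = -170)
  occ <- enumerate_occupancies(tb, cond)
  expect_equal(unname(occ), rep(0.5, 4))  # iso-energetic pairs

  # 1.364 kcal/mol split -> 10:1 ratio at 298 K
  tb2 <- make_titration_system(-170, ox_shift = 1.364)
  occ2 <- enumerate_occupancies(tb2, titration_condition(Eh = -170))
  expect_equal(unname(occ2[1] / occ2[2]), 10^(1.364 / (2.3025851 * KT298)),
               tolerance = 1e-6)

  # per-fragment occupancies always sum to 1
  tbr <- random_titration_system(4, 3, seed = 11)
  occ3 <- enumerate_occupancies(tbr, titration_condition(Eh = -100))
  sums <- tapply(occ3, tbr$conformers$fragment, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)))
})

test_that("enumeration matches an independent brute-force oracle", {
  for (seed in c(2, 13, 40)) {
    tb <- random_titration_system(4, 3, seed = seed)
    cond <- titration_condition(pH = 6.3, Eh = -140)
    expect_equal(unname(enumerate_occupancies(tb, cond)),
                 oracle_occupancies(tb, cond), tolerance = 1e-10)
  }
})

test_that("state-space overflow points the user to Monte Carlo", {
  tb <- make_titration_system(rep(-170, 21))
  expect_error(enumerate_occupancies(tb, titration_condition()),
               "mc_sample")
})

test_that("Monte Carlo sampling is reproducible and tracks enumeration", {
  tb <- make_titration_system(c(-200, -150), W = 1)
  cond <- titration_condition(Eh = -175)
  a <- mc_sample(tb, cond, seed = 99)
  b <- mc_sample(tb, cond, seed = 99)
  expect_identical(a$occupancy, b$occupancy)

  ex <- enumerate_occupancies(tb, cond)
  expect_lt(max(abs(a$occupancy - ex)), max(3 * a$mc_error, 0.01))

  # iso-energetic pair
  tbi <- make_titration_system(-170)
  r <- mc_sample(tbi, titration_condition(Eh = -170), seed = 5)
  expect_lt(abs(r$occupancy[[1]] - 0.5), 3 * r$mc_error[[1]] + 0.003)
})

test_that("an isolated site titrates at its solution midpoint with Nernst slope", {
  tb <- make_titration_system(-170)
  tr <- titrate(tb, eh_grid = seq(-400, 100, by = 2))
  expect_lt(abs(tr$midpoints[["FE1"]] - (-170)), 1)
  ox <- tr$ox_frac[1, ]
  expect_true(all(diff(ox) >= 0))  # non-decreasing in Eh
  eh <- tr$conditions$Eh_mV
  hi <- redoxmc:::crossing_eh(ox, eh, 10 / 11)
  lo <- redoxmc:::crossing_eh(ox, eh, 1 / 11)
  expect_equal((hi - lo) / 2, 59.16, tolerance = 0.005)
})

test_that("injected protein shifts are recovered in the extracted midpoint", {
  for (shift in c(-2, 1, 3)) {
    tb <- make_titration_system(-170, ox_shift = shift)
    tr <- titrate(tb, eh_grid = seq(-600, 400, by = 2))
    expect_lt(abs(tr$midpoints[["FE1"]] - (-170 + 1000 * shift / FKCAL)), 5)
  }
})

test_that("cluster Em follows the second-oxidation convention", {
  # independent sites at -400 / -200: second oxidation at -200
  tr <- titrate(make_titration_system(c(-400, -200)),
                eh_grid = seq(-600, 0, by = 2))
  expect_lt(abs(extract_cluster_em(tr, c("FE1", "FE2")) - (-200)), 1)

  # split sites + ferric-ferric repulsion W: shift = 1000 W / F exactly
  W <- 2.3061
  tr2 <- titrate(make_titration_system(c(-500, -300), W = W),
                 eh_grid = seq(-700, 100, by = 2))
  expect_lt(abs(extract_cluster_em(tr2, c("FE1", "FE2")) -
                (-300 + 1000 * W / FKCAL)), 5)

  # degenerate sites: the exact 2-site partition function adds a
  # configurational-entropy term; crossing at Em + kT ln(t*) / F with
  # t* = w + sqrt(w^2 + 3 w), w = exp(W/kT)
  tr3 <- titrate(make_titration_system(c(-300, -300), W = W),
                 eh_grid = seq(-500, 100, by = 1))
  w <- exp(W / KT298)
  tstar <- w + sqrt(w^2 + 3 * w)
  expect_lt(abs(extract_cluster_em(tr3, c("FE1", "FE2")) -
                (-300 + 1000 * KT298 * log(tstar) / FKCAL)), 1)

  # relabelling the sites changes nothing
  expect_equal(extract_cluster_em(tr3, c("FE2", "FE1")),
               extract_cluster_em(tr3, c("FE1", "FE2")))
})

test_that("stronger ferric-ferric repulsion never lowers the second-oxidation Em", {
  ems <- vapply(c(0, 0.5, 1, 2, 4), function(W) {
    tr <- titrate(make_titration_system(c(-350, -300), W = W),
                  eh_grid = seq(-600, 200, by = 2))
    extract_cluster_em(tr, c("FE1", "FE2"))
  }, numeric(1))
  expect_true(all(diff(ems) > 0))
})

test_that("a crossing outside the Eh grid is a reported error", {
  tr <- titrate(make_titration_system(c(-400, -200)),
                eh_grid = seq(-800, -500, by = 5))
  expect_error(extract_cluster_em(tr, c("FE1", "FE2")), "does not cross")
})

test_that("titration output writes occupancy and midpoint TSVs", {
  tr <- titrate(make_titration_system(-170), eh_grid = seq(-250, -100, 10))
  pre <- file.path(tempdir(), "titr")
  write_titration(tr, pre)
  occ <- read.delim(paste0(pre, "_occupancy.tsv"))
  expect_true(all(c("Eh_mV", "conformer", "occupancy", "mc_error") %in%
                  names(occ)))
  mid <- read.delim(paste0(pre, "_midpoints.tsv"))
  expect_equal(mid$Em_mV, unname(tr$midpoints), tolerance = 1e-8)
})
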