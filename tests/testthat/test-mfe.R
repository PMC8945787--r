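test_that("an isolated site decomposes to its solution reference", {
  tb <- make_titration_system(-170)
  tr <- titrate(tb, eh_grid = seq(-300, 0, by = 2))
  d <- mfe_decompose("FE1", tr, tb)
  expect_equal(d$Em_mfe, -170, tolerance = 1e-6)
  expect_equal(d$dG_bkbn, 0)
  expect_equal(d$dG_rxn, 0)
  expect_equal(d$dG_res_mfe, 0)
  expect_lt(d$dEm, 0.05)
})

test_that("the residue term equals the occupancy-weighted pair sum", {
  # two-site system: decompose FE1 against the 2-state partner FE2
  W <- 1.7
  tb <- make_titration_system(c(-300, -250), W = W)
  tr <- titrate(tb, eh_grid = seq(-500, 100, by = 2))
  d <- mfe_decompose("FE1", tr, tb)
  e <- which.min(abs(tr$conditions$Eh_mV - d$at_Eh))
  occ <- tr$occupancy[, e]
  # ox-red difference of the interaction with each FE2 conformer, weighted
  # by that conformer's occupancy: only (FE1.ox, FE2.ox) carries W
  want <- occ[["FE2.ox"]] * W
  expect_equal(d$dG_res_mfe, unname(want), tolerance = 1e-9)
})

test_that("the mean-field identity holds to machine precision", {
  for (seed in c(1, 7, 23)) {
    set.seed(seed)
    tb <- make_titration_system(c(-350, -250), W = runif(1, 0, 3),
                                ox_shift = rnorm(2))
    tr <- titrate(tb, eh_grid = seq(-700, 300, by = 5))
    for (site in c("FE1", "FE2")) {
      d <- mfe_decompose(site, tr, tb)
      expect_equal(FKCAL * d$Em_mfe / 1000,
                   FKCAL * d$Em_sol / 1000 + d$dG_bkbn + d$dG_rxn +
                     d$dG_res_mfe,
                   tolerance = 1e-12)
    }
  }
  # a fragment without redox variation cannot be decomposed
  tb <- hand_tables()
  tr <- titrate(tb, eh_grid = seq(-300, 0, 50))
  expect_error(mfe_decompose("B", tr, tb), "not redox-titratable")
})

test_that("midpoint shifts convert to energies via the Faraday constant", {
  expect_equal(em_shift_energy(-715, -170), 545 * 23.061 / 1000)
  expect_equal(round(em_shift_energy(-715, -170)), 13)
  expect_equal(em_shift_energy(-300, -300), 0)
  expect_equal(em_shift_energy(830, -170), 23.061)
})

test_that("residue breakdown matches direct occupancy-weighted summation", {
  tb <- random_titration_system(4, 3, seed = 31)
  tr <- titrate(tb, eh_grid = seq(-300, 0, by = 50))
  at <- -150
  probe <- tb$conformers$fragment[1]
  got <- residue_breakdown(probe, tr, tb, at = at)
  e <- which.min(abs(tr$conditions$Eh_mV - at))
  occ <- tr$occupancy[, e]
  ci <- tb$conformers
  prows <- which(ci$fragment == probe)
  wp <- occ[prows] / sum(occ[prows])
  for (k in seq_len(nrow(got))) {
    js <- which(ci$fragment == got$partner[k])
    want <- sum(sapply(js, function(j)
      occ[j] * sum(wp * tb$pair_elec[prows, j])))
    expect_equal(got$energy[k], want, tolerance = 1e-10)
  }
  expect_error(residue_breakdown("nope", tr, tb, at = at), "unknown probe")

  # single-conformer partner at full occupancy reports its raw pair energy
  tb2 <- hand_tables()
  tr2 <- titrate(tb2, eh_grid = seq(-200, -100, by = 50))
  g2 <- residue_breakdown("B", tr2, tb2, at = -150)
  e2 <- which.min(abs(tr2$conditions$Eh_mV - (-150)))
  occ2 <- tr2$occupancy[, e2]
  expect_equal(g2$energy[g2$partner == "A"],
               unname(occ2[1] * (-1.1) + occ2[2] * 0.7), tolerance = 1e-10)
})

test_that("table aggregation reproduces the reference row and grand totals", {
  ref <- load_reference_tables()
  tabs <- ref$interaction_tables

  kc51 <- function(cl) aggregate_row_total(tabs[[cl]]$entries["K C51", ])
  expect_equal(kc51("FA"), -33)
  expect_equal(kc51("FX"), -9.9)
  expect_equal(kc51("FB"), -4.2)
  expect_equal(aggregate_row_total(tabs$FB$entries["R C65", ]), -5.7)
  expect_equal(aggregate_row_total(rep(NA_real_, 4)), 0)

  expect_equal(aggregate_cluster_total(tabs$FX), -152.5, tolerance = 0.6)
  expect_equal(aggregate_cluster_total(tabs$FA), -126, tolerance = 0.6)
  expect_equal(aggregate_cluster_total(tabs$FB), -30, tolerance = 0.6)
  expect_equal(aggregate_cluster_total(as_interaction_table(
    matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("p", "q"))))), 0)
})

test_that("the strongest single interaction is Lys-C51 with S2 of FA", {
  ref <- load_reference_tables()
  s <- strongest_interaction(ref$interaction_tables$FA)
  expect_equal(s$partner, "K C51")
  expect_equal(s$probe, "S2")
  expect_equal(s$energy, -16.9)

  one <- as_interaction_table(matrix(-2.5, 1, 1,
                                     dimnames = list("K X1", "S1")))
  expect_equal(strongest_interaction(one)$energy, -2.5)
  ties <- as_interaction_table(matrix(c(1, -1, 1, -1), 2, 2,
    dimnames = list(c("B", "A"), c("S2", "S1"))))
  s2 <- strongest_interaction(ties)
  expect_equal(s2$partner, "A")
  expect_equal(s2$probe, "S1")
  expect_error(strongest_interaction(as_interaction_table(
    matrix(numeric(0), 0, 0))), "empty")
})

test_that("aggregation is linear and display blanking never changes totals", {
  ref <- load_reference_tables()
  t1 <- ref$interaction_tables$FX
  t2 <- as_interaction_table(3 * t1$entries)
  expect_equal(aggregate_cluster_total(t2), 3 * aggregate_cluster_total(t1))

  f <- tempfile(fileext = ".tsv")
  t3 <- as_interaction_table(t1$entries, blank_threshold = 2.0)
  write_interaction_table(t3, f)
  expect_equal(aggregate_cluster_total(t3), aggregate_cluster_total(t1))
  # blanked cells are empty on disk but row totals are written at full value
  txt <- read.delim(f, nrows = nrow(t1$entries))
  expect_equal(sum(txt$total), aggregate_cluster_total(t1), tolerance = 1e-9)
})
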