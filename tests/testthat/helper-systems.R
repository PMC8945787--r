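# Shared builders and independent oracles for the test suite.

KT298 <- 1.987204e-3 * 298
FKCAL <- 23.061

# Two-fragment system with hand-chosen printed numbers, used for direct
# hand evaluation of the microstate energy.
hand_tables <- function() {
  info <- data.frame(
    conformer = c("A.1", "A.2", "B.1"),
    fragment = c("A", "A", "B"), index = c(1, 2, 1),
    kind = "residue_sidechain", cluster = NA_character_,
    m = c(0, 1, 0), n = c(1, 0, 0),
    pK_sol = c(7, 9, 7), Em_sol = c(-170, 0, 0),
    charge_state = c(2, 1, 0), stringsAsFactors = FALSE)
  pair <- matrix(0, 3, 3)
  pair[1, 3] <- pair[3, 1] <- -1.1
  pair[2, 3] <- pair[3, 2] <- 0.7
  new_energy_tables(info, dG_rxn = c(1.2, 2.0, 0.5),
                    dG_pol = c(0.3, -0.5, 0.1), pair_elec = pair)
}

# Independent Boltzmann-occupancy oracle: explicit loops over all
# microstates, evaluating the microstate energy from the table fields
# directly (never through the package's energy or enumeration code).
oracle_occupancies <- function(tables, cond) {
  ci <- tables$conformers
  G <- tables$pair_elec + tables$pair_lj
  G[is.na(G)] <- 0
  u <- 2.3 * ci$m * KT298 * (cond$pH - ci$pK_sol) +
    ci$n * FKCAL * (cond$Eh - ci$Em_sol) / 1000 +
    as.numeric(tables$dG_rxn) + as.numeric(tables$dG_pol)
  fc <- split(seq_len(nrow(ci)), ci$fragment)
  states <- expand.grid(fc, KEEP.OUT.ATTRS = FALSE)
  E <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    sel <- as.integer(states[s, ])
    e <- sum(u[sel])
    if (length(sel) > 1)
      for (a in 1:(length(sel) - 1)) for (b in (a + 1):length(sel))
        e <- e + G[sel[a], sel[b]]
    E[s] <- e
  }
  w <- exp(-(E - min(E)) / KT298)
  w <- w / sum(w)
  occ <- numeric(nrow(ci))
  for (s in seq_len(nrow(states)))
    for (sel in as.integer(states[s, ])) occ[sel] <- occ[sel] + w[s]
  occ
}

# Independent clash oracle: brute-force all-pairs distance check with the
# same discard rule (backbone clash, or clash with every remaining
# conformer of another fragment), iterated to a fixed point.
oracle_clash <- function(conformers, structure, overlap_tol) {
  native <- redoxmc:::native_contacts(structure, overlap_tol)
  nat_key <- if (nrow(native) > 0)
    c(paste(native[, 1], native[, 2]), paste(native[, 2], native[, 1]))
  else character(0)
  bad_pair <- function(a1, a2) {
    for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
      if (paste(a1$serial[i], a2$serial[j]) %in% nat_key) next
      d <- sqrt(sum((c(a1$x[i], a1$y[i], a1$z[i]) -
                     c(a2$x[j], a2$y[j], a2$z[j]))^2))
      if (d < a1$radius[i] + a2$radius[j] - overlap_tol) return(TRUE)
    }
    FALSE
  }
  frag_of <- vapply(conformers, function(cf) cf$fragment_id, character(1))
  keep <- rep(TRUE, length(conformers))
  repeat {
    changed <- FALSE
    for (i in seq_along(conformers)) {
      if (!keep[i]) next
      cf <- conformers[[i]]
      fr <- structure$fragments[[cf$fragment_id]]$atoms
      res <- paste(fr$chain[1], fr$resno[1])
      bb <- structure$backbone
      bb <- bb[paste(bb$chain, bb$resno) != res, , drop = FALSE]
      if (nrow(bb) > 0 && bad_pair(cf$atoms, bb)) {
        keep[i] <- FALSE; changed <- TRUE; next
      }
      for (fid in setdiff(unique(frag_of), cf$fragment_id)) {
        js <- which(frag_of == fid & keep)
        if (length(js) > 0 &&
            all(vapply(js, function(j)
              bad_pair(cf$atoms, conformers[[j]]$atoms), logical(1)))) {
          keep[i] <- FALSE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
  }
  conformers[keep]
}

# Random single-atom-fragment structure for clash tests.
random_ion_structure <- function(n_frag = 7, n_conf = 3, seed = 1,
                                 box = 8) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_frag), function(i)
    data.frame(serial = i, name = "NZ", resname = "LYS", chain = "X",
               resno = 200 + i, x = runif(1, 0, box), y = runif(1, 0, box),
               z = runif(1, 0, box), stringsAsFactors = FALSE)))
  m <- redoxmc:::build_structure_model(atoms, default_charge_config())
  # add random alternate geometries
  for (fid in names(m$fragments))
    for (k in seq_len(n_conf - 1))
      m <- add_conformers(m, fid, matrix(runif(3, 0, box), 1))
  m
}

minimal_cys_pdb <- c(
  "ATOM      1  N   CYS A   1       0.000   0.000   0.000  1.00  0.00",
  "ATOM      2  CA  CYS A   1       1.458   0.000   0.000  1.00  0.00",
  "ATOM      3  C   CYS A   1       2.009   1.420   0.000  1.00  0.00",
  "ATOM      4  O   CYS A   1       3.220   1.590   0.000  1.00  0.00",
  "ATOM      5  CB  CYS A   1       1.990  -0.770   1.220  1.00  0.00",
  "ATOM      6  SG  CYS A   1       3.760  -1.110   1.210  1.00  0.00",
  "END")

sf4_pdb <- function() {
  m <- make_toy_cluster(toy_system_spec(seed = 11))
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(m, f)
  f
}
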