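conf_charges <- function(conformer) {
  data.frame(x = conformer$atoms$x, y = conformer$atoms$y,
             z = conformer$atoms$z, q = conformer$atoms$charge)
}

## Cavity-defining atoms for a conformer in its protein context: backbone +
## first conformer of every other fragment + the conformer's own geometry.
context_atoms <- function(structure, conformer) {
  others <- lapply(structure$conformers, function(cf) {
    if (cf$fragment_id == conformer$fragment_id) return(NULL)
    if (cf$index == 1) cf$atoms else NULL
  })
  rbind(structure$backbone, do.call(rbind, others), conformer$atoms)
}

#' Desolvation (reaction-field) energy of a conformer
#'
#' The loss of reaction-field stabilization when the conformer moves from
#' bulk water (its own atoms carving the cavity) to its buried position in
#' the protein dielectric: positive for buried net charge.
#'
#' @param conformer a `conformer`.
#' @param structure the `structure_model` providing the protein cavity.
#' @param env a [dielectric_env()].
#' @param grid a [grid_spec()].
#' @return Delta-Delta-G_rxn, kcal/mol.
#' @export
reaction_field_energy <- function(conformer, structure, env,
                                  grid = grid_spec()) {
  q <- conf_charges(conformer)
  if (all(q$q == 0)) return(0)
  rf_prot <- rf_energy(pb_reaction_pair(q, context_atoms(structure, conformer),
                                        env, grid))
  rf_aq <- rf_energy(pb_reaction_pair(q, conformer$atoms, env, grid))
  rf_prot - rf_aq
}

#' Screened interaction of a conformer with the fixed backbone
#'
#' @inheritParams reaction_field_energy
#' @return Delta-G_pol, kcal/mol (0 when either charge set is empty).
#' @export
backbone_energy <- function(conformer, structure, env, grid = grid_spec()) {
  q <- conf_charges(conformer)
  bb <- structure$backbone
  if (all(q$q == 0) || nrow(bb) == 0 || all(bb$charge == 0)) return(0)
  pair <- pb_reaction_pair(q, context_atoms(structure, conformer), env, grid)
  interaction_energy(pair, data.frame(x = bb$x, y = bb$y, z = bb$z,
                                      q = bb$charge))
}

#' Pairwise conformer-conformer interaction energy
#'
#' Screened electrostatic energy (symmetrized over both source/target
#' orderings) plus a 12-6 Lennard-Jones term.  Conformers of the same
#' fragment are never co-occupied: the sentinel `NA` is returned.
#'
#' @param conformer_i,conformer_j two `conformer`s of different fragments.
#' @inheritParams reaction_field_energy
#' @param include_lj add the Lennard-Jones term (default `TRUE`).
#' @return Delta-G_ij, kcal/mol, or `NA` for a same-fragment pair.
#' @export
pairwise_energy <- function(conformer_i, conformer_j, structure, env,
                            grid = grid_spec(), include_lj = TRUE) {
  if (conformer_i$fragment_id == conformer_j$fragment_id) return(NA_real_)
  qi <- conf_charges(conformer_i)
  qj <- conf_charges(conformer_j)
  elec <- 0
  if (any(qi$q != 0) && any(qj$q != 0)) {
    e_ij <- interaction_energy(
      pb_reaction_pair(qi, context_atoms(structure, conformer_i), env, grid), qj)
    e_ji <- interaction_energy(
      pb_reaction_pair(qj, context_atoms(structure, conformer_j), env, grid), qi)
    elec <- (e_ij + e_ji) / 2
  }
  lj <- if (include_lj) lj_energy(conformer_i$atoms, conformer_j$atoms) else 0
  elec + lj
}

## 12-6 Lennard-Jones with per-atom (eps, Rmin/2) parameters,
## Lorentz-Berthelot style combination.
lj_energy <- function(a1, a2) {
  if (nrow(a1) == 0 || nrow(a2) == 0) return(0)
  d <- pair_dists(a1, a2)
  d <- pmax(d, 0.5)
  eps <- sqrt(outer(a1$lj_eps, a2$lj_eps))
  rmin <- outer(a1$lj_rmin, a2$lj_rmin, "+")
  s6 <- (rmin / d)^6
  sum(eps * (s6^2 - 2 * s6))
}

#' Build the full energy tables for a structure model
#'
#' Runs the PB solver for every charged conformer (one heterogeneous +
#' homogeneous pair in the protein context, one pair in the aqueous
#' reference) and assembles the three ingredients of the microstate energy:
#' per-conformer desolvation energies, backbone interaction energies, and
#' the M x M pairwise matrix (electrostatic + Lennard-Jones, symmetrized;
#' same-fragment entries are the sentinel `NA`, the diagonal is 0).
#'
#' @param structure a `structure_model`.
#' @inheritParams reaction_field_energy
#' @param include_lj include Lennard-Jones pair terms.
#' @param verbose print per-conformer progress.
#' @return an `energy_tables` object.
#' @export
build_energy_tables <- function(structure, env, grid = grid_spec(),
                                include_lj = TRUE, verbose = FALSE) {
  info <- conformer_info(structure)
  cfs <- structure$conformers
  M <- length(cfs)
  dG_rxn <- dG_pol <- numeric(M)
  elec_dir <- matrix(0, M, M)
  bb <- structure$backbone
  bbq <- if (nrow(bb) > 0) data.frame(x = bb$x, y = bb$y, z = bb$z,
                                      q = bb$charge) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0), q = numeric(0))

  for (i in seq_len(M)) {
    cf <- cfs[[i]]
    q <- conf_charges(cf)
    if (all(q$q == 0)) next
    ok <- try({
      pair_prot <- pb_reaction_pair(q, context_atoms(structure, cf), env, grid)
      pair_aq <- pb_reaction_pair(q, cf$atoms, env, grid)
      dG_rxn[i] <- rf_energy(pair_prot) - rf_energy(pair_aq)
      dG_pol[i] <- if (nrow(bbq) > 0 && any(bbq$q != 0))
        interaction_energy(pair_prot, bbq) else 0
      for (j in seq_len(M)) {
        if (j == i || cfs[[j]]$fragment_id == cf$fragment_id) next
        elec_dir[i, j] <- interaction_energy(pair_prot, conf_charges(cfs[[j]]))
      }
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("energy calculation failed for conformer ", info$conformer[i],
           " (fragment ", info$fragment[i], "): ", attr(ok, "condition")$message)
    if (verbose)
      message(info$conformer[i], ": rxn=", round(dG_rxn[i], 2),
              " pol=", round(dG_pol[i], 2))
  }

  pair_elec <- (elec_dir + t(elec_dir)) / 2
  pair_lj <- matrix(0, M, M)
  if (include_lj) {
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (j <= i || cfs[[j]]$fragment_id == cfs[[i]]$fragment_id) next
      pair_lj[i, j] <- pair_lj[j, i] <- lj_energy(cfs[[i]]$atoms, cfs[[j]]$atoms)
    }
  }
  same <- outer(info$fragment, info$fragment, "==")
  diag(same) <- FALSE
  pair_elec[same] <- NA_real_
  pair_lj[same] <- NA_real_
  new_energy_tables(info, dG_rxn, dG_pol, pair_elec, pair_lj)
}

#' Construct energy tables from precomputed components
#'
#' @param conformers conformer info data frame (see [conformer_info()]).
#' @param dG_rxn,dG_pol per-conformer desolvation and backbone energies,
#'   kcal/mol.
#' @param pair_elec,pair_lj M x M symmetric matrices (kcal/mol), `NA` for
#'   same-fragment entries, zero diagonal.
#' @return an `energy_tables` object.
#' @export
new_energy_tables <- function(conformers, dG_rxn, dG_pol, pair_elec,
                              pair_lj = NULL) {
  M <- nrow(conformers)
  if (is.null(pair_lj)) pair_lj <- matrix(0, M, M)
  same <- outer(conformers$fragment, conformers$fragment, "==")
  diag(same) <- FALSE
  pair_elec[same] <- NA_real_
  pair_lj[same] <- NA_real_
  diag(pair_elec) <- 0
  diag(pair_lj) <- 0
  stopifnot(length(dG_rxn) == M, length(dG_pol) == M,
            all(dim(pair_elec) == M), all(dim(pair_lj) == M))
  ok <- !is.na(pair_elec)
  stopifnot(all(abs(pair_elec[ok] - t(pair_elec)[ok]) < 1e-9))
  dimnames(pair_elec) <- dimnames(pair_lj) <-
    list(conformers$conformer, conformers$conformer)
  structure(list(conformers = conformers,
                 dG_rxn = setNames(dG_rxn, conformers$conformer),
                 dG_pol = setNames(dG_pol, conformers$conformer),
                 pair_elec = pair_elec, pair_lj = pair_lj),
            class = "energy_tables")
}

#' Pairwise energy matrix of an `energy_tables` object
#'
#' @param tables an `energy_tables` object.
#' @param include_lj include the Lennard-Jones component.
#' @return M x M matrix, `NA` sentinel for same-fragment pairs.
#' @export
dG_pair <- function(tables, include_lj = TRUE) {
  if (include_lj) tables$pair_elec + tables$pair_lj else tables$pair_elec
}

#' @export
print.energy_tables <- function(x, ...) {
  cat("energy_tables:", nrow(x$conformers), "conformers,",
      length(unique(x$conformers$fragment)), "fragments\n")
  cat("  dG_rxn range:", paste(round(range(x$dG_rxn), 3), collapse = " .. "),
      "kcal/mol\n")
  invisible(x)
}

#' Write / read energy tables as TSV
#'
#' `<prefix>_conformers.tsv` holds the per-conformer vectors and reference
#' chemistry; `<prefix>_pair_elec.tsv` and `<prefix>_pair_lj.tsv` hold the
#' dense pair matrices (header = conformer ids, `NA` = same-fragment
#' sentinel).
#'
#' @param tables an `energy_tables` object.
#' @param prefix file path prefix.
#' @return `read_energy_tables()` returns the reconstructed object.
#' @export
write_energy_tables <- function(tables, prefix) {
  cv <- cbind(tables$conformers, dG_rxn = as.numeric(tables$dG_rxn),
              dG_pol = as.numeric(tables$dG_pol))
  write.table(cv, paste0(prefix, "_conformers.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(tables$pair_elec, paste0(prefix, "_pair_elec.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(tables$pair_lj, paste0(prefix, "_pair_lj.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_energy_tables
#' @export
read_energy_tables <- function(prefix) {
  cv <- read.delim(paste0(prefix, "_conformers.tsv"), check.names = FALSE)
  pe <- as.matrix(read.delim(paste0(prefix, "_pair_elec.tsv"),
                             check.names = FALSE))
  pl <- as.matrix(read.delim(paste0(prefix, "_pair_lj.tsv"),
                             check.names = FALSE))
  info <- cv[, setdiff(names(cv), c("dG_rxn", "dG_pol"))]
  new_energy_tables(info, cv$dG_rxn, cv$dG_pol, unname(pe), unname(pl))
}
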