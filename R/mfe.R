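#' Mean-field energy decomposition of an in-protein midpoint potential
#'
#' Splits the shift of a redox site's Em from its solution reference into
#' desolvation, backbone and occupancy-weighted residue terms:
#'
#'   F Em_MFE = n F Em_sol + dG_bkbn + ddG_rxn + dG_res_MFE
#'
#' Each term is the oxidized-minus-reduced difference of that energy for
#' the site's conformers; the residue term weights each partner conformer
#' by its Boltzmann occupancy at the evaluation Eh.  The identity above
#' holds by construction.  `dEm` is reported separately from the sampled
#' (Monte Carlo / enumeration) Em, which differs from the mean-field sum by
#' construction.
#'
#' @param site fragment id of a redox-titratable site.
#' @param result a `titration_result` whose grid covers the site's Em.
#' @param tables the `energy_tables` used for the titration.
#' @param at Eh (mV) at which occupancies are taken; defaults to the
#'   site's midpoint from `result`.
#' @param em_calc the sampled Em used for `dEm` (default: the site's
#'   midpoint; pass the cluster Em when decomposing a cluster site).
#' @return an `mfe_breakdown`: `site_id`, `Em_sol`, `dG_bkbn`, `dG_rxn`,
#'   `dG_res_mfe`, `Em_mfe` (mV), `dEm` (kcal/mol, from `em_calc`),
#'   `dG_mfe_sum` (kcal/mol, sum of the three mean-field terms), and
#'   `residue_terms` (per-partner-fragment contributions).
#' @export
mfe_decompose <- function(site, result, tables, at = NULL, em_calc = NULL) {
  ci <- tables$conformers
  rows <- which(ci$fragment == site)
  if (length(rows) == 0) stop("unknown fragment id: ", site)
  if (all(ci$n[rows] == ci$n[rows][1]))
    stop("fragment ", site, " is not redox-titratable (no variation in n)")
  nmin <- min(ci$n[rows])
  nmax <- max(ci$n[rows])
  ox <- rows[ci$n[rows] == nmin]
  red <- rows[ci$n[rows] == nmax]
  n_el <- nmax - nmin
  Em_sol <- ci$Em_sol[red[1]]

  if (is.null(em_calc)) em_calc <- result$midpoints[[site]]
  if (is.null(at)) at <- em_calc
  e <- which.min(abs(result$conditions$Eh_mV - at))
  occ <- result$occupancy[, e]

  ## occupancy weights within each redox state of the site
  wt <- function(ix) {
    w <- occ[ix]
    if (sum(w) <= 0) w <- rep(1, length(ix))
    w / sum(w)
  }
  wox <- wt(ox)
  wred <- wt(red)

  dG_rxn <- sum(wox * tables$dG_rxn[ox]) - sum(wred * tables$dG_rxn[red])
  dG_bkbn <- sum(wox * tables$dG_pol[ox]) - sum(wred * tables$dG_pol[red])

  G <- dG_pair(tables)
  others <- which(!ci$fragment %in% site)
  diffint <- vapply(others, function(j) {
    sum(wox * G[ox, j]) - sum(wred * G[red, j])
  }, numeric(1))
  contrib <- occ[others] * diffint
  dG_res <- sum(contrib)
  res_terms <- tapply(contrib, ci$fragment[others], sum)

  Em_mfe <- Em_sol + 1000 * (dG_bkbn + dG_rxn + dG_res) /
    (n_el * FARADAY_KCAL)
  structure(list(site_id = site, Em_sol = Em_sol, dG_bkbn = dG_bkbn,
                 dG_rxn = dG_rxn, dG_res_mfe = dG_res, Em_mfe = Em_mfe,
                 dEm = em_shift_energy(em_calc, Em_sol),
                 dG_mfe_sum = dG_bkbn + dG_rxn + dG_res,
                 residue_terms = res_terms, at_Eh = result$conditions$Eh_mV[e]),
            class = "mfe_breakdown")
}

#' Midpoint shift expressed as an energy
#'
#' @param Em_calc,Em_sol midpoint potentials, mV.
#' @return `|Em_calc - Em_sol| * F / 1000`, kcal/mol.
#' @export
em_shift_energy <- function(Em_calc, Em_sol) {
  abs(Em_calc - Em_sol) * FARADAY_KCAL / 1000
}

#' Per-partner mean-field interaction energies of a probe fragment
#'
#' For each partner fragment, the occupancy-weighted electrostatic
#' interaction with the probe at the evaluation Eh (typically the cluster
#' Em): `sum_j <occ_j> dG_elec(probe, j)`.  Entries below the display
#' threshold are flagged but retained at full precision.
#'
#' @param probe fragment id of the probe (e.g. a bridging sulfur).
#' @param result a `titration_result`.
#' @param tables the `energy_tables`.
#' @param at Eh (mV) for the occupancies; default: nearest grid point to
#'   the middle of the grid is NOT assumed -- pass the cluster Em.
#' @param blank_threshold display threshold, kcal/mol (default 0.5).
#' @return data frame: `partner`, `energy` (kcal/mol), `blanked`.
#' @export
residue_breakdown <- function(probe, result, tables, at,
                              blank_threshold = 0.5) {
  ci <- tables$conformers
  prows <- which(ci$fragment == probe)
  if (length(prows) == 0) stop("unknown probe fragment id: ", probe)
  e <- which.min(abs(result$conditions$Eh_mV - at))
  occ <- result$occupancy[, e]
  G <- tables$pair_elec   # interaction reports are purely electrostatic
  wp <- occ[prows] / max(sum(occ[prows]), 1e-12)
  partners <- setdiff(unique(ci$fragment), probe)
  energy <- vapply(partners, function(f) {
    js <- which(ci$fragment == f)
    sum(vapply(js, function(j) occ[j] * sum(wp * G[prows, j]), numeric(1)))
  }, numeric(1))
  data.frame(partner = partners, energy = as.numeric(energy),
             blanked = abs(energy) < blank_threshold,
             stringsAsFactors = FALSE)
}

#' Interaction tables (partner residues x probe fragments)
#'
#' `interaction_table()` assembles a mean-field interaction table with one
#' column per probe fragment; `as_interaction_table()` wraps an existing
#' numeric matrix (e.g. a transcribed reference table, `NA` = blank).
#'
#' @param probes character vector of probe fragment ids.
#' @inheritParams residue_breakdown
#' @return an `interaction_table`: list with `entries` (matrix, rows =
#'   partners, cols = probes; `NA` = blank), `blank_threshold`.
#' @export
interaction_table <- function(probes, result, tables, at,
                              blank_threshold = 0.5) {
  cols <- lapply(probes, residue_breakdown, result = result, tables = tables,
                 at = at, blank_threshold = blank_threshold)
  partners <- cols[[1]]$partner
  entries <- vapply(cols, function(d) d$energy[match(partners, d$partner)],
                    numeric(length(partners)))
  entries <- matrix(entries, nrow = length(partners),
                    dimnames = list(partners, probes))
  as_interaction_table(entries, blank_threshold)
}

#' @rdname interaction_table
#' @param entries numeric matrix of mean-field energies (kcal/mol).
#' @export
as_interaction_table <- function(entries, blank_threshold = 0.5) {
  stopifnot(is.matrix(entries))
  structure(list(entries = entries, blank_threshold = blank_threshold),
            class = "interaction_table")
}

#' Row and table totals of an interaction table
#'
#' Blank (`NA`) cells count as zero; displayed blanking never changes the
#' stored values, so totals are unaffected by the display threshold.
#'
#' @param entries numeric vector (one partner row across probes).
#' @return kcal/mol.
#' @export
aggregate_row_total <- function(entries) sum(entries, na.rm = TRUE)

#' @rdname aggregate_row_total
#' @param table an `interaction_table`.
#' @export
aggregate_cluster_total <- function(table) {
  sum(apply(table$entries, 1, aggregate_row_total))
}

#' Strongest single interaction in a table
#'
#' Maximum-magnitude entry; ties broken by (partner id, probe id)
#' lexicographic order.
#'
#' @param table an `interaction_table`.
#' @return list with `partner`, `probe`, `energy`.
#' @export
strongest_interaction <- function(table) {
  e <- table$entries
  if (length(e) == 0 || all(is.na(e))) stop("empty interaction table")
  mag <- abs(e)
  mag[is.na(mag)] <- -Inf
  best <- max(mag)
  hits <- which(mag == best, arr.ind = TRUE)
  ord <- order(rownames(e)[hits[, 1]], colnames(e)[hits[, 2]])
  h <- hits[ord[1], , drop = FALSE]
  list(partner = rownames(e)[h[1]], probe = colnames(e)[h[2]],
       energy = e[h])
}

#' Write an interaction table as TSV
#'
#' Residue rows, per-probe columns, row totals and a grand total; cells
#' below the blank threshold are written empty (stored values are not
#' modified).
#'
#' @param table an `interaction_table`.
#' @param file output path.
#' @export
write_interaction_table <- function(table, file) {
  e <- table$entries
  disp <- ifelse(is.na(e) | abs(e) < table$blank_threshold, "",
                 format(round_half_away(e, 1)))
  out <- data.frame(partner = rownames(e), disp,
                    total = apply(e, 1, aggregate_row_total),
                    check.names = FALSE)
  names(out) <- c("partner", colnames(e), "total")
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("# grand_total\t", aggregate_cluster_total(table), "\n",
      file = file, append = TRUE, sep = "")
  invisible(file)
}

#' @export
print.mfe_breakdown <- function(x, ...) {
  cat("Mean-field decomposition for", x$site_id, "\n")
  cat(sprintf("  Em_sol      %8.1f mV\n", x$Em_sol))
  cat(sprintf("  dG_bkbn     %8.2f kcal/mol\n", x$dG_bkbn))
  cat(sprintf("  ddG_rxn     %8.2f kcal/mol\n", x$dG_rxn))
  cat(sprintf("  dG_res_MFE  %8.2f kcal/mol\n", x$dG_res_mfe))
  cat(sprintf("  Em_MFE      %8.1f mV\n", x$Em_mfe))
  cat(sprintf("  dEm         %8.2f kcal/mol (from sampled Em)\n", x$dEm))
  invisible(x)
}
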