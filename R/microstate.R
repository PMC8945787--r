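#' Titration condition
#'
#' @param pH solution pH (default 7).
#' @param Eh solution redox potential, mV vs SHE.
#' @param temperature Kelvin.
#' @return a `titration_condition` list.
#' @export
titration_condition <- function(pH = 7, Eh = 0, temperature = 298) {
  stopifnot(temperature > 0)
  structure(list(pH = pH, Eh = Eh, temperature = temperature),
            class = "titration_condition")
}

## Condition-dependent self energy of every conformer (kcal/mol):
##   2.3 m kT (pH - pKsol) + n F (Eh - Em,sol) + ddG_rxn + dG_pol
## Eh and Em,sol in mV; F converts V to kcal/mol.
self_energies <- function(tables, cond) {
  ci <- tables$conformers
  kT <- kbt(cond$temperature)
  2.3 * ci$m * kT * (cond$pH - ci$pK_sol) +
    ci$n * FARADAY_KCAL * (cond$Eh - ci$Em_sol) / 1000 +
    as.numeric(tables$dG_rxn) + as.numeric(tables$dG_pol)
}

fragment_conformers <- function(tables) {
  split(seq_len(nrow(tables$conformers)), tables$conformers$fragment)
}

#' Microstate energy
#'
#' Energy of one choice of conformer per fragment: the sum over selected
#' conformers of the pH/Eh ionization terms, desolvation and backbone
#' energies, plus the pairwise interaction counted once per unordered pair.
#'
#' @param selection integer vector of conformer indices (rows of
#'   `tables$conformers`), exactly one per fragment.
#' @param tables an `energy_tables` object.
#' @param cond a [titration_condition()].
#' @return kcal/mol.
#' @export
microstate_energy <- function(selection, tables, cond = titration_condition()) {
  frag <- tables$conformers$fragment[selection]
  if (anyDuplicated(frag) || length(selection) !=
      length(unique(tables$conformers$fragment)))
    stop("selection must pick exactly one conformer per fragment")
  u <- self_energies(tables, cond)
  G <- dG_pair(tables)
  tot <- sum(u[selection])
  if (length(selection) > 1) {
    pr <- utils::combn(selection, 2)
    gv <- G[t(pr)]
    stopifnot(!anyNA(gv))  # same-fragment sentinel is unreachable here
    tot <- tot + sum(gv)
  }
  tot
}

#' Exact Boltzmann occupancies by enumeration
#'
#' Enumerates every microstate (feasible for small systems only) and
#' returns each conformer's Boltzmann probability.  Serves as the exact
#' reference for the Monte Carlo engine.
#'
#' @inheritParams microstate_energy
#' @param max_states refuse enumeration beyond this many microstates.
#' @return named numeric vector of occupancies (each fragment's conformers
#'   sum to 1).
#' @export
enumerate_occupancies <- function(tables, cond = titration_condition(),
                                  max_states = 1e6) {
  fc <- fragment_conformers(tables)
  nstates <- prod(vapply(fc, length, numeric(1)))
  if (nstates > max_states)
    stop("state space too large (", format(nstates, big.mark = ","),
         " microstates); use mc_sample()")
  sel <- as.matrix(expand.grid(fc, KEEP.OUT.ATTRS = FALSE))
  u <- self_energies(tables, cond)
  G <- dG_pair(tables)
  G[is.na(G)] <- 0
  E <- rowSums(matrix(u[sel], nrow = nrow(sel)))
  nf <- ncol(sel)
  if (nf > 1)
    for (a in seq_len(nf - 1)) for (b in seq((a + 1), nf))
      E <- E + G[cbind(sel[, a], sel[, b])]
  kT <- kbt(cond$temperature)
  w <- exp(-(E - min(E)) / kT)
  w <- w / sum(w)
  occ <- numeric(nrow(tables$conformers))
  for (f in seq_len(nf)) {
    agg <- tapply(w, sel[, f], sum)
    occ[as.integer(names(agg))] <- as.numeric(agg)
  }
  setNames(occ, tables$conformers$conformer)
}

#' Metropolis Monte Carlo conformer sampling
#'
#' Single-conformer flips with Metropolis acceptance; occupancies are visit
#' fractions after burn-in and `mc_error` is the batch-means standard
#' error.  The same seed reproduces results bit-for-bit.
#'
#' @inheritParams microstate_energy
#' @param sweeps_burnin,sweeps_sample full sweeps (one attempted flip per
#'   flexible fragment) discarded / sampled.
#' @param nbatch batches for the error estimate.
#' @param seed RNG seed (required, for reproducibility).
#' @return list with `occupancy`, `mc_error` (named vectors), `acceptance`.
#' @export
mc_sample <- function(tables, cond = titration_condition(),
                      sweeps_burnin = 2000, sweeps_sample = 10000,
                      nbatch = 20, seed) {
  if (missing(seed)) stop("an explicit seed is required for mc_sample()")
  set.seed(seed)
  fc <- fragment_conformers(tables)
  u <- self_energies(tables, cond)
  G <- dG_pair(tables)
  G[is.na(G)] <- 0
  res <- mc_run_cpp(u, G, lapply(fc, function(ix) as.integer(ix - 1)),
                    kbt(cond$temperature), as.integer(sweeps_burnin),
                    as.integer(sweeps_sample), as.integer(nbatch))
  if (res$acceptance == 0 && any(vapply(fc, length, numeric(1)) > 1))
    warning("Monte Carlo acceptance ratio was 0; sampling may be non-ergodic")
  list(occupancy = setNames(res$occupancy, tables$conformers$conformer),
       mc_error = setNames(res$mc_error, tables$conformers$conformer),
       acceptance = res$acceptance)
}

#' Titrate a system across an Eh grid
#'
#' Computes conformer occupancies at each Eh (fixed pH), retains per-site
#' oxidized-fraction curves for redox fragments, and extracts per-site
#' midpoints (0.5-crossings, linear interpolation).
#'
#' @param tables an `energy_tables` object.
#' @param pH fixed pH (default 7).
#' @param eh_grid monotone vector of Eh values, mV.
#' @param engine `"enumerate"` (exact) or `"mc"`.
#' @param seed RNG seed (required for the MC engine).
#' @param temperature Kelvin.
#' @param ... passed to [mc_sample()].
#' @return a `titration_result`: `conditions` (data frame), `occupancy`
#'   (M x n_Eh matrix), `mc_error`, `ox_frac` (redox sites x n_Eh),
#'   `midpoints` (per-site Em, mV).
#' @export
titrate <- function(tables, pH = 7, eh_grid, engine = c("enumerate", "mc"),
                    seed = NULL, temperature = 298, ...) {
  engine <- match.arg(engine)
  if (is.unsorted(eh_grid)) stop("eh_grid must be monotone increasing")
  M <- nrow(tables$conformers)
  occ <- err <- matrix(0, M, length(eh_grid),
                       dimnames = list(tables$conformers$conformer, NULL))
  for (e in seq_along(eh_grid)) {
    cond <- titration_condition(pH = pH, Eh = eh_grid[e],
                                temperature = temperature)
    if (engine == "enumerate") {
      occ[, e] <- enumerate_occupancies(tables, cond)
    } else {
      if (is.null(seed)) stop("the MC engine requires a seed")
      r <- mc_sample(tables, cond, seed = seed + e, ...)
      occ[, e] <- r$occupancy
      err[, e] <- r$mc_error
    }
  }
  ox <- oxidized_fractions(tables, occ)
  structure(list(
    conditions = data.frame(pH = pH, Eh_mV = eh_grid,
                            temperature = temperature),
    occupancy = occ, mc_error = err, ox_frac = ox,
    midpoints = apply_midpoints(ox, eh_grid), engine = engine),
    class = "titration_result")
}

## Oxidized fraction per redox fragment: occupancy of the electron-poor
## (lowest-n) conformers.
oxidized_fractions <- function(tables, occ) {
  ci <- tables$conformers
  redox <- unique(ci$fragment[ci$n > 0])
  if (length(redox) == 0)
    return(matrix(numeric(0), 0, ncol(occ)))
  out <- t(vapply(redox, function(f) {
    rows <- which(ci$fragment == f)
    nmin <- min(ci$n[rows])
    colSums(occ[rows[ci$n[rows] == nmin], , drop = FALSE])
  }, numeric(ncol(occ))))
  rownames(out) <- redox
  out
}

apply_midpoints <- function(ox, eh_grid) {
  vapply(seq_len(nrow(ox)), function(i)
    tryCatch(crossing_eh(ox[i, ], eh_grid, 0.5), error = function(e) NA_real_),
    numeric(1)) |> setNames(rownames(ox))
}

crossing_eh <- function(f, eh, level) {
  above <- f >= level
  k <- which(!above[-length(f)] & above[-1])
  if (length(k) == 0) {
    if (all(above) || all(!above))
      stop("curve does not cross ", level, " inside the Eh grid (range ",
           round(min(f), 3), " .. ", round(max(f), 3), ")")
    k <- which(diff(above) != 0)
  }
  k <- k[1]
  eh[k] + (level - f[k]) * (eh[k + 1] - eh[k]) / (f[k + 1] - f[k])
}

#' Cluster midpoint potential by the second-oxidation convention
#'
#' The Em of a multi-Fe cluster is the Eh at which the expected number of
#' oxidized Fe sites crosses `event - 0.5` (default `event = 2`: the
#' midpoint of the second oxidation, i.e. the +1 to +2 couple of a 4Fe-4S
#' cluster), linearly interpolated between grid points.
#'
#' @param result a `titration_result` from [titrate()].
#' @param cluster_fragments ids of the cluster's Fe fragments (>= 2).
#' @param event which oxidation event defines the midpoint.
#' @return Em, mV.
#' @export
extract_cluster_em <- function(result, cluster_fragments, event = 2) {
  stopifnot(length(cluster_fragments) >= 2)
  miss <- setdiff(cluster_fragments, rownames(result$ox_frac))
  if (length(miss) > 0)
    stop("not redox-titratable site(s): ", paste(miss, collapse = ", "))
  nox <- colSums(result$ox_frac[cluster_fragments, , drop = FALSE])
  crossing_eh(nox, result$conditions$Eh_mV, event - 0.5)
}

#' Write titration output as TSV
#'
#' Long-format occupancies (`Eh_mV`, `fragment`, `conformer`, `occupancy`,
#' `mc_error`) and a per-site midpoint summary.
#'
#' @param result a `titration_result`.
#' @param prefix output path prefix.
#' @export
write_titration <- function(result, prefix) {
  ci <- data.frame(conformer = rownames(result$occupancy))
  long <- do.call(rbind, lapply(seq_len(ncol(result$occupancy)), function(e)
    data.frame(Eh_mV = result$conditions$Eh_mV[e], conformer = ci$conformer,
               occupancy = result$occupancy[, e],
               mc_error = result$mc_error[, e])))
  write.table(long, paste0(prefix, "_occupancy.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  mid <- data.frame(fragment = names(result$midpoints),
                    Em_mV = as.numeric(result$midpoints))
  write.table(mid, paste0(prefix, "_midpoints.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @export
print.titration_result <- function(x, ...) {
  cat("titration_result:", nrow(x$occupancy), "conformers x",
      nrow(x$conditions), "Eh points (engine:", x$engine, ")\n")
  if (length(x$midpoints) > 0) {
    cat("  site midpoints (mV):\n")
    print(round(x$midpoints, 1))
  }
  invisible(x)
}
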