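#' Specification for a synthetic cluster system
#'
#' Defines a toy structure with the physical features the analysis assumes:
#' a buried cubane Fe/S core with integer formal charges, cysteine-thiolate
#' SG ligands, charged Lys-like shell residues with charged/neutral
#' conformer pairs, and amide-like backbone dipoles.  All placement is a
#' pure function of the spec and its seed.
#'
#' @param n_fe 4 for a cubane, 1 for a single Born-like buried ion.
#' @param cube_edge Fe-S edge length of the cubane, Angstrom.
#' @param sg_bond Fe-SG bond length, Angstrom.
#' @param shell_charges list of shells, each `list(charge, distance, count)`
#'   (elementary charge, Angstrom from the cluster centre, number of
#'   sites); emulates the Lys/Arg hydrogen-bond donors around a buried
#'   cluster.
#' @param backbone_dipoles `list(count, distance)`: number of amide-like
#'   N-H dipoles and their distance from the centre (partial charges come
#'   from the charge configuration: N -0.4, H +0.4).
#' @param site_em_sol solution reference Em for the Fe sites, mV (recycled
#'   over sites).
#' @param seed integer seed controlling shell/dipole placement.
#' @return a `toy_system_spec` list.
#' @export
toy_system_spec <- function(n_fe = 4, cube_edge = 2.3, sg_bond = 2.31,
                            shell_charges = list(list(charge = 1,
                                                      distance = 6,
                                                      count = 4)),
                            backbone_dipoles = list(count = 8, distance = 5),
                            site_em_sol = -170, seed = 1) {
  stopifnot(n_fe %in% c(1, 4), cube_edge > 0, sg_bond > 0)
  structure(list(n_fe = n_fe, cube_edge = cube_edge, sg_bond = sg_bond,
                 shell_charges = shell_charges,
                 backbone_dipoles = backbone_dipoles,
                 site_em_sol = site_em_sol, seed = as.integer(seed)),
            class = "toy_system_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

unit_directions <- function(k) {
  m <- matrix(stats::rnorm(3 * k), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate a toy cluster structure
#'
#' @param spec a [toy_system_spec()].
#' @param config charge configuration (default [default_charge_config()]).
#' @return a `structure_model` (PDB-writable via [write_structure_pdb()]).
#' @export
make_toy_cluster <- function(spec = toy_system_spec(),
                             config = default_charge_config()) {
  a <- spec$cube_edge
  rows <- list()
  serial <- 0
  add <- function(name, resname, resno, xyz) {
    serial <<- serial + 1
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, resname = resname, chain = "X",
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }

  if (spec$n_fe == 4) {
    fe_pos <- rbind(c(0, 0, 0), c(a, a, 0), c(a, 0, a), c(0, a, a))
    s_pos <- rbind(c(a, 0, 0), c(0, a, 0), c(0, 0, a), c(a, a, a))
    centre <- colMeans(fe_pos)
    for (i in 1:4) add(paste0("FE", i), "SF4", 900, fe_pos[i, ])
    for (i in 1:4) add(paste0("S", i), "SF4", 900, s_pos[i, ])
    for (i in 1:4) {
      dir <- fe_pos[i, ] - centre
      dir <- dir / sqrt(sum(dir^2))
      add("SG", "CYS", 100 + i, fe_pos[i, ] + spec$sg_bond * dir)
    }
  } else {
    centre <- c(0, 0, 0)
    add("FE", "FE", 900, centre)
  }

  with_local_seed(spec$seed, {
    placed <- matrix(numeric(0), ncol = 3)
    resno <- 200
    for (shell in spec$shell_charges) {
      if (is.null(shell$count) || shell$count == 0) next
      if (shell$charge <= 0)
        stop("toy shells are Lys-like donors; shell charge must be positive")
      for (i in seq_len(shell$count)) {
        ## rejection-sample a direction keeping shell sites apart
        p <- NULL
        for (try in 1:200) {
          cand <- centre + shell$distance * unit_directions(1)[1, ]
          if (nrow(placed) == 0 ||
              min(sqrt(rowSums(sweep(placed, 2, cand)^2))) >= 2.5) {
            p <- cand
            break
          }
        }
        if (is.null(p))
          stop("overlapping shell sites; the requested shell layout cannot ",
               "be placed with 2.5 A separation")
        placed <- rbind(placed, p)
        resno <- resno + 1
        add("NZ", "LYS", resno, p)
      }
    }
    bd <- spec$backbone_dipoles
    if (!is.null(bd) && bd$count > 0) {
      dirs <- unit_directions(bd$count)
      hdirs <- unit_directions(bd$count)
      for (i in seq_len(bd$count)) {
        p <- centre + bd$distance * dirs[i, ]
        resno <- resno + 1
        add("N", "GLY", resno, p)
        add("H", "GLY", resno, p + 1.0 * hdirs[i, ])
      }
    }
  })

  atoms <- do.call(rbind, rows)
  model <- build_structure_model(atoms, config)

  ## per-site solution reference Em
  fe_ids <- names(model$fragments)[vapply(model$fragments, function(f)
    f$kind == "fe_ion", logical(1))]
  ems <- rep_len(spec$site_em_sol, length(fe_ids))
  for (k in seq_along(model$conformers)) {
    fid <- model$conformers[[k]]$fragment_id
    hit <- match(fid, fe_ids)
    if (!is.na(hit)) model$conformers[[k]]$Em_sol <- ems[hit]
  }
  for (k in seq_along(fe_ids))
    model$fragments[[fe_ids[k]]]$states <- lapply(
      model$fragments[[fe_ids[k]]]$states,
      function(s) { s$Em_sol <- ems[k]; s })
  model
}

#' Analytic titration system with known closed-form behaviour
#'
#' Builds energy tables for a set of one-electron redox sites with given
#' solution midpoints, an optional ferric-ferric repulsion `W` between
#' oxidized conformers of different sites, and optional per-site shifts of
#' the oxidized conformer's self energy.  With split site potentials the
#' second-oxidation midpoint is `max(site_ems) + 1000 * W / 23.061` mV
#' exactly; with degenerate potentials the exact crossing carries an
#' additional configurational-entropy shift (see the vignette).
#'
#' @param site_ems solution midpoints (mV), one per site.
#' @param W ferric-ferric coupling, kcal/mol: scalar (all pairs) or an
#'   n_site x n_site symmetric matrix.
#' @param ox_shift per-site energy added to the oxidized conformer
#'   (kcal/mol), e.g. an injected net protein shift.
#' @param interaction_overrides optional full M x M pair-energy matrix
#'   (M = 2 * n_sites, conformer order red1, ox1, red2, ox2, ...).
#' @return an `energy_tables` object.
#' @export
make_titration_system <- function(site_ems, W = 0, ox_shift = 0,
                                  interaction_overrides = NULL) {
  ns <- length(site_ems)
  ox_shift <- rep_len(ox_shift, ns)
  frag <- rep(paste0("FE", seq_len(ns)), each = 2)
  state <- rep(c("red", "ox"), ns)
  info <- data.frame(
    conformer = paste0(frag, ".", state),
    fragment = frag, index = rep(1:2, ns), kind = "fe_ion",
    cluster = "TOY", m = 0,
    n = rep(c(1, 0), ns),
    pK_sol = 7, Em_sol = rep(site_ems, each = 2),
    charge_state = rep(c(2, 3), ns), stringsAsFactors = FALSE)
  M <- 2 * ns
  dG_rxn <- numeric(M)
  dG_rxn[seq(2, M, by = 2)] <- ox_shift
  pair <- matrix(0, M, M)
  if (!is.null(interaction_overrides)) {
    pair <- interaction_overrides
  } else if (ns > 1) {
    Wm <- if (is.matrix(W)) W else matrix(W, ns, ns)
    for (i in seq_len(ns - 1)) for (j in seq((i + 1), ns)) {
      pair[2 * i, 2 * j] <- pair[2 * j, 2 * i] <- Wm[i, j]
    }
  }
  new_energy_tables(info, dG_rxn, numeric(M), pair)
}

#' Random small titration system (for engine cross-checks)
#'
#' Random fragments with 1-4 conformers each, random reference chemistry
#' and a random symmetric pair matrix; used to exercise the Monte Carlo
#' engine against exact enumeration.
#'
#' @param n_frag number of fragments.
#' @param max_conf maximum conformers per fragment.
#' @param seed RNG seed.
#' @return an `energy_tables` object with at most 10 conformers.
#' @export
random_titration_system <- function(n_frag = 3, max_conf = 3, seed = 1) {
  with_local_seed(seed, {
    counts <- sample(seq_len(max_conf), n_frag, replace = TRUE)
    counts[1] <- max(counts[1], 2)
    while (sum(counts) > 10) counts[which.max(counts)] <-
        counts[which.max(counts)] - 1
    M <- sum(counts)
    frag <- rep(paste0("F", seq_len(n_frag)), counts)
    idx <- unlist(lapply(counts, seq_len))
    kindsel <- sample(c("redox", "acid", "fixed"), n_frag, replace = TRUE)
    n <- m <- numeric(M)
    for (f in seq_len(n_frag)) {
      rows <- which(frag == paste0("F", f))
      if (length(rows) < 2) next
      if (kindsel[f] == "redox") n[rows] <- c(1, numeric(length(rows) - 1))
      if (kindsel[f] == "acid") m[rows] <- c(-1, numeric(length(rows) - 1))
    }
    info <- data.frame(
      conformer = paste0(frag, ".", idx), fragment = frag, index = idx,
      kind = "residue_sidechain", cluster = NA_character_, m = m, n = n,
      pK_sol = round(stats::runif(M, 4, 10), 2),
      Em_sol = round(stats::runif(M, -400, 0), 0),
      charge_state = 0, stringsAsFactors = FALSE)
    pair <- matrix(stats::rnorm(M * M), M, M)
    pair <- round((pair + t(pair)) / 2, 3)
    diag(pair) <- 0
    new_energy_tables(info, round(stats::rnorm(M), 3),
                      round(stats::rnorm(M), 3), pair)
  })
}

#' Write a complete synthetic system to a directory
#'
#' Writes the toy structure as PDB, the charge configuration as YAML and
#' the analytic energy tables as TSV, so any stage of the pipeline can be
#' run from files.
#'
#' @param spec a [toy_system_spec()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_toy_system <- function(spec = toy_system_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- default_charge_config()
  model <- make_toy_cluster(spec, config)
  write_structure_pdb(model, file.path(dir, "toy.pdb"))
  write_charge_config(config, file.path(dir, "charges.yaml"))
  n_sites <- if (spec$n_fe == 4) 4 else 1
  tables <- make_titration_system(rep_len(spec$site_em_sol, n_sites))
  write_energy_tables(tables, file.path(dir, "toy"))
  invisible(dir)
}
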