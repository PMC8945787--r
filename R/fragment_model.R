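#' Parse a PDB structure into a multi-conformer fragment model
#'
#' Reads ATOM/HETATM records, drops crystallographic waters and dissolved
#' ions (they are represented by the continuum), assigns every remaining
#' atom to exactly one fragment according to the charge configuration, and
#' generates one conformer per ionization/redox state of each fragment.
#' Backbone atoms (zero conformational degrees of freedom) are kept apart
#' from the fragments and carry fixed partial charges.
#'
#' 4Fe-4S hetero groups (`SF4`, atom names `FE1`-`FE4`, `S1`-`S4`) are split
#' into four `fe_ion` fragments (formal charge +2 reduced / +3 oxidized) and
#' four `bridging_sulfur` fragments (formal charge -2), each a separate
#' titratable site.
#'
#' @param pdb PDB text (single string or character vector of lines) or a
#'   path to a PDB file.
#' @param config charge configuration (see [charge_config]); defaults to
#'   [default_charge_config()].
#' @return an object of class `structure_model`: a list with elements
#'   `fragments` (named list; each with `id`, `kind`, `cluster`, `atoms`,
#'   `allowed_charge_states`, `states`), `conformers` (list of `conformer`
#'   objects), and `backbone` (data frame of fixed atoms with charges).
#' @export
parse_structure <- function(pdb, config = default_charge_config()) {
  path <- pdb_as_file(pdb)
  p <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- p$atom
  if (anyDuplicated(at$eleno))
    stop("duplicate atom serial number(s): ",
         paste(unique(at$eleno[duplicated(at$eleno)]), collapse = ", "))
  solvent <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD", "H2O")
  ions <- c("NA", "CL", "K", "MG", "ZN", "MN", "CA", "BR", "IOD", "CS", "LI")
  drop <- at$resid %in% c(solvent, ions)
  at <- at[!drop, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after stripping solvent/ions")

  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)

  unknown <- setdiff(unique(atoms$resname), names(config$residues))
  if (length(unknown) > 0)
    stop("no charge configuration entry for residue type(s): ",
         paste(unknown, collapse = ", "))

  build_structure_model(atoms, config)
}

## Assemble a structure_model from a flat atom table + config.
build_structure_model <- function(atoms, config) {
  bb_names <- config$backbone$names
  bb_charges <- config$backbone$charges
  grp <- interaction(atoms$chain, atoms$resno, atoms$resname, drop = TRUE)
  fragments <- list()
  conformers <- list()
  backbone <- list()

  for (g in levels(grp)) {
    sub <- atoms[grp == g, , drop = FALSE]
    resname <- sub$resname[1]
    rc <- config$residues[[resname]]
    label <- paste0(sub$chain[1], sub$resno[1])

    if (isTRUE(rc$split)) {
      for (i in seq_len(nrow(sub))) {
        an <- sub$name[i]
        ac <- rc$atoms[[an]]
        if (is.null(ac))
          stop("atom ", an, " of split group ", resname, " ", label,
               " has no configuration entry")
        fid <- paste0(an, "_", label)
        adf <- sub[i, , drop = FALSE]
        adf$radius <- ac$radius %||% element_radius(an)
        adf$charge <- ac$charge %||% 0
        adf$lj_eps <- ac$lj_eps %||% config$defaults$lj_eps
        adf$lj_rmin <- ac$lj_rmin %||% (adf$radius)
        frag <- new_fragment(fid, ac$kind %||% "residue_sidechain", adf,
                             states = normalize_states(ac$states, adf),
                             cluster = paste0(resname, "_", label))
        fragments[[fid]] <- frag
        conformers <- c(conformers, make_state_conformers(frag))
      }
    } else {
      is_bb <- sub$name %in% bb_names
      bb <- sub[is_bb, , drop = FALSE]
      if (nrow(bb) > 0) {
        bb$radius <- vapply(bb$name, element_radius, numeric(1))
        bb$charge <- vapply(bb$name, function(n)
          as.numeric(bb_charges[[n]] %||% 0), numeric(1))
        bb$lj_eps <- config$defaults$lj_eps
        bb$lj_rmin <- bb$radius
        backbone[[length(backbone) + 1]] <- bb
      }
      sc <- sub[!is_bb, , drop = FALSE]
      if (nrow(sc) > 0) {
        sc$radius <- sc$charge <- numeric(nrow(sc))
        sc$lj_eps <- sc$lj_rmin <- numeric(nrow(sc))
        for (i in seq_len(nrow(sc))) {
          ac <- rc$atoms[[sc$name[i]]]
          sc$radius[i] <- ac$radius %||% element_radius(sc$name[i])
          sc$charge[i] <- ac$charge %||% 0
          sc$lj_eps[i] <- ac$lj_eps %||% config$defaults$lj_eps
          sc$lj_rmin[i] <- ac$lj_rmin %||% sc$radius[i]
        }
        fid <- paste0(resname, "_", label)
        frag <- new_fragment(fid, rc$kind %||% "residue_sidechain", sc,
                             states = normalize_states(rc$states, sc))
        fragments[[fid]] <- frag
        conformers <- c(conformers, make_state_conformers(frag))
      }
    }
  }

  backbone <- if (length(backbone) > 0) do.call(rbind, backbone) else
    empty_atom_frame()
  structure(list(fragments = fragments, conformers = conformers,
                 backbone = backbone, config = config),
            class = "structure_model")
}

new_fragment <- function(id, kind, atoms, states, cluster = NA_character_) {
  allowed <- vapply(states, function(s) s$charge_state, integer(1))
  if (kind == "fe_ion" && !all(allowed %in% c(2L, 3L)))
    stop(id, ": fe_ion charge states must lie in {+2, +3}")
  if (kind == "bridging_sulfur" && !all(allowed == -2L))
    stop(id, ": bridging_sulfur charge state must be -2")
  structure(list(id = id, kind = kind, cluster = cluster, atoms = atoms,
                 states = states, allowed_charge_states = allowed),
            class = "fragment")
}

## Fill state defaults; default single state = net base charge.
normalize_states <- function(states, atoms) {
  if (is.null(states))
    states <- list(list(charge_state = as.integer(round(sum(atoms$charge)))))
  lapply(states, function(s) {
    list(charge_state = as.integer(s$charge_state),
         m = as.integer(s$m %||% 0L), n = as.integer(s$n %||% 0L),
         pK_sol = as.numeric(s$pK_sol %||% 7),
         Em_sol = as.numeric(s$Em_sol %||% 0),
         charges = s$charges)
  })
}

make_state_conformers <- function(fragment, positions = NULL) {
  lapply(seq_along(fragment$states), function(i) {
    st <- fragment$states[[i]]
    atoms <- fragment$atoms
    if (!is.null(positions)) atoms[, c("x", "y", "z")] <- positions
    atoms$charge <- state_charges(fragment, st)
    if (st$m != 0 && st$n != 0)
      stop(fragment$id, ": a conformer cannot be both acid/base (m != 0) ",
           "and redox (n != 0)")
    structure(list(fragment_id = fragment$id, index = i, atoms = atoms,
                   m = st$m, n = st$n, pK_sol = st$pK_sol, Em_sol = st$Em_sol,
                   charge_state = st$charge_state),
              class = "conformer")
  })
}

## Per-atom charges for one state; guaranteed to sum exactly to the
## integer charge_state (any configuration rounding residual is spread
## uniformly).
state_charges <- function(fragment, state) {
  atoms <- fragment$atoms
  q <- atoms$charge
  if (!is.null(state$charges))
    for (an in names(state$charges))
      q[atoms$name == an] <- as.numeric(state$charges[[an]])
  if (nrow(atoms) == 1) q <- as.numeric(state$charge_state)
  resid <- state$charge_state - sum(q)
  if (abs(resid) > 0.01)
    stop(fragment$id, ": per-atom charges sum to ", round(sum(q), 4),
         " but state charge is ", state$charge_state)
  q + resid / length(q)
}

#' Assign formal per-atom charges to a fragment for a given state
#'
#' @param fragment a `fragment` from a [parse_structure()] model.
#' @param redox_state an integer charge state from the fragment's allowed
#'   set, or `"oxidized"`/`"reduced"` for `fe_ion` fragments (+3 / +2).
#' @return named numeric vector of per-atom charges summing exactly to the
#'   requested integer.
#' @export
assign_formal_charges <- function(fragment, redox_state) {
  if (is.character(redox_state)) {
    if (fragment$kind != "fe_ion")
      stop("named redox states apply only to fe_ion fragments")
    redox_state <- switch(match.arg(redox_state, c("oxidized", "reduced")),
                          oxidized = 3L, reduced = 2L)
  }
  redox_state <- as.integer(redox_state)
  hit <- which(vapply(fragment$states, function(s) s$charge_state,
                      integer(1)) == redox_state)
  if (length(hit) == 0)
    stop("state ", redox_state, " not in allowed charge states of ",
         fragment$id, " {", paste(fragment$allowed_charge_states,
                                  collapse = ", "), "}")
  q <- state_charges(fragment, fragment$states[[hit[1]]])
  setNames(q, fragment$atoms$name)
}

#' Add externally supplied alternate-position conformers
#'
#' Appends conformers at the new geometry, one per ionization state of the
#' fragment (the package generates ionization variants itself; rotamer
#' geometries are supplied by the caller).
#'
#' @param structure a `structure_model`.
#' @param fragment_id id of the fragment to extend.
#' @param positions numeric matrix (n_atoms x 3) of new coordinates, atom
#'   order as in the fragment.
#' @return the updated `structure_model`.
#' @export
add_conformers <- function(structure, fragment_id, positions) {
  frag <- structure$fragments[[fragment_id]]
  if (is.null(frag)) stop("unknown fragment id: ", fragment_id)
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(frag$atoms) || ncol(positions) != 3)
    stop("positions must be a ", nrow(frag$atoms), " x 3 matrix")
  existing <- sum(vapply(structure$conformers, function(cf)
    cf$fragment_id == fragment_id, logical(1)))
  new_cfs <- make_state_conformers(frag, positions)
  for (i in seq_along(new_cfs)) new_cfs[[i]]$index <- existing + i
  structure$conformers <- c(structure$conformers, new_cfs)
  structure
}

#' Discard conformers with unavoidable van der Waals clashes
#'
#' A conformer is discarded when one of its atoms overlaps (centre distance
#' below `r_i + r_j - overlap_tol`) a backbone atom, or overlaps every
#' remaining conformer of some other fragment (so no microstate could avoid
#' the clash).  Atom pairs already in contact in the input geometry of the
#' first conformers (covalent bonds, cluster Fe-S contacts, ligating SG-Fe
#' contacts) are treated as native contacts and never counted as clashes.
#' The filter is run to a fixed point, so it is idempotent; retained order
#' is stable.
#'
#' @param conformers list of `conformer` objects (defaults to the model's).
#' @param structure a `structure_model` providing backbone atoms.
#' @param overlap_tol allowed overlap, Angstrom (default 0.1).
#' @return the retained conformer list.
#' @export
clash_filter <- function(conformers, structure, overlap_tol = 0.1) {
  stopifnot(overlap_tol >= 0)
  if (length(conformers) == 0) return(conformers)
  bb <- structure$backbone
  frag_of <- vapply(conformers, function(cf) cf$fragment_id, character(1))
  frag_res <- function(fid) {
    a <- structure$fragments[[fid]]$atoms
    paste(a$chain[1], a$resno[1])
  }
  residue_of <- vapply(frag_of, frag_res, character(1))

  native <- native_contacts(structure, overlap_tol)

  clashes <- function(a1, a2) {
    if (nrow(a1) == 0 || nrow(a2) == 0) return(FALSE)
    d <- pair_dists(a1, a2)
    cut <- outer(a1$radius, a2$radius, "+") - overlap_tol
    bad <- d < cut
    if (any(bad)) bad[native_pairs(native, a1, a2)] <- FALSE
    any(bad)
  }

  keep <- rep(TRUE, length(conformers))
  repeat {
    changed <- FALSE
    for (i in seq_along(conformers)) {
      if (!keep[i]) next
      cf <- conformers[[i]]
      bb_other <- bb[!(paste(bb$chain, bb$resno) == residue_of[i]), ,
                     drop = FALSE]
      if (clashes(cf$atoms, bb_other)) {
        keep[i] <- FALSE; changed <- TRUE; next
      }
      for (fid in unique(frag_of)) {
        if (fid == cf$fragment_id) next
        js <- which(frag_of == fid & keep)
        if (length(js) == 0) next
        all_clash <- all(vapply(js, function(j)
          clashes(cf$atoms, conformers[[j]]$atoms), logical(1)))
        if (all_clash) { keep[i] <- FALSE; changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  conformers[keep]
}

## Atom-serial pairs that already overlap in the reference (first-conformer)
## geometry: covalent/native contacts exempt from clash testing.
native_contacts <- function(structure, overlap_tol) {
  ref <- reference_atoms(structure)
  if (nrow(ref) < 2) return(matrix(numeric(0), ncol = 2))
  d <- pair_dists(ref, ref)
  cut <- outer(ref$radius, ref$radius, "+") - overlap_tol
  bad <- which(d < cut, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  cbind(ref$serial[bad[, 1]], ref$serial[bad[, 2]])
}

native_pairs <- function(native, a1, a2) {
  if (nrow(native) == 0) return(matrix(FALSE, nrow(a1), nrow(a2)))
  key <- c(paste(native[, 1], native[, 2]), paste(native[, 2], native[, 1]))
  outer(a1$serial, a2$serial, function(s1, s2) paste(s1, s2) %in% key)
}

pair_dists <- function(a1, a2) {
  p1 <- as.matrix(a1[, c("x", "y", "z")])
  p2 <- as.matrix(a2[, c("x", "y", "z")])
  sqrt(pmax(outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * tcrossprod(p1, p2), 0))
}

empty_atom_frame <- function() {
  data.frame(serial = integer(0), name = character(0), resname = character(0),
             chain = character(0), resno = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0), radius = numeric(0),
             charge = numeric(0), lj_eps = numeric(0), lj_rmin = numeric(0),
             stringsAsFactors = FALSE)
}

#' Tabulate conformers of a structure model
#'
#' @param structure a `structure_model`.
#' @return data frame with one row per conformer: `conformer` (id),
#'   `fragment`, `index`, `kind`, `cluster`, `m`, `n`, `pK_sol`, `Em_sol`,
#'   `charge_state`.
#' @export
conformer_info <- function(structure) {
  cfs <- structure$conformers
  data.frame(
    conformer = vapply(cfs, function(cf)
      paste0(cf$fragment_id, ".", cf$index), character(1)),
    fragment = vapply(cfs, function(cf) cf$fragment_id, character(1)),
    index = vapply(cfs, function(cf) cf$index, numeric(1)),
    kind = vapply(cfs, function(cf)
      structure$fragments[[cf$fragment_id]]$kind, character(1)),
    cluster = vapply(cfs, function(cf)
      structure$fragments[[cf$fragment_id]]$cluster %||% NA_character_,
      character(1)),
    m = vapply(cfs, function(cf) as.numeric(cf$m), numeric(1)),
    n = vapply(cfs, function(cf) as.numeric(cf$n), numeric(1)),
    pK_sol = vapply(cfs, function(cf) cf$pK_sol, numeric(1)),
    Em_sol = vapply(cfs, function(cf) cf$Em_sol, numeric(1)),
    charge_state = vapply(cfs, function(cf)
      as.numeric(cf$charge_state), numeric(1)),
    stringsAsFactors = FALSE)
}

## All atoms in the reference geometry: backbone + first conformer of each
## fragment (defines the dielectric cavity).
reference_atoms <- function(structure) {
  first <- lapply(names(structure$fragments), function(fid) {
    for (cf in structure$conformers)
      if (cf$fragment_id == fid && cf$index == 1) return(cf$atoms)
    structure$fragments[[fid]]$atoms
  })
  rbind(structure$backbone, do.call(rbind, first))
}

#' Write a structure model to PDB
#'
#' Writes backbone plus the selected conformer of every fragment, ordered by
#' the original atom serials, through `bio3d::write.pdb()`.
#'
#' @param structure a `structure_model`.
#' @param file output path.
#' @param conformer which conformer index of each fragment to write.
#' @export
write_structure_pdb <- function(structure, file, conformer = 1) {
  frag_atoms <- lapply(structure$conformers, function(cf)
    if (cf$index == conformer) cf$atoms else NULL)
  all <- rbind(structure$backbone, do.call(rbind, frag_atoms))
  all <- all[order(all$serial), , drop = FALSE]
  het <- all$resname %in% names(structure$config$residues)[
    vapply(structure$config$residues, function(r) isTRUE(r$split), logical(1))]
  bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(
    all[, c("x", "y", "z")]))), type = ifelse(het, "HETATM", "ATOM"),
    resno = all$resno, resid = all$resname, eleno = all$serial,
    elety = all$name, chain = ifelse(all$chain == " ", "", all$chain),
    o = rep(1, nrow(all)), b = rep(0, nrow(all)))
  invisible(file)
}

pdb_as_file <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb, tf)
  tf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structure_model <- function(x, ...) {
  ci <- conformer_info(x)
  cat("structure_model:", length(x$fragments), "fragments,",
      nrow(ci), "conformers,", nrow(x$backbone), "backbone atoms\n")
  kinds <- table(vapply(x$fragments, function(f) f$kind, character(1)))
  cat("  fragments by kind:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
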