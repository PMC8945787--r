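#' Charge and titration configuration
#'
#' A charge configuration maps residue and hetero-group atom names to
#' partial charges, radii, Lennard-Jones parameters and titration reference
#' chemistry (`pK_sol`, `Em_sol`, the acid/base indicator `m` and the
#' electron count `n`).  Configurations are plain YAML with the layout
#'
#' ```yaml
#' defaults: {lj_eps: 0.05, lj_rmin: 2.0}
#' backbone:
#'   names: [N, H, CA, C, O, OXT, H1, H2, H3, HA]
#'   charges: {N: -0.40, H: 0.40, C: 0.55, O: -0.55}
#' residues:
#'   LYS:
#'     kind: residue_sidechain
#'     atoms: {NZ: {charge: 1.0, radius: 1.5}}
#'     states:
#'       - {charge_state: 1, m: 1, pK_sol: 10.4}
#'       - {charge_state: 0, m: 0, charges: {NZ: 0.0}}
#'   SF4:
#'     split: true
#'     atoms:
#'       FE1: {radius: 1.3, kind: fe_ion,
#'             states: [{charge_state: 2, n: 1, Em_sol: -170},
#'                      {charge_state: 3, n: 0, Em_sol: -170}]}
#'       S1:  {radius: 1.8, kind: bridging_sulfur,
#'             states: [{charge_state: -2}]}
#' ```
#'
#' `split: true` makes every atom of the group its own fragment (used for
#' the Fe ions and bridging sulfides of a 4Fe-4S cubane).  Per-state
#' `charges` override the base atom charges; single-atom fragments default
#' to carrying their full `charge_state` on the atom.  State fields default
#' to `m = 0`, `n = 0`, `pK_sol = 7`, `Em_sol = 0`.  Unlisted atoms fall
#' back to zero charge and an element-based radius.
#'
#' @param path file to read or write.
#' @return `default_charge_config()` and `read_charge_config()` return a
#'   validated configuration list.
#' @name charge_config
NULL

ELEMENT_RADII <- c(C = 1.7, N = 1.5, O = 1.4, S = 1.85, H = 1.0,
                   P = 1.85, FE = 1.3)

#' @rdname charge_config
#' @export
default_charge_config <- function() {
  fe_states <- list(
    list(charge_state = 2L, n = 1L, Em_sol = -170),   # reduced, electron-bearing
    list(charge_state = 3L, n = 0L, Em_sol = -170))   # oxidized
  s_states <- list(list(charge_state = -2L))
  sf4_atoms <- c(
    setNames(lapply(1:4, function(i) list(radius = 1.3, kind = "fe_ion",
                                          states = fe_states)),
             paste0("FE", 1:4)),
    setNames(lapply(1:4, function(i) list(radius = 1.8, kind = "bridging_sulfur",
                                          states = s_states)),
             paste0("S", 1:4)))
  neutral <- function() list(kind = "residue_sidechain",
                             states = list(list(charge_state = 0L)))
  cfg <- list(
    defaults = list(lj_eps = 0.05, lj_rmin = 2.0),
    backbone = list(
      names = c("N", "H", "HN", "CA", "C", "O", "OXT", "H1", "H2", "H3", "HA",
                "HA2", "HA3"),
      charges = list(N = -0.40, H = 0.40, HN = 0.40, C = 0.55, O = -0.55)),
    residues = list(
      GLY = neutral(), ALA = neutral(), VAL = neutral(), LEU = neutral(),
      ILE = neutral(), PRO = neutral(), MET = neutral(), PHE = neutral(),
      SER = neutral(), THR = neutral(), ASN = neutral(), GLN = neutral(),
      TRP = neutral(), TYR = neutral(),
      CYS = list(
        kind = "cysteine_ligand",
        atoms = list(SG = list(charge = -1.0, radius = 1.85)),
        # thiolate ligand: fixed -1, no titration in the cluster model
        states = list(list(charge_state = -1L),
                      list(charge_state = 0L, charges = list(SG = 0.0)))),
      LYS = list(
        kind = "residue_sidechain",
        atoms = list(NZ = list(charge = 1.0, radius = 1.5)),
        states = list(list(charge_state = 1L, m = 1L, pK_sol = 10.4),
                      list(charge_state = 0L, charges = list(NZ = 0.0)))),
      ARG = list(
        kind = "residue_sidechain",
        atoms = list(CZ = list(charge = 1.0, radius = 1.7)),
        states = list(list(charge_state = 1L, m = 1L, pK_sol = 12.0),
                      list(charge_state = 0L, charges = list(CZ = 0.0)))),
      HIS = list(
        kind = "residue_sidechain",
        atoms = list(ND1 = list(charge = 0.5, radius = 1.5),
                     NE2 = list(charge = 0.5, radius = 1.5)),
        states = list(list(charge_state = 1L, m = 1L, pK_sol = 6.5),
                      list(charge_state = 0L,
                           charges = list(ND1 = 0.0, NE2 = 0.0)))),
      ASP = list(
        kind = "residue_sidechain",
        atoms = list(OD1 = list(charge = -0.5, radius = 1.4),
                     OD2 = list(charge = -0.5, radius = 1.4)),
        states = list(list(charge_state = -1L, m = -1L, pK_sol = 4.75),
                      list(charge_state = 0L,
                           charges = list(OD1 = 0.0, OD2 = 0.0)))),
      GLU = list(
        kind = "residue_sidechain",
        atoms = list(OE1 = list(charge = -0.5, radius = 1.4),
                     OE2 = list(charge = -0.5, radius = 1.4)),
        states = list(list(charge_state = -1L, m = -1L, pK_sol = 4.35),
                      list(charge_state = 0L,
                           charges = list(OE1 = 0.0, OE2 = 0.0)))),
      SF4 = list(split = TRUE, atoms = sf4_atoms),
      FE = list(split = TRUE,
                atoms = list(FE = list(radius = 1.3, kind = "fe_ion",
                                       states = fe_states)))
    ))
  validate_charge_config(cfg)
}

#' @rdname charge_config
#' @export
read_charge_config <- function(path) {
  validate_charge_config(yaml::read_yaml(path))
}

#' @rdname charge_config
#' @param config a charge configuration list.
#' @export
write_charge_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_charge_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$residues))
  if (is.null(cfg$defaults)) cfg$defaults <- list()
  if (is.null(cfg$defaults$lj_eps)) cfg$defaults$lj_eps <- 0.05
  if (is.null(cfg$defaults$lj_rmin)) cfg$defaults$lj_rmin <- 2.0
  if (is.null(cfg$backbone))
    cfg$backbone <- list(names = character(), charges = list())
  kinds <- c("fe_ion", "bridging_sulfur", "cysteine_ligand",
             "residue_sidechain", "backbone")
  for (rn in names(cfg$residues)) {
    res <- cfg$residues[[rn]]
    if (isTRUE(res$split)) {
      for (an in names(res$atoms)) {
        a <- res$atoms[[an]]
        if (!is.null(a$kind) && !a$kind %in% kinds)
          stop("unknown fragment kind '", a$kind, "' for ", rn, ":", an)
        check_state_charges(a$states, a$kind, paste0(rn, ":", an))
      }
    } else {
      if (!is.null(res$kind) && !res$kind %in% kinds)
        stop("unknown fragment kind '", res$kind, "' for ", rn)
      check_state_charges(res$states, res$kind, rn)
    }
  }
  cfg
}

check_state_charges <- function(states, kind, label) {
  if (is.null(states)) return(invisible(NULL))
  cs <- vapply(states, function(s) as.integer(s$charge_state), integer(1))
  if (identical(kind, "fe_ion") && !all(cs %in% c(2L, 3L)))
    stop(label, ": fe_ion charge states must lie in {+2, +3}")
  if (identical(kind, "bridging_sulfur") && !all(cs == -2L))
    stop(label, ": bridging_sulfur charge state must be -2")
  invisible(NULL)
}

element_radius <- function(atom_name) {
  nm <- toupper(sub("^[0-9]*", "", atom_name))
  if (substr(nm, 1, 2) %in% names(ELEMENT_RADII))
    return(ELEMENT_RADII[[substr(nm, 1, 2)]])
  el <- substr(nm, 1, 1)
  if (el %in% names(ELEMENT_RADII)) ELEMENT_RADII[[el]] else 1.7
}
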