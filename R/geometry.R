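#' Bond-distance summary of a 4Fe-4S cluster
#'
#' Computes Fe-S (bridging sulfide), Fe-SG (cysteine thiolate) and Fe-Fe
#' distances of a cubane cluster: the 12 Fe-S bonds (each Fe to its three
#' nearest bridging sulfurs), the 4 Fe-SG bonds (nearest-Fe pairing) and
#' all 6 Fe-Fe pairs.  Distances are kept at full precision; rounding is
#' applied only when writing reports.
#'
#' @param structure a `structure_model`.
#' @param cluster_id cluster id as assigned by [parse_structure()] (e.g.
#'   `"SF4_A800"`) or by the toy generator.
#' @param sg_cutoff max SG-Fe distance for a cysteine to count as a ligand
#'   (Angstrom).
#' @return a `cluster_geometry`: data frames `fe_s`, `fe_sg`, `fe_fe` with
#'   columns (`a`, `b`, `distance`).
#' @export
cluster_distances <- function(structure, cluster_id, sg_cutoff = 3.0) {
  frs <- structure$fragments
  fe <- frs[vapply(frs, function(f)
    f$kind == "fe_ion" && identical(f$cluster, cluster_id), logical(1))]
  ss <- frs[vapply(frs, function(f)
    f$kind == "bridging_sulfur" && identical(f$cluster, cluster_id),
    logical(1))]
  if (length(fe) != 4 || length(ss) != 4)
    stop("cluster ", cluster_id, " must have 4 Fe and 4 bridging S; found ",
         length(fe), " Fe (", paste(names(fe), collapse = ", "), ") and ",
         length(ss), " S (", paste(names(ss), collapse = ", "), ")")
  fe_pos <- t(vapply(fe, function(f)
    as.numeric(f$atoms[1, c("x", "y", "z")]), numeric(3)))
  s_pos <- t(vapply(ss, function(f)
    as.numeric(f$atoms[1, c("x", "y", "z")]), numeric(3)))

  cys <- frs[vapply(frs, function(f) f$kind == "cysteine_ligand", logical(1))]
  sg <- do.call(rbind, lapply(cys, function(f) {
    a <- f$atoms[f$atoms$name == "SG", , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    data.frame(id = f$id, x = a$x[1], y = a$y[1], z = a$z[1])
  }))
  if (!is.null(sg)) {
    dmin <- apply(sg[, c("x", "y", "z")], 1, function(p)
      min(sqrt(colSums((t(fe_pos) - p)^2))))
    sg <- sg[dmin <= sg_cutoff, , drop = FALSE]
  }
  if (is.null(sg) || nrow(sg) != 4)
    stop("cluster ", cluster_id, " must have 4 ligating cysteine SG atoms ",
         "within ", sg_cutoff, " A; found ",
         if (is.null(sg)) 0 else nrow(sg))

  dmat <- function(p1, p2) sqrt(outer(rowSums(p1^2), rowSums(p2^2), "+") -
                                  2 * tcrossprod(p1, p2))
  d_fs <- dmat(fe_pos, s_pos)
  fe_s <- do.call(rbind, lapply(seq_len(4), function(i) {
    nb <- order(d_fs[i, ])[1:3]
    data.frame(a = names(fe)[i], b = names(ss)[nb], distance = d_fs[i, nb])
  }))
  sg_pos <- as.matrix(sg[, c("x", "y", "z")])
  d_fsg <- dmat(fe_pos, sg_pos)
  fe_sg <- do.call(rbind, lapply(seq_len(nrow(sg)), function(j) {
    i <- which.min(d_fsg[, j])
    data.frame(a = names(fe)[i], b = sg$id[j], distance = d_fsg[i, j])
  }))
  d_ff <- dmat(fe_pos, fe_pos)
  pr <- utils::combn(4, 2)
  fe_fe <- data.frame(a = names(fe)[pr[1, ]], b = names(fe)[pr[2, ]],
                      distance = d_ff[t(pr)])
  structure(list(cluster_id = cluster_id, fe_s = fe_s, fe_sg = fe_sg,
                 fe_fe = fe_fe), class = "cluster_geometry")
}

#' Ligand distances of the (second-)oxidized Fe site
#'
#' The three bridging-sulfur distances and the one cysteine-SG distance of
#' the given Fe site, and their arithmetic mean.  Which Fe is "the second
#' oxidized" is an input (from the titration ordering or the user);
#' geometry does not guess it.
#'
#' @param geometry a `cluster_geometry` from [cluster_distances()].
#' @param oxidized_fe fragment id of the oxidized Fe site.
#' @return list with `distances` (named, 4) and `avg`.
#' @export
ligand_distance_summary <- function(geometry, oxidized_fe) {
  fs <- geometry$fe_s[geometry$fe_s$a == oxidized_fe, ]
  fsg <- geometry$fe_sg[geometry$fe_sg$a == oxidized_fe, ]
  if (nrow(fs) == 0)
    stop("site ", oxidized_fe, " is not an Fe of cluster ",
         geometry$cluster_id)
  if (nrow(fsg) == 0)
    stop("site ", oxidized_fe, " has no paired cysteine SG")
  d <- c(setNames(fs$distance, fs$b), setNames(fsg$distance[1], fsg$b[1]))
  list(distances = d, avg = mean(d))
}

#' Write a bond-distance summary as TSV
#'
#' Distances rounded half-away-from-zero to 2 decimals, report style.
#'
#' @param geometry a `cluster_geometry`.
#' @param file output path.
#' @export
write_cluster_geometry <- function(geometry, file) {
  all <- rbind(cbind(bond = "Fe-S", geometry$fe_s),
               cbind(bond = "Fe-SG", geometry$fe_sg),
               cbind(bond = "Fe-Fe", geometry$fe_fe))
  all$distance <- round_half_away(all$distance, 2)
  write.table(all, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat("cluster_geometry for", x$cluster_id, "\n")
  cat("  Fe-S :", paste(round_half_away(sort(x$fe_s$distance), 2),
                        collapse = " "), "\n")
  cat("  Fe-SG:", paste(round_half_away(sort(x$fe_sg$distance), 2),
                        collapse = " "), "\n")
  cat("  Fe-Fe:", paste(round_half_away(sort(x$fe_fe$distance), 2),
                        collapse = " "), "\n")
  invisible(x)
}
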