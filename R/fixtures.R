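REFERENCE_MD5 <- c(
  psi_sulfur_interactions.tsv   = "ca0832377e5fc05881545388e5e37331",
  psi_cluster_em.tsv            = "c40822d7673eec6ecaa02cf31888eb27",
  psi_cluster_decomposition.tsv = "66ae69514d63e82c703547a642506407",
  psi_ligand_distances.tsv      = "58423569268ceda0e6143e07b094bbc4")

#' Bundled reference tables for the PS I iron-sulfur clusters
#'
#' Published reference values for the three 4Fe-4S clusters of
#' cyanobacterial photosystem I (F_X, F_A, F_B), transcribed once into
#' versioned data files and checksum-verified on load: calculated and
#' solution-reference midpoint potentials, the energy-term decomposition
#' of the Em shift, the ligand bond distances of the second-oxidized Fe,
#' and the per-bridging-sulfur x per-residue mean-field interaction
#' energies (blank cells are `NA`, meaning below the display threshold).
#' Used by worked examples and regression tests of the aggregation and
#' unit-conversion code paths.
#'
#' @return a list: `em` (data frame cluster/em_calc_mV/em_sol_mV),
#'   `decomposition` (term x cluster, kcal/mol), `ligand_distances`
#'   (per-cluster 4 bold distances + printed average, Angstrom),
#'   `sulfur_interactions` (long data frame with printed row totals), and
#'   `interaction_tables` (named list of `interaction_table` objects, one
#'   per cluster).
#' @export
load_reference_tables <- function() {
  dir <- system.file("extdata", package = "redoxmc")
  for (f in names(REFERENCE_MD5)) {
    path <- file.path(dir, f)
    got <- as.character(tools::md5sum(path))
    if (!identical(got, unname(REFERENCE_MD5[[f]])))
      stop("reference table ", f, " failed its checksum (", got, ")")
  }
  si <- read.delim(file.path(dir, "psi_sulfur_interactions.tsv"))
  tables <- lapply(c(FX = "FX", FA = "FA", FB = "FB"), function(cl) {
    sub <- si[si$cluster == cl, ]
    m <- as.matrix(sub[, c("S1", "S2", "S3", "S4")])
    rownames(m) <- paste(sub$restype, sub$residue)
    as_interaction_table(m)
  })
  list(em = read.delim(file.path(dir, "psi_cluster_em.tsv")),
       decomposition = read.delim(file.path(dir,
                                            "psi_cluster_decomposition.tsv")),
       ligand_distances = read.delim(file.path(dir,
                                               "psi_ligand_distances.tsv")),
       sulfur_interactions = si,
       interaction_tables = tables)
}
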