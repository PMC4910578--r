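## Curated experimental-structure sets.
##
## The package ships the curation as data: which deposited structures
## carry which ligand in which site class, and how the conformational
## ensemble partitions.  Expected classes and group memberships are used
## only as test expectations; every number is recomputed from
## coordinates at run time.

#' Curated ligand-site manifest
#'
#' One row per (accession, ligand occurrence): the deposited structures
#' in which each of the ten site classes is observed.  `het_code` is
#' given where unambiguous and `.` otherwise; `boldface` marks the
#' representative subset in which all ten classes occur.
#'
#' @return Data frame with columns `accession`, `ligand`, `het_code`,
#'   `expected_class`, `boldface`.
#' @export
curated_site_manifest <- function() {
  utils::read.table(
    system.file("extdata", "curated_set.tsv", package = "plgicmap"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
}

#' The conformational pentamer ensemble and its two-group partition
#'
#' Eleven anion-channel pentamer structures (GlyR, GluCl and the
#' GABA-A beta3 homopentamer) that separate into two conformational
#' groups: the agonist-bound-like conformations versus the
#' strychnine-bound GlyR and apo/POPC-bound GluCl conformations.
#'
#' @return Data frame with columns `accession` and `group`.
#' @export
published_conformational_set <- function() {
  data.frame(
    accession = c("3JAE", "3JAF", "3RIF", "3RHW", "3RIA", "3RI5", "4COF",
                  "3JAD", "5CFB", "4TNV", "4TNW"),
    group = c(rep(1L, 7L), rep(2L, 4L)),
    stringsAsFactors = FALSE
  )
}

#' Locate locally cached coordinate files for an accession list
#'
#' The package performs no downloads during analysis; deposited
#' structures must be fetched beforehand (e.g. with the command-line
#' `fetch` helper) into a cache directory holding `<accession>.pdb`
#' files.
#'
#' @param accessions Character vector of PDB accessions.
#' @param dir Cache directory (default: option `plgicmap.pdb_dir`, else
#'   `"pdb"` under the working directory).
#' @return Named character vector of paths (existing or not).
#' @export
pdb_cache_paths <- function(accessions,
                            dir = getOption("plgicmap.pdb_dir", "pdb")) {
  setNames(file.path(dir, paste0(tolower(accessions), ".pdb")), accessions)
}
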