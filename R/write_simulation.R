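#' Write a simulated two-species study to disk
#'
#' Materializes every artifact of a [simulate_dual_species()] run in
#' standard formats: expression TSVs (genes as rows), per-sample metadata
#' TSVs, GMT catalogs, the two-column homolog TSV, and a JSON truth sidecar
#' recording the planted programs and sample patterns.
#'
#' @param sim a `dual_species_simulation`.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dual_species_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression_a = file.path(dir, "expression_a.tsv"),
    expression_b = file.path(dir, "expression_b.tsv"),
    metadata_a = file.path(dir, "metadata_a.tsv"),
    metadata_b = file.path(dir, "metadata_b.tsv"),
    catalog_a = file.path(dir, "gene_sets_a.gmt"),
    catalog_b = file.path(dir, "gene_sets_b.gmt"),
    homology = file.path(dir, "homology.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(sim$profile_a, paths[["expression_a"]])
  write_expression(sim$profile_b, paths[["expression_b"]])
  utils::write.table(sim$profile_a$metadata, paths[["metadata_a"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$profile_b$metadata, paths[["metadata_b"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$catalogs$a, paths[["catalog_a"]])
  write_gmt(sim$catalogs$b, paths[["catalog_b"]])
  write_homology(sim$map, paths[["homology"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA,
                       auto_unbox = FALSE)
  invisible(paths)
}
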