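#' Bundled antimetabolite fixture set
#'
#' Loads the package's worked example: parent structures (as SMILES) for
#' the 17 antimetabolite drugs of the gold-standard set, their 15 enzyme
#' substrates, and the additional candidate drugs levoleucovorin and
#' vidarabine; the 27 curated antimetabolite-enzyme-substrate relations
#' with their reference similarity and p-value; the 11 enzyme-group records
#' with their substrate lists; and the bare (drug, enzyme) relation table
#' that feeds [select_gsp()]. Referential integrity is verified on load.
#'
#' The structures are parent (desalted, uncharged-where-possible) forms;
#' the reference similarity column carries the values reported for these
#' pairs so that recomputed scores can be compared against them.
#'
#' @return list of class `fixture_bundle` with elements `compounds` (a
#'   [compound_set()] of drugs and metabolites combined), `drugs`,
#'   `metabolites` (role subsets), `relations`, `enzymes`, `drug_enzyme`.
#' @export
load_fixture_bundle <- function() {
  path <- function(f) system.file("extdata", f, package = "metalike",
                                  mustWork = TRUE)
  tab <- utils::read.table(path("fixture_compounds.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  split <- split(tab, tab$role)
  drugs <- compound_set(split$drug$id, split$drug$smiles, role = "drug",
                        name = split$drug$name)
  mets <- compound_set(split$metabolite$id, split$metabolite$smiles,
                       role = "metabolite", name = split$metabolite$name)
  relations <- utils::read.table(path("gsp_relations.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE,
                                 quote = "", comment.char = "")
  enzymes <- read_enzyme_table(path("enzyme_substrates.tsv"))
  drug_enzyme <- read_drug_enzyme_table(path("drug_enzyme.tsv"))
  compounds <- rbind(drugs, mets)
  class(compounds) <- class(drugs)
  check_bundle(compounds, relations, enzymes, drug_enzyme)
  structure(list(compounds = compounds, drugs = drugs, metabolites = mets,
                 relations = relations, enzymes = enzymes,
                 drug_enzyme = drug_enzyme),
            class = "fixture_bundle")
}

check_bundle <- function(compounds, relations, enzymes, drug_enzyme) {
  bad <- setdiff(c(relations$drug_id, relations$substrate_id,
                   drug_enzyme$drug_id,
                   unlist(lapply(enzymes$substrate_ids, split_ids))),
                 compounds$id)
  if (length(bad))
    mlk_error(sprintf("fixture bundle has dangling compound ids: %s",
                      paste(unique(bad), collapse = ", ")),
              "metalike_corrupt_bundle")
  if (!setequal(relations$enzyme_label, enzymes$label))
    mlk_error("fixture enzymes and relations disagree on enzyme labels",
              "metalike_corrupt_bundle")
  if (any(compounds$failed))
    mlk_error("fixture bundle contains unparseable structures",
              "metalike_corrupt_bundle")
  invisible(TRUE)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  s <- gsp_summary(x$relations)
  cat(sprintf(paste0("<fixture_bundle> %d drugs + %d metabolites; ",
                     "%d relations (%d drugs, %d enzymes, %d substrates)\n"),
              nrow(x$drugs), nrow(x$metabolites), s$n_relations, s$n_drugs,
              s$n_enzymes, s$n_substrates))
  invisible(x)
}
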