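#' Read an enzyme-substrate table
#'
#' Tab-separated with header; columns `label` (enzyme or enzyme-group
#' display label, e.g. `"IMPDH1/2"`), `substrate_ids` (semicolon-separated
#' metabolite compound ids), and optionally `ec_numbers`,
#' `protein_accessions` and `excluded_cosubstrates` (ubiquitous
#' co-substrates such as water or cofactors, dropped upstream of any
#' selection). Excluded ids are removed from the substrate list on load so
#' the two sets never overlap.
#'
#' @param path file to read.
#' @return a data frame of class `enzyme_table`.
#' @export
read_enzyme_table <- function(path) {
  if (!file.exists(path))
    mlk_error(sprintf("no such file: %s", path), "metalike_missing_file")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("label", "substrate_ids") %in% names(tab)))
    mlk_error("enzyme table needs columns label and substrate_ids",
              "metalike_bad_table")
  for (opt in c("ec_numbers", "protein_accessions", "excluded_cosubstrates"))
    if (is.null(tab[[opt]])) tab[[opt]] <- ""
  tab$substrate_ids <- mapply(function(subs, excl) {
    paste(setdiff(split_ids(subs), split_ids(excl)), collapse = ";")
  }, tab$substrate_ids, tab$excluded_cosubstrates, USE.NAMES = FALSE)
  class(tab) <- c("enzyme_table", "data.frame")
  tab
}

#' Substrates of one enzyme label
#'
#' @param enzymes an `enzyme_table`.
#' @param label enzyme-group label to look up.
#' @return character vector of substrate compound ids (post exclusion).
#' @export
enzyme_substrates <- function(enzymes, label) {
  i <- match(label, enzymes$label)
  if (is.na(i))
    mlk_error(sprintf("unknown enzyme label '%s'", label),
              "metalike_unknown_id")
  split_ids(enzymes$substrate_ids[i])
}

#' Read a drug-enzyme relation table
#'
#' Tab-separated with header columns `drug_id` and `enzyme_label`; one row
#' per known (drug, enzyme) relation entering gold-standard selection.
#'
#' @param path file to read.
#' @return a data frame with columns `drug_id`, `enzyme_label`.
#' @export
read_drug_enzyme_table <- function(path) {
  if (!file.exists(path))
    mlk_error(sprintf("no such file: %s", path), "metalike_missing_file")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("drug_id", "enzyme_label") %in% names(tab)))
    mlk_error("relation table needs columns drug_id and enzyme_label",
              "metalike_bad_table")
  tab
}

#' Select the gold-standard positive (GSP) set
#'
#' For each known (drug, enzyme) relation the enzyme's substrate with the
#' highest Tanimoto similarity to the drug is chosen; the relation is kept
#' only when that similarity is strictly greater than `min_sim` (a drug far
#' from every substrate of its target plausibly acts by a different
#' mechanism than metabolite mimicry). A drug may map to several enzymes;
#' each (drug, enzyme) pair contributes at most one relation. Two substrates
#' tied at the maximum are both kept, with a warning.
#'
#' @param m a `sim_matrix` containing every referenced drug and substrate.
#' @param drug_enzyme data frame with columns `drug_id`, `enzyme_label`.
#' @param enzymes an `enzyme_table`.
#' @param min_sim strict similarity cutoff (default 0.5).
#' @return data frame of class `gsp_set` with columns `enzyme_label`,
#'   `substrate_id`, `drug_id`, `similarity`, sorted by enzyme label then
#'   descending similarity.
#' @export
select_gsp <- function(m, drug_enzyme, enzymes, min_sim = 0.5) {
  rows <- list()
  for (i in seq_len(nrow(drug_enzyme))) {
    drug <- drug_enzyme$drug_id[i]
    label <- drug_enzyme$enzyme_label[i]
    if (!drug %in% rownames(m))
      mlk_error(sprintf("drug '%s' not in similarity matrix", drug),
                "metalike_unknown_id")
    subs <- enzyme_substrates(enzymes, label)
    if (length(subs) == 0L) {
      warning(sprintf("enzyme '%s' has no substrates after exclusion; %s skipped",
                      label, drug), call. = FALSE)
      next
    }
    missing <- setdiff(subs, colnames(m))
    if (length(missing))
      mlk_error(sprintf("substrates of '%s' not in matrix: %s", label,
                        paste(missing, collapse = ", ")),
                "metalike_unknown_id")
    sims <- m[drug, subs]
    best <- sims == max(sims)
    if (sum(best) > 1L)
      warning(sprintf("substrate tie for %s at %s (%s); keeping all", drug,
                      label, paste(subs[best], collapse = ", ")),
              call. = FALSE)
    if (max(sims) > min_sim)
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme_label = label, substrate_id = subs[best],
                   drug_id = drug, similarity = unname(sims[best]),
                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme_label = character(0), substrate_id = character(0),
               drug_id = character(0), similarity = numeric(0))
  out <- out[order(out$enzyme_label, -out$similarity, out$drug_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsp_set", "data.frame")
  out
}

#' Distinct-entity counts of a GSP relation set
#'
#' @param relations a `gsp_set` or any data frame with columns `drug_id`,
#'   `enzyme_label`, `substrate_id`.
#' @return list with `n_drugs`, `n_enzymes`, `n_substrates`, `n_relations`.
#' @export
gsp_summary <- function(relations) {
  list(n_drugs = length(unique(relations$drug_id)),
       n_enzymes = length(unique(relations$enzyme_label)),
       n_substrates = length(unique(relations$substrate_id)),
       n_relations = nrow(relations))
}

#' @export
print.gsp_set <- function(x, ...) {
  s <- gsp_summary(x)
  cat(sprintf("<gsp_set> %d relations: %d drugs, %d enzymes, %d substrates\n",
              s$n_relations, s$n_drugs, s$n_enzymes, s$n_substrates))
  df <- as.data.frame(x)
  df$similarity <- round(df$similarity, 2)   # report precision
  print.data.frame(df, ...)
  invisible(x)
}
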