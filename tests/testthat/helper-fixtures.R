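# shared fixtures, computed once per test run

.cache <- new.env(parent = emptyenv())

fixture_pipeline <- function() {
  if (is.null(.cache$m)) {
    .cache$bundle <- load_fixture_bundle()
    .cache$m <- similarity_matrix(.cache$bundle$drugs,
                                  .cache$bundle$metabolites)
    .cache$gsp <- suppressWarnings(
      select_gsp(.cache$m, .cache$bundle$drug_enzyme, .cache$bundle$enzymes))
  }
  list(bundle = .cache$bundle, m = .cache$m, gsp = .cache$gsp)
}

# a similarity matrix with one high-similarity block planted in noise
planted_block_matrix <- function(n_drugs, n_mets, block_drugs, block_mets,
                                 seed = 42, high = c(0.8, 0.95),
                                 low = c(0, 0.2)) {
  set.seed(seed)
  m <- matrix(runif(n_drugs * n_mets, low[1], low[2]), n_drugs, n_mets,
              dimnames = list(paste0("d", seq_len(n_drugs)),
                              paste0("m", seq_len(n_mets))))
  m[seq_len(block_drugs), seq_len(block_mets)] <-
    runif(block_drugs * block_mets, high[1], high[2])
  structure(m, scheme = "synthetic", class = c("sim_matrix", class(m)))
}

# independent subtree enumeration through the dendrogram interface,
# used as the oracle for cluster-highlight detection
dendro_subtrees <- function(hc, labels) {
  out <- list()
  walk <- function(node) {
    if (!is.leaf(node)) {
      out[[length(out) + 1L]] <<- sort(labels[order.dendrogram(node)])
      walk(node[[1]]); walk(node[[2]])
    }
  }
  walk(stats::as.dendrogram(hc))
  out
}

# small labeled-score sets for calibration tests
labeled_df <- function(scores, labels) {
  data.frame(drug_id = paste0("d", seq_along(scores)),
             enzyme_label = "E", score = scores, label = labels,
             stringsAsFactors = FALSE)
}

write_tmp_smiles <- function(rows, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  sep <- if (ext == ".csv") "," else "\t"
  write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
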