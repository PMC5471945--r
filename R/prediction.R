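#' Enumerate repositioning candidates per enzyme
#'
#' For every enzyme of the gold-standard set, drugs whose maximum similarity
#' over the enzyme's GSP substrates reaches `threshold` (inclusive) are
#' proposed as modulator candidates, ranked by descending similarity.
#' Excluded are the enzyme's own GSP (antimetabolite) drugs and drugs
#' structurally identical to the substrate (the endogenous ligand:
#' similarity 1.0 or the same compound id). An enzyme whose only relation
#' at the threshold is its GSP one therefore yields no candidates.
#'
#' @param m a `sim_matrix`; its full drug set is the candidate universe.
#' @param gsp a `gsp_set` defining the enzymes, their GSP substrates and
#'   their GSP drugs.
#' @param threshold similarity cutoff in (0, 1), typically the
#'   Youden-optimal threshold from [youden_optimal()].
#' @return data frame of class `candidate_set` with columns `enzyme_label`,
#'   `substrate_id`, `drug_id`, `similarity`, `rank` (within enzyme);
#'   attribute `enzymes` lists every enzyme evaluated, including those with
#'   no candidates.
#' @export
predict_candidates <- function(m, gsp, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    mlk_error("threshold must lie in (0, 1)", "metalike_bad_input")
  labels <- unique(gsp$enzyme_label)
  out <- do.call(rbind, lapply(labels, function(lab) {
    subs <- unique(gsp$substrate_id[gsp$enzyme_label == lab])
    block <- m[, subs, drop = FALSE]
    best_j <- max.col(block, ties.method = "first")
    score <- block[cbind(seq_len(nrow(block)), best_j)]
    cand <- data.frame(enzyme_label = lab, substrate_id = subs[best_j],
                       drug_id = rownames(m), similarity = score,
                       stringsAsFactors = FALSE)
    keep <- cand$similarity >= threshold &
      !cand$drug_id %in% gsp$drug_id[gsp$enzyme_label == lab] &
      cand$similarity < 1 & cand$drug_id != cand$substrate_id
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(-cand$similarity, cand$drug_id), , drop = FALSE]
    if (nrow(cand)) cand$rank <- seq_len(nrow(cand))
    else cand$rank <- integer(0)
    cand
  }))
  rownames(out) <- NULL
  structure(out, enzymes = labels, threshold = threshold,
            class = c("candidate_set", "data.frame"))
}

#' One best candidate per enzyme
#'
#' Collapses a candidate set to the single highest-similarity proposal per
#' evaluated enzyme. Enzymes with no candidate are reported with dash
#' fields, mirroring the convention of printed candidate tables. A
#' similarity tie at the top is broken by ascending drug id, with a
#' warning.
#'
#' @param cands a `candidate_set` from [predict_candidates()].
#' @return data frame with one row per evaluated enzyme: `enzyme_label`,
#'   `substrate_id`, `drug_id`, `similarity` (`"-"` / `NA` when empty).
#' @export
top_candidate_report <- function(cands) {
  labels <- attr(cands, "enzymes") %||% unique(cands$enzyme_label)
  out <- do.call(rbind, lapply(labels, function(lab) {
    rows <- cands[cands$enzyme_label == lab, , drop = FALSE]
    if (nrow(rows) == 0L)
      return(data.frame(enzyme_label = lab, substrate_id = "-",
                        drug_id = "-", similarity = NA_real_,
                        stringsAsFactors = FALSE))
    top <- rows[rows$rank == 1L, , drop = FALSE]
    ties <- sum(rows$similarity == top$similarity[1])
    if (ties > 1L)
      warning(sprintf("top-candidate tie for %s; keeping %s (ascending drug id)",
                      lab, top$drug_id[1]), call. = FALSE)
    top[1, c("enzyme_label", "substrate_id", "drug_id", "similarity")]
  }))
  rownames(out) <- NULL
  out
}

#' Write a candidate table
#'
#' @param cands a `candidate_set` or top-candidate report.
#' @param path output file.
#' @param format `"tsv"` (full precision) or `"json"`.
#' @export
write_candidates <- function(cands, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(cands)
  if (format == "tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidates over %d enzymes (threshold %.3f)\n",
              nrow(x), length(attr(x, "enzymes")), attr(x, "threshold")))
  df <- as.data.frame(x)
  df$similarity <- round(df$similarity, 2)
  print.data.frame(df, ...)
  invisible(x)
}
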