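#' Similarity distribution of a metabolite over all drugs
#'
#' The significance of one drug-metabolite similarity is judged against the
#' distribution of that metabolite's similarity scores across the whole
#' drug collection (the metabolite's column of the similarity matrix,
#' including the query drug itself). The sample standard deviation (n - 1
#' denominator) is used.
#'
#' @param m a `sim_matrix`.
#' @param metabolite_id column to profile.
#' @param keep_scores retain the raw score vector in the result.
#' @return object of class `sim_dist` with `metabolite_id`, `n`, `mean`,
#'   `sd` and optionally `scores`.
#' @export
fit_similarity_distribution <- function(m, metabolite_id,
                                        keep_scores = FALSE) {
  if (!metabolite_id %in% colnames(m))
    mlk_error(sprintf("metabolite '%s' not in matrix", metabolite_id),
              "metalike_unknown_id")
  scores <- m[, metabolite_id]
  if (length(scores) < 2L)
    mlk_error("need at least 2 drugs to fit a distribution",
              "metalike_empty_input")
  s <- stats::sd(scores)
  if (s == 0)
    mlk_error(sprintf("degenerate (constant) similarity column for '%s'",
                      metabolite_id), "metalike_degenerate_distribution")
  structure(list(metabolite_id = metabolite_id, n = length(scores),
                 mean = mean(scores), sd = s,
                 scores = if (keep_scores) scores),
            class = "sim_dist")
}

#' Standardized score and upper-tail p-value of a similarity
#'
#' `z = (score - mean) / sd`; the p-value is the one-sided upper-tail
#' probability. `mode = "normal"` (the default) evaluates the standard
#' normal tail at z; `mode = "empirical"` is the observed fraction of drugs
#' scoring at least as high, and needs the distribution fitted with
#' `keep_scores = TRUE`. The empirical mode is floor-limited to 1/n and so
#' cannot produce the very small tail probabilities a normal tail can.
#'
#' @param d a `sim_dist`.
#' @param score similarity score to test.
#' @param mode `"normal"` or `"empirical"`.
#' @return list with elements `z` and `p`.
#' @export
zscore_pvalue <- function(d, score, mode = c("normal", "empirical")) {
  mode <- match.arg(mode)
  z <- (score - d$mean) / d$sd
  p <- switch(mode,
    normal = stats::pnorm(z, lower.tail = FALSE),
    empirical = {
      if (is.null(d$scores))
        mlk_error("empirical mode needs a distribution fitted with keep_scores = TRUE",
                  "metalike_bad_input")
      mean(d$scores >= score)
    })
  list(z = z, p = p)
}

#' Significance table for a set of relations
#'
#' Evaluates each (drug, substrate) pair of a GSP relation set against the
#' substrate's similarity distribution over all drugs in the matrix.
#'
#' @param m a `sim_matrix` (its full drug set defines the distributions).
#' @param relations data frame with columns `drug_id`, `substrate_id`.
#' @param mode passed to [zscore_pvalue()].
#' @return data frame with columns `drug_id`, `metabolite_id`,
#'   `similarity`, `z`, `p`.
#' @export
significance_table <- function(m, relations, mode = "normal") {
  dists <- lapply(stats::setNames(nm = unique(relations$substrate_id)),
                  function(s)
                    fit_similarity_distribution(m, s,
                                                keep_scores = mode == "empirical"))
  out <- do.call(rbind, lapply(seq_len(nrow(relations)), function(i) {
    drug <- relations$drug_id[i]; sub <- relations$substrate_id[i]
    zp <- zscore_pvalue(dists[[sub]], m[drug, sub], mode = mode)
    data.frame(drug_id = drug, metabolite_id = sub,
               similarity = m[drug, sub], z = zp$z, p = zp$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a significance report
#'
#' Tab-separated; p-values in scientific notation, similarities at full
#' precision.
#'
#' @param x output of [significance_table()].
#' @param path output file.
#' @export
write_significance <- function(x, path) {
  x$p <- format(x$p, scientific = TRUE, digits = 3)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
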