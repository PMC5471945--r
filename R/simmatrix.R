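#' Drug-by-metabolite similarity matrix
#'
#' Computes the complete rectangle of pairwise Tanimoto scores between a
#' drug set and a metabolite set under a common fingerprint scheme. Members
#' that cannot be fingerprinted are excluded with a logged warning, and the
#' matrix dimensions reflect the exclusions. The result is deterministic for
#' fixed inputs.
#'
#' @param drugs,metabolites [compound_set()] objects, or fingerprint
#'   matrices (`maccs_fp` or any 0/1 matrix with row names) already computed
#'   e.g. by [generate_fingerprint_universe()].
#' @return a numeric matrix of class `sim_matrix` (rows = drugs, columns =
#'   metabolites, values in \[0, 1\]) with a `scheme` attribute.
#' @export
similarity_matrix <- function(drugs, metabolites) {
  fd <- as_fp(drugs, "drug")
  fm <- as_fp(metabolites, "metabolite")
  m <- tanimoto(fd, fm)
  structure(m, scheme = attr(fd, "scheme") %||% "user",
            class = c("sim_matrix", class(m)))
}

as_fp <- function(x, what) {
  if (inherits(x, "compound_set")) {
    if (nrow(x) == 0L)
      mlk_error(sprintf("empty %s set", what), "metalike_empty_input")
    if (any(x$failed))
      warning(sprintf("excluding %d unparseable %ss: %s", sum(x$failed),
                      what, paste(x$id[x$failed], collapse = ", ")),
              call. = FALSE)
    return(maccs_fingerprint(x))
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      mlk_error("fingerprint matrices need compound ids as row names",
                "metalike_bad_id")
    return(x)
  }
  mlk_error(sprintf("cannot interpret %s input of class %s", what,
                    paste(class(x), collapse = "/")), "metalike_bad_input")
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix> %d drugs x %d metabolites (scheme %s)\n",
              nrow(x), ncol(x), attr(x, "scheme")))
  cat(sprintf("  Tc range [%.3f, %.3f], %.1f%% of cells >= 0.7\n",
              min(x), max(x), 100 * mean(x >= 0.7)))
  invisible(x)
}

#' Write / read a similarity matrix
#'
#' `"wide"` is drugs as rows and metabolites as columns; `"long"` has one
#' `(drug_id, metabolite_id, tc)` row per cell. Both round-trip at full
#' precision through [read_matrix()].
#'
#' @param m a `sim_matrix`.
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @export
write_matrix <- function(m, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(drug_id = rownames(m),
                     format(as.data.frame(unclass(m)), digits = 17,
                            scientific = FALSE, trim = TRUE),
                     check.names = FALSE)
  } else {
    df <- data.frame(drug_id = rep(rownames(m), times = ncol(m)),
                     metabolite_id = rep(colnames(m), each = nrow(m)),
                     tc = format(as.vector(m), digits = 17, trim = TRUE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (format == "wide") {
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  } else {
    drugs <- unique(tab$drug_id); mets <- unique(tab$metabolite_id)
    m <- matrix(NA_real_, length(drugs), length(mets),
                dimnames = list(drugs, mets))
    m[cbind(tab$drug_id, tab$metabolite_id)] <- tab$tc
  }
  structure(m, scheme = "file", class = c("sim_matrix", class(m)))
}

#' Detect high-similarity cluster blocks in a similarity matrix
#'
#' Rows and columns are clustered hierarchically (complete linkage) on a
#' correlation distance between similarity profiles; every (row-subtree,
#' column-subtree) pair of the two dendrograms is then audited against three
#' criteria: more than `min_drugs` drugs, more than `min_metabolites`
#' metabolites, and at least `min_frac` of the block's cells at Tanimoto
#' `high_tc` or higher. Qualifying pairs nested inside a larger qualifying
#' pair are suppressed, so each reported highlight is maximal.
#'
#' @param m a `sim_matrix`.
#' @param min_drugs,min_metabolites strict lower bounds on block dimensions.
#' @param high_tc similarity level that counts as a high-similarity cell.
#' @param min_frac minimum fraction of high cells in the block.
#' @param distance `"pearson"` (1 - correlation of similarity profiles,
#'   the heat-map default) or `"cosine"` (1 - cosine of the profiles).
#' @return a list of `cluster_highlight` records, largest block first, each
#'   with `drug_members`, `metabolite_members` and `frac_high`; an empty
#'   list when the matrix is smaller than the thresholds.
#' @export
find_highlight_clusters <- function(m, min_drugs = 50, min_metabolites = 100,
                                    high_tc = 0.7, min_frac = 0.3,
                                    distance = c("pearson", "cosine")) {
  distance <- match.arg(distance)
  if (nrow(m) <= min_drugs || ncol(m) <= min_metabolites) return(list())
  row_sets <- subtree_sets(profile_hclust(m, distance), rownames(m))
  col_sets <- subtree_sets(profile_hclust(t(m), distance), colnames(m))
  row_sets <- Filter(function(s) length(s) > min_drugs, row_sets)
  col_sets <- Filter(function(s) length(s) > min_metabolites, col_sets)
  hits <- list()
  for (rs in row_sets) for (cs in col_sets) {
    frac <- mean(m[rs, cs] >= high_tc)
    if (frac >= min_frac)
      hits[[length(hits) + 1L]] <-
        structure(list(drug_members = rs, metabolite_members = cs,
                       frac_high = frac), class = "cluster_highlight")
  }
  keep_maximal(hits)
}

profile_hclust <- function(m, distance) {
  d <- switch(distance,
    pearson = 1 - suppressWarnings(stats::cor(t(m))),
    cosine  = {
      nrm <- sqrt(rowSums(m^2)); nrm[nrm == 0] <- 1
      1 - (m %*% t(m)) / outer(nrm, nrm)
    })
  d[!is.finite(d)] <- 1   # constant profiles have no defined correlation
  stats::hclust(stats::as.dist(d), method = "complete")
}

# leaf-label sets of every internal node of an hclust tree
subtree_sets <- function(hc, labels) {
  n <- length(labels)
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    members[[k]] <- c(
      if (kids[1] < 0) -kids[1] else members[[kids[1]]],
      if (kids[2] < 0) -kids[2] else members[[kids[2]]])
  }
  lapply(members, function(ix) labels[sort(ix)])
}

keep_maximal <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  nested <- vapply(seq_along(hits), function(i) {
    any(vapply(seq_along(hits), function(j) {
      i != j &&
        all(hits[[i]]$drug_members %in% hits[[j]]$drug_members) &&
        all(hits[[i]]$metabolite_members %in% hits[[j]]$metabolite_members) &&
        (length(hits[[j]]$drug_members) > length(hits[[i]]$drug_members) ||
         length(hits[[j]]$metabolite_members) >
           length(hits[[i]]$metabolite_members))
    }, logical(1)))
  }, logical(1))
  hits <- hits[!nested]
  sizes <- vapply(hits, function(h)
    length(h$drug_members) * length(h$metabolite_members), numeric(1))
  hits[order(sizes, decreasing = TRUE)]
}

#' @export
print.cluster_highlight <- function(x, ...) {
  cat(sprintf("<cluster_highlight> %d drugs x %d metabolites, %.1f%% cells high\n",
              length(x$drug_members), length(x$metabolite_members),
              100 * x$frac_high))
  invisible(x)
}
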