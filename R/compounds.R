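#' Compound sets
#'
#' A compound set is a data frame with one row per compound and columns
#' `id`, `name`, `role` (`"drug"` or `"metabolite"`), `smiles` and `failed`.
#' Records whose structure cannot be interpreted are kept, flagged
#' `failed = TRUE`, and excluded from fingerprinting; they are never silently
#' dropped.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param smiles SMILES line notation, one per compound.
#' @param role `"drug"` or `"metabolite"`.
#' @param name display names; defaults to `id`.
#' @param strip_salts drop counter-ions by keeping the largest organic
#'   fragment of each dot-disconnected SMILES. Database records frequently
#'   carry salts, and similarity values on parent structures are what
#'   reference tables report. Set `FALSE` to fingerprint the record as given.
#' @return an object of class `compound_set` (a data frame).
#' @export
compound_set <- function(id, smiles, role = c("drug", "metabolite"),
                         name = id, strip_salts = TRUE) {
  role <- match.arg(role)
  id <- as.character(id)
  if (any(!nzchar(id)) || anyNA(id))
    mlk_error("compound ids must be non-empty", "metalike_bad_id")
  if (anyDuplicated(id))
    mlk_error(sprintf("duplicate compound ids: %s",
                      paste(unique(id[duplicated(id)]), collapse = ", ")),
              "metalike_bad_id")
  smiles <- as.character(smiles)
  if (strip_salts) smiles <- vapply(smiles, largest_fragment, character(1))
  failed <- !vapply(smiles, smiles_parses, logical(1))
  if (any(failed))
    mlk_log("%d of %d records failed to parse: %s", sum(failed), length(id),
            paste(id[failed], collapse = ", "))
  out <- data.frame(id = id, name = as.character(name), role = role,
                    smiles = smiles, failed = failed,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("compound_set", "data.frame")
  out
}

# does OpenBabel accept this SMILES and produce at least one atom?
smiles_parses <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  ok <- try(suppressWarnings(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "MACCS")),
    silent = TRUE)
  !inherits(ok, "try-error") && is.numeric(ok) && length(ok) > 0
}

#' Read compounds from an SDF file or a delimited SMILES table
#'
#' SMILES tables need a header with at least `id` and `smiles` columns
#' (`name` optional); the separator is a comma for `.csv`, otherwise a tab.
#' SDF records are converted to SMILES with OpenBabel before fingerprinting.
#' Unparseable records are counted, logged and flagged; input order is kept.
#'
#' @param path file to read.
#' @param format `"auto"` resolves `.sdf` to SDF and anything else to a
#'   SMILES table.
#' @param role role assigned to every compound in the file.
#' @param strip_salts see [compound_set()].
#' @return a [compound_set()].
#' @export
read_compounds <- function(path, format = c("auto", "sdf", "smiles_table"),
                           role = c("drug", "metabolite"),
                           strip_salts = TRUE) {
  format <- match.arg(format)
  role <- match.arg(role)
  if (!file.exists(path))
    mlk_error(sprintf("no such file: %s", path), "metalike_missing_file")
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles_table"
  tab <- if (format == "sdf") read_sdf_table(path) else read_smiles_table(path)
  cs <- compound_set(tab$id, tab$smiles, role = role, name = tab$name,
                     strip_salts = strip_salts)
  if (all(cs$failed))
    mlk_error(sprintf("no parseable records in %s (%d failures)",
                      path, sum(cs$failed)), "metalike_empty_input")
  cs
}

read_smiles_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("id", "smiles")
  if (!all(need %in% names(tab)))
    mlk_error(sprintf("%s must have columns id and smiles", path),
              "metalike_bad_table")
  if (is.null(tab$name)) tab$name <- tab$id
  tab[, c("id", "name", "smiles")]
}

read_sdf_table <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  ids[!nzchar(ids) | is.na(ids)] <-
    paste0("mol", which(!nzchar(ids) | is.na(ids)))
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  smiles <- rep(NA_character_, length(sdf))
  if (any(ok)) {
    smi <- try(ChemmineR::sdf2smiles(sdf[ok]), silent = TRUE)
    if (!inherits(smi, "try-error"))
      smiles[ok] <- as.character(smi)
  }
  smiles[is.na(smiles)] <- ""   # flagged as failed downstream
  data.frame(id = ids, name = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d %ss (%d failed to parse)\n",
              nrow(x), x$role[1] %||% "compound", sum(x$failed)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
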