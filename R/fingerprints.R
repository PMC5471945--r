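#' MACCS substructure fingerprints
#'
#' Encodes molecules as presence/absence bits over the 166 public MACCS
#' substructure keys (computed with OpenBabel via ChemmineOB and trimmed to
#' the 166 meaningful key positions). Fingerprinting is deterministic: the
#' same structure always yields the same bits.
#'
#' @param x a [compound_set()] or a named character vector of SMILES.
#' @param ... unused.
#' @return an integer 0/1 matrix of class `maccs_fp`, one row per compound,
#'   166 columns, with a `scheme` attribute.
#' @export
maccs_fingerprint <- function(x, ...) UseMethod("maccs_fingerprint")

MACCS_NBITS <- 166L

#' @export
maccs_fingerprint.character <- function(x, ...) {
  ids <- names(x) %||% as.character(seq_along(x))
  bits <- matrix(0L, nrow = length(x), ncol = MACCS_NBITS,
                 dimnames = list(ids, NULL))
  for (i in seq_along(x)) bits[i, ] <- fingerprint_one(x[[i]], ids[[i]])
  structure(bits, scheme = "maccs166", class = c("maccs_fp", class(bits)))
}

#' @export
maccs_fingerprint.compound_set <- function(x, ...) {
  usable <- x[!x$failed, , drop = FALSE]
  if (nrow(usable) == 0L)
    mlk_error("no fingerprintable compounds in set", "metalike_empty_input")
  maccs_fingerprint(stats::setNames(usable$smiles, usable$id))
}

fingerprint_one <- function(smiles, id) {
  fp <- try(suppressWarnings(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "MACCS")),
    silent = TRUE)
  if (inherits(fp, "try-error") || !is.numeric(fp) || length(fp) < MACCS_NBITS)
    mlk_error(sprintf("cannot fingerprint compound '%s'", id),
              "metalike_parse_error")
  as.integer(fp[seq_len(MACCS_NBITS)] != 0)
}

#' Number of set bits in a fingerprint
#'
#' The quantities A and B of the Tanimoto formula.
#'
#' @param fp a `maccs_fp` matrix or a single 0/1 vector.
#' @return integer vector of popcounts.
#' @export
n_on <- function(fp) {
  if (is.matrix(fp)) rowSums(fp != 0) else sum(fp != 0)
}

#' Tanimoto similarity between binary fingerprints
#'
#' `T_c(A, B) = C / (A + B - C)` with A and B the set-bit counts of the two
#' fingerprints and C the count of shared bits; equal to the Jaccard index
#' on the bit sets, and bounded in \[0, 1\]. A pair of all-zero fingerprints
#' has identical (empty) feature sets; that degenerate case is defined as
#' similarity 1 and flagged with a warning.
#'
#' @param fa,fb fingerprints of the same scheme/length: 0/1 vectors for a
#'   single pair, or matrices (rows = compounds) for all pairwise scores.
#' @return a scalar for vector input, else a `nrow(fa) x nrow(fb)` matrix.
#' @export
tanimoto <- function(fa, fb) {
  if (!is.matrix(fa) && !is.matrix(fb)) {
    check_same_scheme(length(fa), length(fb))
    a <- sum(fa != 0); b <- sum(fb != 0); c <- sum(fa != 0 & fb != 0)
    if (a + b == 0L) {
      warning("Tanimoto of two empty fingerprints defined as 1",
              call. = FALSE)
      return(1)
    }
    return(c / (a + b - c))
  }
  fa <- rbind(fa); fb <- rbind(fb)
  check_same_scheme(ncol(fa), ncol(fb))
  fa <- (fa != 0) + 0L; fb <- (fb != 0) + 0L
  cc <- fa %*% t(fb)
  denom <- outer(rowSums(fa), rowSums(fb), "+") - cc
  if (any(denom == 0)) {
    warning("Tanimoto of two empty fingerprints defined as 1", call. = FALSE)
    cc[denom == 0] <- 1; denom[denom == 0] <- 1
  }
  cc / denom
}

check_same_scheme <- function(na, nb) {
  if (na != nb)
    mlk_error(sprintf("fingerprint schemes differ (%d vs %d bits)", na, nb),
              "metalike_scheme_error")
}

#' Export fingerprints as a delimited table of hex-encoded bit strings
#'
#' @param fp a `maccs_fp` matrix.
#' @param path output file (tab-separated, columns `id` and `fp_hex`).
#' @export
write_fingerprints <- function(fp, path) {
  hex <- apply(fp, 1, function(bits) {
    pad <- c(as.integer(bits), rep(0L, (4 - length(bits) %% 4) %% 4))
    nib <- matrix(pad, nrow = 4)
    paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
  })
  utils::write.table(data.frame(id = rownames(fp), fp_hex = hex),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
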