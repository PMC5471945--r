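# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# typed conditions so callers can distinguish failure modes
mlk_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "metalike_error"), call = call))
}

mlk_log <- function(...) message("[metalike] ", sprintf(...))

# semicolon-separated list cells used in the enzyme / fixture tables
split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

# crude heavy-atom count for salt stripping: each bracket atom, two-letter
# organic-subset halogen, or aromatic/aliphatic organic symbol counts once
heavy_atom_count <- function(smiles) {
  pat <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]"
  hits <- gregexpr(pat, smiles)[[1]]
  if (hits[1] == -1L) return(0L)
  frags <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  sum(!grepl("^\\[H", frags))
}

# largest organic fragment of a dot-disconnected SMILES (counter-ion removal)
largest_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) <= 1L) return(smiles)
  frags[which.max(vapply(frags, heavy_atom_count, integer(1)))]
}
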