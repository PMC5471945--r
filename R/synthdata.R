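#' Configuration for a synthetic fingerprint universe
#'
#' Describes a simulated drug/metabolite fingerprint collection: background
#' fingerprints are independent Bernoulli(`bit_density`) bit vectors, and
#' selected (drug, metabolite) pairs are planted at a target Tanimoto
#' similarity. Fixing `seed` makes the generated universe bit-identical
#' across runs.
#'
#' @param n_drugs,n_metabolites collection sizes.
#' @param fp_length fingerprint length in bits (166 matches the MACCS key
#'   set used on real structures).
#' @param bit_density probability that a background bit is set. 0.2 is a
#'   realistic MACCS density for drug-like molecules (~33 of 166 keys on)
#'   and gives a background Tanimoto of about `p/(2-p)` = 0.11 between
#'   unrelated compounds.
#' @param planted_pairs data frame with columns `drug`, `metabolite`
#'   (indices) and `target` (desired expected Tanimoto), or NULL.
#' @param noise extra symmetric bit-flip rate applied to every drug
#'   fingerprint after planting.
#' @param seed RNG seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs, n_metabolites, fp_length = 166,
                             bit_density = 0.2, planted_pairs = NULL,
                             noise = 0, seed = 1) {
  stopifnot(n_drugs >= 1, n_metabolites >= 1, fp_length >= 1)
  if (bit_density < 0 || bit_density > 1 || noise < 0 || noise > 1)
    mlk_error("bit_density and noise must lie in [0, 1]",
              "metalike_bad_input")
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("drug", "metabolite", "target") %in%
                    names(planted_pairs)))
    if (any(planted_pairs$target < 0 | planted_pairs$target > 1))
      mlk_error("planted target similarities must lie in [0, 1]",
                "metalike_bad_input")
  }
  structure(list(n_drugs = n_drugs, n_metabolites = n_metabolites,
                 fp_length = fp_length, bit_density = bit_density,
                 planted_pairs = planted_pairs, noise = noise, seed = seed),
            class = "synthetic_config")
}

#' Expected Tanimoto between two independent Bernoulli(p) fingerprints
#'
#' With expected intersection `L p^2` and expected union `L p (2 - p)`, the
#' background similarity concentrates around `p / (2 - p)` for long
#' fingerprints.
#'
#' @param p bit density.
#' @return expected background similarity.
#' @export
expected_background_tanimoto <- function(p) p / (2 - p)

#' Generate a synthetic fingerprint universe
#'
#' Background fingerprints are independent Bernoulli(`bit_density`) bit
#' vectors. Each planted pair's drug fingerprint is derived from its
#' metabolite fingerprint by flipping ON bits off at rate
#' `q = (1 - t) / (1 + t)` and OFF bits on at rate `q * A / (L - A)` (A =
#' set bits, L = length), which keeps the expected popcount at A and makes
#' the expected Tanimoto approximately `(1 - q) / (1 + q) = t`, the target
#' similarity. A target of 1 copies the fingerprint exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `fp_universe`: `drug_fps` and `metabolite_fps`
#'   (0/1 matrices with ids `d1..dn` / `m1..mn`) and `truth` (the planted
#'   pairs with ids attached).
#' @export
generate_fingerprint_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  L <- cfg$fp_length
  draw <- function(n) matrix(stats::rbinom(n * L, 1L, cfg$bit_density),
                             nrow = n, ncol = L)
  mets <- draw(cfg$n_metabolites)
  drugs <- draw(cfg$n_drugs)
  rownames(mets) <- paste0("m", seq_len(cfg$n_metabolites))
  rownames(drugs) <- paste0("d", seq_len(cfg$n_drugs))
  truth <- cfg$planted_pairs
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      t_sim <- truth$target[i]
      src <- mets[truth$metabolite[i], ]
      if (t_sim >= 1) {
        drugs[truth$drug[i], ] <- src
        next
      }
      q <- (1 - t_sim) / (1 + t_sim)
      a <- sum(src)
      q_on <- if (a == 0) 0 else q * a / (L - a)
      if (q_on > 1)
        mlk_error(sprintf("target similarity %.2f infeasible at density %.2f",
                          t_sim, cfg$bit_density),
                  "metalike_infeasible_target")
      flip_off <- src == 1 & stats::runif(L) < q
      flip_on <- src == 0 & stats::runif(L) < q_on
      drugs[truth$drug[i], ] <- as.integer(xor(src, flip_off | flip_on))
    }
    truth$drug_id <- rownames(drugs)[truth$drug]
    truth$metabolite_id <- rownames(mets)[truth$metabolite]
  }
  if (cfg$noise > 0) {
    flips <- matrix(stats::runif(length(drugs)) < cfg$noise, nrow(drugs))
    drugs <- (drugs != flips) + 0L
  }
  structure(list(drug_fps = drugs, metabolite_fps = mets, truth = truth,
                 config = cfg),
            class = "fp_universe")
}

#' @export
print.fp_universe <- function(x, ...) {
  cat(sprintf("<fp_universe> %d drugs x %d metabolites, %d bits, density %.2f, %d planted pairs (seed %d)\n",
              nrow(x$drug_fps), nrow(x$metabolite_fps), x$config$fp_length,
              x$config$bit_density,
              if (is.null(x$truth)) 0L else nrow(x$truth), x$config$seed))
  invisible(x)
}
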