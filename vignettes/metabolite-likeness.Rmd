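---
title: "Metabolite-likeness screening: model, calibration and design notes"
author: "metalike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-likeness screening: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalike)
```

## The model

`metalike` operationalizes a simple pharmacological idea: a drug that is
structurally close to an endogenous substrate of an enzyme is a plausible
modulator of that enzyme. The antimetabolite drug class — nucleoside
analogues, antifolates, purine analogues — exists precisely because this
works, so that class doubles as a validation set with known
drug–enzyme–substrate relations.

Structures are encoded as **166-key public MACCS substructure
fingerprints**: presence/absence bits over a fixed dictionary of
substructure patterns. Similarity between two fingerprints is the
**Tanimoto coefficient**

$$T_c(A,B) = \frac{C}{A + B - C},$$

with $A$, $B$ the set-bit counts of the two molecules and $C$ the shared
count — the Jaccard index on bit sets, bounded in $[0,1]$, 1 iff the key
sets coincide. MACCS keys carry no stereochemistry, so enantiomers and
epimers (cytarabine vs. cytidine, vidarabine vs. adenosine) score exactly
1; the prediction stage treats a score of 1 as "endogenous ligand" and
excludes it, which is also the pragmatic reading of how such analogues are
handled in reference candidate tables.

The pipeline stages and their contracts:

1. **Similarity matrix** — the full drugs × metabolites rectangle of
   $T_c$. Deterministic for fixed input; unparseable structures are
   flagged and excluded, never silently dropped.
2. **Cluster highlights** — complete-linkage hierarchical clustering of
   rows and columns on $d = 1 - \mathrm{cor}$ between similarity profiles
   (a cosine option is provided); every (row-subtree, column-subtree)
   pair is audited against three criteria — more than 50 drugs, more than
   100 metabolites, at least 30 % of cells with $T_c \ge 0.7$ — and
   maximal qualifying pairs are reported.
3. **Gold-standard selection** — per known (drug, enzyme) relation, the
   argmax substrate; kept iff $T_c > 0.5$ (strict).
4. **Significance** — $z = (T_c - \mu)/\sigma$ against the substrate's
   score distribution over *all* drugs (query included), one-sided
   upper-tail normal $p$.
5. **Threshold calibration** — ROC over all drug–enzyme scores labeled by
   GSP membership; Youden's $J(x) = Sp(x) + Se(x) - 1$ maximized over the
   exact threshold grid.
6. **Prediction** — all drugs at/above the threshold per enzyme, minus
   the enzyme's GSP drugs and identical-structure ligands.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| fingerprint scheme | MACCS, 166 keys | The key dictionary is sometimes described as a 1,024-bit descriptor in the literature; the reproducible, toolkit-standard object is the 166-key set, and the bundled worked examples confirm it reproduces the reference similarities. |
| GSP cutoff `min_sim` | 0.5 (strict >) | A known drug scoring below 0.5 against every substrate of its target is likely acting by a non-mimicry mechanism and would poison the positive set. |
| cluster criteria | >50 drugs, >100 metabolites, ≥30 % cells at $T_c \ge 0.7$ | "Almost 30 %" is operationalized as an exact ≥ 0.30 boundary for reproducibility; all three are configurable. |
| clustering distance | $1 - $ Pearson correlation of profiles | Standard heat-map practice; robust to overall similarity level. Cosine available. |
| decision threshold | Youden-optimal (≥ comparison) | `score ≥ t` predicts positive; at the optimum this keeps sensitivity at 1 before trading it for specificity, and keeps the GSP relations themselves above threshold. A tie on $J$ resolves to the higher (more specific) threshold. |
| p-value mode | normal tail | Reference reports contain p-values far below $1/n_{\text{drugs}}$, which an empirical percentile cannot produce; the normal-tail mode is therefore the primary one, with an explicitly labeled empirical alternative. Sample (n−1) standard deviation. |
| salt stripping | on | Database records often carry counter-ions; similarities on parent structures are what reference tables report. |

## Numerical and degenerate-input choices

* Two all-zero fingerprints have identical (empty) key sets: $T_c$ is
  defined as 1 with a warning rather than 0/0.
* A constant similarity column cannot be standardized: fitting its
  distribution raises a typed `metalike_degenerate_distribution` error.
* ROC construction requires both classes; single-class input is a typed
  error, not an `NaN`.
* The threshold grid is every distinct observed score plus a sentinel
  above the maximum — an exact step-function ROC with no binning, whose
  trapezoid AUC equals the Mann–Whitney concordance statistic (tested
  against a brute-force concordant-pair count).
* Substrate argmax ties in GSP selection keep both substrates with a
  warning; discarding one silently would lose information.

## The bundled fixture set

The package ships parent structures (as SMILES, desalted, neutral where
possible) for the 17 antimetabolites of the validation set, their 15
enzyme substrates and the candidate drugs levoleucovorin and vidarabine,
plus the curated 27-row relation table across 11 enzyme groups. Worked
examples reproduced on these structures include azacitidine–cytidine 0.97,
decitabine–cytidine 0.88 and levoleucovorin–10-formyl-tetrahydrofolate
0.969 (the quantity recomputed by `scripts/acceptance.R`).

Two provenance caveats are worth recording rather than hiding. First, the
exact tautomer/protonation states behind the original curated similarity
values are unknown (the source structure files mixed several registries);
with neutral parent structures a handful of folate- and purine-family
pairs land 0.03–0.17 from their reference values (e.g.
pemetrexed–dihydrofolate 0.84 vs. 0.86; allopurinol–hypoxanthine 0.86 vs.
0.69 under every tautomer combination we tried), while charged folate
forms fix some pairs and break others. These are reported, not tuned.
Second, as a consequence, pemetrexed's best dihydrofolate-reductase
substrate computes as tetrahydrofolate rather than dihydrofolate, so a
GSP set *recomputed* from these structures spans 14 distinct substrates
while the curated relation table spans 15. Fludarabine is bundled as the
free nucleoside: its phosphate form scores 0.92 against ADP where the
reference value is 0.80, and the free form matches.

## The synthetic generator

`generate_fingerprint_universe()` emulates the one feature of fingerprint
data the statistics depend on: background pairs with low, concentrated
similarity and planted pairs with controlled high similarity.

* Background fingerprints are independent Bernoulli($p$) bit vectors; two
  such vectors have expected Tanimoto $\approx p/(2-p)$ (0.11 at the
  default $p = 0.2$, which also matches a realistic MACCS on-bit density
  for drug-like molecules, ~33 of 166 keys).
* A planted pair copies the metabolite fingerprint into the drug and
  flips ON bits off at rate $q = (1-t)/(1+t)$ and OFF bits on at rate
  $q\,A/(L-A)$, keeping the expected popcount fixed; the expected
  Tanimoto is then $(1-q)/(1+q) = t$, the target. A target of 1 copies
  exactly; infeasible combinations raise a typed error.
* Fixed seed ⇒ bit-identical universes.

What it does **not** emulate: correlated keys (real substructure keys are
strongly dependent), the heavy right tail of similarity within chemical
families, and any relation between a drug's fingerprints across several
substrates. Tests passing on synthetic universes therefore certify the
statistical machinery (ROC/Youden recovery, calibration of the normal-tail
p under its own null, block detection), not chemistry; the fixture set
covers the chemistry end at desk scale.

Test problem sizes were chosen to keep the whole suite in the
few-minute range on one core: 1,024-bit universes with 500–1,000
replicates for the Monte-Carlo expectations, 65 × 130 matrices for block
detection, 200 + 200 scores for threshold-recovery properties.

## Design decisions that were genuinely open

* **Relation universe for calibration.** Scores could be labeled per
  drug × substrate or per drug × enzyme; we fold substrates to enzymes
  (max over the enzyme's GSP substrates), matching how the validation
  set itself is defined, and note it as an interpretation.
* **Cluster enumeration.** Reading blocks off a heat map is visual; the
  reproducible formalization chosen here scans all subtree pairs of the
  two dendrograms and suppresses nested qualifying pairs. With a dense
  block, modest supersets of the block also qualify (the 30 % criterion
  is forgiving), so "one highlight per planted block" is only guaranteed
  when the block dominates its universe; the tests are built that way on
  purpose, and the brute-force oracle check is universe-independent.
* **Negative set.** All (drug, GSP-enzyme) pairs not in the GSP are
  treated as negatives. Some are surely unknown positives; that biases
  AUC downward, which is the conservative direction for threshold
  setting.
* **Endogenous-ligand exclusion** is `similarity == 1` or identical id —
  with stereochemistry-blind keys this is exactly the "same molecule up
  to stereochemistry" equivalence class.

## Limitations

* MACCS/Tanimoto sees 2-D substructure content only: no stereochemistry,
  no 3-D complementarity, no binding-site context. It proposes
  *modulators* without sign (inhibitor vs. substrate-competitive vs.
  activator).
* The normal-tail p-value assumes the similarity column is adequately
  normal; columns of small or strongly clustered drug sets are not, and
  the empirical mode exists for exactly that check.
* Calibration on a small, hard validation set (every bundled drug is a
  metabolite mimic) understates the separation achievable on a full drug
  library; threshold and AUC from the bundle should not be quoted as
  library-scale performance.
* Enzyme groups are treated as labels; no attempt is made to split
  grouped isoenzymes (e.g. "IMPDH1/2") back into proteins.
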