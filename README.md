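# metalike

Metabolite-likeness screening for enzyme-modulator drug repositioning.

Many drugs act because they resemble an endogenous metabolite closely
enough to engage the metabolite's enzyme — the antimetabolites
(5-fluorouracil analogues, antifolates, nucleoside analogues) are the
textbook case. `metalike` turns that observation into a screening method:
score every drug against every substrate of the enzymes of interest by
structural similarity, validate the score on the antimetabolite class where
drug–enzyme–substrate relations are known, calibrate a decision threshold
on the resulting ROC curve, and propose every other drug that clears the
threshold as a candidate modulator of the corresponding enzyme.

It is aimed at computational chemists and drug-repositioning researchers
who want a transparent, fingerprint-based baseline that runs from plain
SDF/SMILES inputs with no web services.

## Method

* **Similarity.** Molecules are encoded as 166-key public MACCS
  substructure fingerprints and compared with the Tanimoto coefficient

  `T_c(A, B) = C / (A + B − C)`

  where *A* and *B* are the set-bit counts of the two fingerprints and *C*
  the shared-bit count. A drugs × metabolites matrix of `T_c` is the core
  object; hierarchically clustering it (complete linkage on a correlation
  distance between similarity profiles) exposes the dense drug/metabolite
  blocks typical of purine/pyrimidine, CoA and sterol chemistry.
* **Gold standard.** For each known (antimetabolite, enzyme) relation the
  enzyme substrate with the highest similarity to the drug is chosen; the
  relation enters the gold-standard positive (GSP) set iff `T_c > 0.5`.
* **Significance.** Each GSP similarity is standardized against the
  substrate's similarity distribution over all drugs
  (`z = (T_c − mean)/sd`, one-sided upper-tail normal p-value).
* **Calibration.** All drug–enzyme scores (max similarity over the
  enzyme's GSP substrates) are labeled by GSP membership; the ROC curve is
  swept over every distinct score, AUC is the trapezoid/rank statistic, and
  the operating threshold maximizes Youden's `J(x) = Sp(x) + Se(x) − 1`.
* **Prediction.** Per enzyme, every drug at or above the threshold is
  reported as a candidate, excluding the enzyme's own GSP drugs and
  structurally identical endogenous ligands.

## Worked example

The package bundles parent structures and curated relations for the
classic antimetabolite set: 17 drugs, their 11 target enzyme groups and 15
substrates, plus the candidate drugs levoleucovorin and vidarabine.

```r
library(metalike)

bundle <- load_fixture_bundle()
m <- similarity_matrix(bundle$drugs, bundle$metabolites)
#> <sim_matrix> 19 drugs x 15 metabolites (scheme maccs166)
#>   Tc range [0.364, 1.000], 31.9% of cells >= 0.7

round(m["azacitidine", "cytidine"], 2)
#> [1] 0.97

gsp <- select_gsp(m, bundle$drug_enzyme, bundle$enzymes)
str(gsp_summary(gsp))
#> List of 4
#>  $ n_drugs     : int 17
#>  $ n_enzymes   : int 11
#>  $ n_substrates: int 14
#>  $ n_relations : int 27

roc <- roc_curve(label_relations(m, gsp))
youden_optimal(roc)
#> <youden_profile> J max = 0.655 at threshold 0.689 (Se 0.963, Sp 0.692)

top_candidate_report(predict_candidates(m, gsp, threshold = 0.654))
#>    enzyme_label substrate_id        drug_id similarity
#> 1          ATIC       f10THF levoleucovorin       0.97
#> 2          DHFR          THF levoleucovorin       0.92
#> 3         DNMT1     cytidine    gemcitabine       0.88
#> 4         ENPP1         dNAD     vidarabine       0.76
#> 5          GART       f10THF levoleucovorin       0.97
#> 6      IMPDH1/2          IMP     nelarabine       0.77
#> 7        NME1/2         dCDP     decitabine       0.81
#> 8    POLA1,POLB         dCTP     decitabine       0.81
#> 9          RRM1          CDP     cytarabine       0.84
#> 10         TYMS       CH2THF levoleucovorin       0.89
#> 11          XDH            -              -         NA
```

Azacitidine, a cytidine analogue targeting DNA methyltransferase 1, scores
0.97 against cytidine — near-identical substructure content. The top
candidate table reads: for each enzyme, the non-antimetabolite drug most
similar to a substrate at the 0.654 operating threshold (levoleucovorin
against the folate-handling enzymes, for example), with a dash where only
the known antimetabolite relation clears the threshold (xanthine
dehydrogenase, XDH). Note the AUC/J values on this 19-drug bundle are not
comparable to a full drug-library screen: almost every bundled drug is a
metabolite mimic, so the "negatives" here are unusually hard.

The same pipeline is scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "metalike.R", package = "metalike"))')" \
    predict --drugs drugs.tsv --metabolites mets.tsv \
    --enzymes enzymes.tsv --relations drug_enzyme.tsv \
    --threshold 0.654 --outdir out/
```

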