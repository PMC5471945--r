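test_that("synthetic universes are seed-deterministic and validated", {
  cfg <- synthetic_config(20, 10, seed = 5)
  u1 <- generate_fingerprint_universe(cfg)
  u2 <- generate_fingerprint_universe(cfg)
  expect_identical(u1$drug_fps, u2$drug_fps)
  expect_identical(u1$metabolite_fps, u2$metabolite_fps)
  u3 <- generate_fingerprint_universe(synthetic_config(20, 10, seed = 6))
  expect_false(identical(u1$drug_fps, u3$drug_fps))

  expect_error(synthetic_config(5, 5, bit_density = 1.5),
               class = "metalike_bad_input")
  expect_error(
    synthetic_config(5, 5, planted_pairs = data.frame(drug = 1, metabolite = 1,
                                                      target = 1.3)),
    class = "metalike_bad_input")
  # infeasible plant: dense fingerprint, near-zero target needs an
  # off->on flip rate above 1
  dense <- synthetic_config(2, 2, fp_length = 20, bit_density = 0.95,
                            planted_pairs = data.frame(drug = 1, metabolite = 1,
                                                       target = 0.01),
                            seed = 5)
  expect_error(generate_fingerprint_universe(dense),
               class = "metalike_infeasible_target")
})

test_that("a target similarity of 1 copies the fingerprint exactly", {
  cfg <- synthetic_config(3, 3, planted_pairs = data.frame(
    drug = 1, metabolite = 2, target = 1), seed = 8)
  u <- generate_fingerprint_universe(cfg)
  expect_identical(u$drug_fps["d1", ], u$metabolite_fps["m2", ])
  expect_equal(tanimoto(u$drug_fps["d1", ], u$metabolite_fps["m2", ]), 1)
})

test_that("planted pairs realize their target similarity in expectation", {
  # 500 replicates of a 0.8-target plant at 1024 bits, density 0.2
  cfg <- synthetic_config(500, 500, fp_length = 1024, bit_density = 0.2,
                          planted_pairs = data.frame(drug = 1:500,
                                                     metabolite = 1:500,
                                                     target = 0.8),
                          seed = 9)
  u <- generate_fingerprint_universe(cfg)
  sims <- vapply(1:500, function(i)
    tanimoto(u$drug_fps[i, ], u$metabolite_fps[i, ]), numeric(1))
  expect_lt(abs(mean(sims) - 0.8), 0.02)
})

test_that("background pairs concentrate near the analytic p/(2-p)", {
  cfg <- synthetic_config(1000, 1000, fp_length = 1024, bit_density = 0.2,
                          seed = 10)
  u <- generate_fingerprint_universe(cfg)
  sims <- vapply(1:1000, function(i)
    tanimoto(u$drug_fps[i, ], u$metabolite_fps[i, ]), numeric(1))
  expect_lt(abs(mean(sims) - expected_background_tanimoto(0.2)), 0.01)
  expect_equal(expected_background_tanimoto(0.2), 0.2 / 1.8)
})

test_that("the fixture bundle is internally consistent", {
  b <- load_fixture_bundle()
  expect_s3_class(b, "fixture_bundle")
  # every relation resolves to bundled structures
  expect_true(all(b$relations$drug_id %in% b$compounds$id))
  expect_true(all(b$relations$substrate_id %in% b$compounds$id))
  expect_true(all(unlist(lapply(b$enzymes$substrate_ids,
                                metalike:::split_ids)) %in% b$compounds$id))
  # Table-level census: each entity appears exactly once in the compound set
  expect_false(anyDuplicated(b$compounds$id) > 0)
  expect_equal(nrow(b$enzymes), 11)
  expect_equal(length(unique(b$relations$drug_id)), 17)
  expect_equal(length(unique(b$relations$substrate_id)), 15)
})

test_that("the synthetic pipeline runs end to end with clean separation", {
  # 10 enzymes, each with one substrate planted against one drug at 0.8;
  # 20 extra background drugs at ~0.11 expected similarity
  cfg <- synthetic_config(30, 10, fp_length = 1024, bit_density = 0.2,
                          planted_pairs = data.frame(drug = 1:10,
                                                     metabolite = 1:10,
                                                     target = 0.8),
                          seed = 11)
  u <- generate_fingerprint_universe(cfg)
  m <- similarity_matrix(u$drug_fps, u$metabolite_fps)
  enz <- structure(
    data.frame(label = paste0("E", 1:10), ec_numbers = "",
               protein_accessions = "",
               substrate_ids = paste0("m", 1:10),
               excluded_cosubstrates = "", stringsAsFactors = FALSE),
    class = c("enzyme_table", "data.frame"))
  de <- data.frame(drug_id = paste0("d", 1:10), enzyme_label = paste0("E", 1:10))
  gsp <- select_gsp(m, de, enz)
  expect_equal(nrow(gsp), 10)                     # all plants pass > 0.5
  roc <- roc_curve(label_relations(m, gsp))
  expect_equal(roc$auc, 1)
  yj <- youden_optimal(roc)
  expect_equal(yj$j_max, 1)
  # the recovered threshold separates plants from background
  expect_gt(yj$optimal_threshold, 0.4)
  expect_lte(yj$optimal_threshold, min(gsp$similarity))
  cands <- predict_candidates(m, gsp, yj$optimal_threshold)
  expect_equal(nrow(cands), 0)                    # only GSP relations pass
})
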