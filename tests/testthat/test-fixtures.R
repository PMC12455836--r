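test_that("library generation is seeded, deduplicated and bounded", {
  sp <- fixture_spec(scaffold_library = c("c1ccccc1", "c1ccncc1"),
                     substituent_library = c("*C", "*F", "*Cl", "*C(F)(F)F"),
                     n_compounds = 20, seed = 1)
  lib1 <- generate_library(sp)
  lib2 <- generate_library(sp)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 20)
  expect_false(any(duplicated(lib1$smiles)))
  expect_true(all(lib1$smiles == canonical_smiles(lib1$smiles)))
  # combinatorial bound: 2 scaffolds x (4 + 4^2) assemblies before dedup
  expect_warning(
    big <- generate_library(fixture_spec(
      scaffold_library = c("c1ccccc1", "c1ccncc1"),
      substituent_library = c("*C", "*F", "*Cl", "*C(F)(F)F"),
      n_compounds = 10000, seed = 1)),
    "capping")
  expect_lte(nrow(big), 2 * (4 + 16))
})

test_that("motif carriers are enriched in the motif class", {
  lib <- small_library()
  tab <- table(lib$label[lib$has_motif])
  expect_equal(names(which.max(tab)), "selective")
  expect_gt(mean(lib$label[lib$has_motif] == "selective"), 0.5)
  freq_in <- mean(lib$has_motif[lib$label == "selective"])
  freq_out <- mean(lib$has_motif[lib$label != "selective"])
  expect_gt(freq_in, freq_out)
})

test_that("the toy classifier is closed-form logistic in the motif count", {
  sp <- small_spec()
  tc <- toy_classifier(sp)       # weights a = 2, b = -1
  pr0 <- tc$predict_proba("Cc1ccccc1")        # 0 motif matches
  expect_equal(unname(pr0[1, "selective"]), 1 / (1 + exp(1)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(pr0)), 1, tolerance = 1e-12)
  pr1 <- tc$predict_proba("FC(F)(F)c1ccccc1")  # 1 match
  expect_equal(unname(pr1[1, "selective"]), plogis(1), tolerance = 1e-9)
  expect_gt(pr1[1, "selective"], pr0[1, "selective"])
  # non-motif classes split the remaining mass equally
  expect_equal(unname(pr0[1, "non_selective"]),
               unname(pr0[1, "other_selective"]))
  # a change in non-motif atoms leaves the prediction untouched
  expect_equal(unname(tc$predict_proba("Clc1ccccc1")[1, ]),
               unname(pr0[1, ]))
})

test_that("designed potency folds survive the curation round-trip", {
  design <- data.frame(compound_id = c("s", "n", "g", "d"),
                       fold = c(500, 5, 50, 200),
                       spread = c(1, 1, 1, 20), stringsAsFactors = FALSE)
  rec <- generate_potency_table(design)
  expect_equal(aggregate_potency(
    rec$value_nm[rec$compound_id == "s" & rec$target == "B"]) /
      aggregate_potency(
        rec$value_nm[rec$compound_id == "s" & rec$target == "A"]), 500)
  out <- suppressWarnings(build_selectivity_dataset(rec, c("A", "B")))
  expect_identical(out$data$label[out$data$compound_id == "s"],
                   "selective_for_A")
  expect_identical(out$data$label[out$data$compound_id == "n"],
                   "non_selective")
  expect_false("g" %in% out$data$compound_id)
  # replicate ratio of exactly `spread` triggers the discard rule
  reps <- rec$value_nm[rec$compound_id == "d" & rec$target == "A"]
  expect_equal(max(reps) / min(reps), 20, tolerance = 1e-9)
  expect_identical(out$excluded$reason[out$excluded$compound_id == "d"],
                   "replicate spread")
})

test_that("planted-motif recovery holds across seeds with the toy oracle", {
  deltas <- list()
  for (seed in 1:3) {
    sp <- fixture_spec(n_compounds = 60, seed = seed)
    lib <- suppressWarnings(generate_library(sp))
    pool <- build_substituent_pool(lib)
    dict <- build_skeleton_dictionary(lib)
    tc <- toy_classifier(sp)
    test <- head(lib[!lib$has_motif, ], 5)
    foils <- generate_foils(test, pool, dict)
    sc <- score_all(tc, test, foils, "selective")
    deltas[[seed]] <- sc
  }
  agg <- aggregate_global(do.call(rbind, deltas), "substituent")
  expect_identical(agg$fragment[1], canonical_smiles("*C(F)(F)F"))
  expect_gt(agg$mean_delta[1], max(agg$mean_delta[-1]))
})
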