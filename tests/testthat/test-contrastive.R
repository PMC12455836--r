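test_that("contrastive behavior has the stated range semantics", {
  # complete probability shift from fact to foil
  expect_equal(contrastive_behavior(1, 0, 0, 1), 1)
  # no shift
  expect_equal(contrastive_behavior(0.7, 0.3, 0.7, 0.3), 0)
  expect_equal(contrastive_behavior(0.2, 0.05, 0.2, 0.05), 0)
  # hand-evaluated intermediate case
  expect_equal(contrastive_behavior(0.6, 0.2, 0.3, 0.6), 0.75 - 0.3 / 0.9,
               tolerance = 1e-12)
  expect_error(contrastive_behavior(0, 0, 0.5, 0.5), "degenerate")
  expect_error(contrastive_behavior(0.5, 0.5, 0, 0), "degenerate")
})

test_that("contrastive behavior attains -1 and 1 on the probability grid", {
  # delta separates into the fact-share of p minus the fact-share of q, so
  # the grid extrema are the share extremes; shares are evaluated through
  # the scoring formula itself (against a fixed uniform reference)
  g <- seq(0, 1, by = 0.01)
  pairs <- expand.grid(fact = g, foil = g)
  pairs <- pairs[pairs$fact + pairs$foil > 0, ]
  share <- contrastive_behavior(pairs$fact, pairs$foil, 0.5, 0.5) + 0.5
  expect_equal(min(share) , 0)
  expect_equal(max(share), 1)
  expect_equal(min(outer(range(share), range(share), "-")), -1)
  expect_equal(max(outer(range(share), range(share), "-")), 1)
  # spot-check the extreme combinations through the full formula
  expect_equal(contrastive_behavior(0, 1, 1, 0), -1)
  expect_equal(contrastive_behavior(1, 0, 0, 1), 1)
  # and a coarse full four-dimensional cross never leaves [-1, 1]
  cg <- seq(0, 1, by = 0.1)
  cp <- expand.grid(pf = cg, pl = cg, qf = cg, ql = cg)
  cp <- cp[cp$pf + cp$pl > 0 & cp$qf + cp$ql > 0, ]
  d <- contrastive_behavior(cp$pf, cp$pl, cp$qf, cp$ql)
  expect_true(all(d >= -1 & d <= 1))
})

test_that("contrastive behavior is antisymmetric and scale invariant", {
  set.seed(42)
  n <- 10000
  pf <- runif(n); pl <- runif(n); qf <- runif(n); ql <- runif(n)
  d1 <- contrastive_behavior(pf, pl, qf, ql)
  d2 <- contrastive_behavior(qf, ql, pf, pl)
  expect_lt(max(abs(d1 + d2)), 1e-12)
  k <- runif(n, 0.05, 1)
  d3 <- contrastive_behavior(k * pf, k * pl, qf, ql)
  expect_lt(max(abs(d1 - d3)), 1e-12)
})

test_that("scored foils match a brute-force evaluation of the shift formula", {
  spec <- small_spec()
  tc <- toy_classifier(spec)
  lib <- small_library()
  test <- head(lib[!lib$has_motif, ], 4)
  foils <- generate_foils(test, small_pool(), small_dictionary())
  sc <- score_all(tc, test, foils, "selective")
  expect_gt(nrow(sc), 0)
  expect_true(all(sc$delta >= -1 & sc$delta <= 1))
  # independent oracle: closed-form logistic probabilities from the motif
  # count, combined by the definition of the normalized shift
  match_count <- function(s) {
    vapply(s, function(x)
      molce:::smarts_count(x, spec$planted_motif), integer(1))
  }
  p_sel <- function(s) plogis(tc$a * match_count(s) + tc$b)
  for (i in seq_len(nrow(sc))) {
    parent <- test$smiles[match(sc$parent_id[i], test$id)]
    pm <- p_sel(parent); qm <- p_sel(sc$structure[i])
    # fact class of a motif-free parent is a non-motif class with
    # probability (1 - pm) / 2; foil class is the motif class
    expected <- ((1 - pm) / 2) / ((1 - pm) / 2 + pm) -
      ((1 - qm) / 2) / ((1 - qm) / 2 + qm)
    expect_equal(sc$delta[i], unname(expected), tolerance = 1e-12)
  }
})

test_that("ranking is a deterministic permutation with tie-breaks", {
  sc <- data.frame(parent_id = "p", structure = c("a", "b", "c"),
                   foil_type = "substituent",
                   replaced_fragment = "*F",
                   new_fragment = c("*Cl", "*Br", "*C"),
                   site = 1L, delta = c(0.3, -0.1, 0.3),
                   stringsAsFactors = FALSE)
  r <- rank_foils(sc)
  expect_identical(r$most$new_fragment, c("*C", "*Cl", "*Br"))
  expect_identical(r$least$new_fragment, c("*Br", "*C", "*Cl"))
  expect_setequal(r$most$structure, sc$structure)
  single <- rank_foils(sc[1, ])
  expect_identical(single$most, single$least)
})

test_that("global aggregation partitions eligible scores by fragment", {
  sc <- data.frame(parent_id = rep(c("p", "q"), each = 2),
                   structure = letters[1:4], foil_type = "substituent",
                   replaced_fragment = "*F",
                   new_fragment = c("*Cl", "*C", "*Cl", "*C"),
                   site = 1L, n_sites = c(1L, 1L, 1L, 2L),
                   delta = c(0.2, 0.1, 0.4, 0.9),
                   stringsAsFactors = FALSE)
  agg <- aggregate_global(sc, "substituent")
  expect_equal(agg$mean_delta[agg$fragment == "*Cl"], 0.3)
  expect_equal(agg$mean_delta[agg$fragment == "*C"], 0.1)  # 2-site row excluded
  expect_equal(sum(agg$n_foils), sum(sc$n_sites == 1))
  all_in <- aggregate_global(sc, "substituent", single_site_only = FALSE)
  expect_equal(sum(all_in$n_foils), nrow(sc))
})

test_that("substructure occurrence fractions are exact on planted carriers", {
  lib <- small_library()
  freq <- substructure_frequency("FC(F)F", lib$smiles, lib$label)
  # audit against the generator's own bookkeeping
  for (cl in names(freq)) {
    expect_equal(unname(freq[cl]),
                 mean(lib$has_motif[lib$label == cl]))
  }
  # the planted motif is enriched in the motif class
  expect_true(freq["selective"] > max(freq[names(freq) != "selective"]))
  none <- substructure_frequency("[Si]", lib$smiles, lib$label)
  expect_true(all(none == 0))
  arene <- substructure_frequency("c1ccccc1", rep("Cc1ccccc1", 5),
                                  rep("x", 5))
  expect_equal(unname(arene), 1)
})

test_that("Tanimoto similarity follows set-overlap arithmetic", {
  a <- matrix(0, 1, 16); a[1, 1:4] <- 1
  b <- matrix(0, 1, 16); b[1, 3:8] <- 1
  expect_equal(tanimoto(a, b)[1, 1], 2 / 8)
  expect_equal(tanimoto(a, a)[1, 1], 1)
  disj <- matrix(0, 1, 16); disj[1, 9:12] <- 1
  expect_equal(tanimoto(a, disj)[1, 1], 0)
  fp <- ecfp4(c("Cc1ccccc1", "Cc1ccccc1", "ClCCCl"))
  expect_equal(tanimoto(fp[1, , drop = FALSE], fp[2, , drop = FALSE])[1, 1], 1)
})

test_that("shift-similarity correlation is plain Pearson with guards", {
  expect_equal(shift_similarity_correlation(1:5, 2 * (1:5) + 3), 1)
  expect_equal(shift_similarity_correlation(1:5, -(1:5)), -1)
  expect_equal(shift_similarity_correlation(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(shift_similarity_correlation(1:2, 1:2), "3 pairs")
  expect_error(shift_similarity_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("applicability diagnostics cover tests and foils", {
  lib <- small_library()
  spec <- small_spec()
  tc <- toy_classifier(spec)
  train <- lib[1:40, ]
  test <- lib[41:44, c("id", "smiles")]
  foils <- generate_foils(test, small_pool(), small_dictionary())
  diag <- applicability_diagnostics(tc, test, foils, train, n_bits = 1024)
  expect_setequal(unique(diag$kind[diag$kind != "test"]),
                  unique(foils$foil_type))
  expect_true(all(diag$max_prob >= 1 / 3 & diag$max_prob <= 1))
  expect_true(all(diag$train_sim_max >= diag$train_sim_mean - 1e-12))
  expect_true(all(is.na(diag$parent_sim[diag$kind == "test"])))
  expect_true(all(!is.na(diag$parent_sim[diag$kind != "test"])))
  # a molecule identical to a training compound has max similarity 1
  t2 <- data.frame(id = "dup", smiles = train$smiles[1],
                   stringsAsFactors = FALSE)
  d2 <- applicability_diagnostics(tc, t2, NULL, train, n_bits = 1024)
  expect_equal(d2$train_sim_max, 1)
  expect_error(applicability_diagnostics(tc, test, foils, train[0, ]),
               "empty training set")
})
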