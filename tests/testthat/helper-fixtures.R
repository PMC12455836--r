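# Shared fixtures built in code. Heavier objects are memoized so the suite
# builds them once.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# small library shared by property tests (kept small for speed)
small_spec <- function(seed = 0, n = 120) {
  fixture_spec(n_compounds = n, seed = seed)
}

small_library <- function() {
  memo("small_library", suppressWarnings(generate_library(small_spec())))
}

small_dictionary <- function() {
  memo("small_dictionary", build_skeleton_dictionary(small_library()))
}

small_pool <- function() {
  memo("small_pool", build_substituent_pool(small_library()))
}

# default seed-0 fixture study, shared by the end-to-end tests
full_spec <- function() fixture_spec()

full_library <- function() {
  memo("full_library", generate_library(full_spec()))
}

full_dictionary <- function() {
  memo("full_dictionary", build_skeleton_dictionary(full_library()))
}

full_pool <- function() {
  memo("full_pool", build_substituent_pool(full_library()))
}

full_test_set <- function() {
  lib <- full_library()
  head(lib[!lib$has_motif, ], 15)
}

full_foils <- function() {
  memo("full_foils",
       generate_foils(full_test_set(), full_pool(), full_dictionary()))
}

# scaffold pairs for skeleton-invariance property tests: ring systems joined
# by variable-length linkers with heteroatom variants
ring_set <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "C1CCCCC1", "C1CCNCC1")

linked_scaffold <- function(ring_a, ring_b, linker_len) {
  paste0(ring_a, strrep("C", linker_len), ring_b)
}

# score all foils of a set of test compounds against a classifier
score_all <- function(model, test, foils, foil_class) {
  parts <- lapply(split(foils, foils$parent_id), function(f) {
    orig <- test$smiles[match(f$parent_id[1], test$id)]
    tryCatch(score_foils(model, orig, f, foil_class),
             error = function(e) NULL)
  })
  do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
}
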