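# Synthetic compound libraries with planted class-determining motifs, and a
# closed-form toy classifier. These fixtures emulate the structure of
# pairwise receptor-selectivity data sets (two selective classes plus a
# non-selective class) at desk scale, so that every pipeline stage can be
# exercised and audited without external data.

#' Specification for a synthetic compound library
#'
#' The default scaffold library is chosen so that scaffolds share reduced
#' carbon skeletons in groups (e.g. benzene/pyridine/pyrimidine/piperidine
#' all reduce to the six-ring), which makes scaffold-foil generation
#' non-trivial. The planted motif (default: trifluoromethyl) is carried by
#' one substituent fragment and determines class membership with the stated
#' enrichment.
#'
#' @param scaffold_library character vector of scaffold SMILES.
#' @param substituent_library character vector of single-attachment
#'   fragment SMILES (`*` marker).
#' @param planted_motif substructure (SMARTS) that drives class membership.
#' @param motif_class class enriched in motif carriers.
#' @param enrichment probability that a motif carrier is assigned to
#'   `motif_class` (default 0.8).
#' @param n_compounds library size (default 300).
#' @param class_balance named class fractions summing to 1.
#' @param seed integer seed (default 0).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(
    scaffold_library = c("c1ccccc1", "c1ccncc1", "c1cncnc1", "C1CCNCC1",
                         "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
                         "C(c1ccccc1)c1ccccc1", "C(c1ccccc1)c1ccncc1"),
    substituent_library = c("*C", "*CC", "*O", "*OC", "*N", "*NC", "*F",
                            "*Cl", "*C#N", "*C(F)(F)F", "*C(=O)N", "*CCO"),
    planted_motif = "FC(F)F",
    motif_class = "selective",
    enrichment = 0.8,
    n_compounds = 300,
    class_balance = c(selective = 1 / 3, other_selective = 1 / 3,
                      non_selective = 1 / 3),
    seed = 0) {
  stopifnot(length(scaffold_library) > 0, length(substituent_library) > 0,
            abs(sum(class_balance) - 1) < 1e-8,
            motif_class %in% names(class_balance),
            enrichment >= 0, enrichment <= 1)
  carriers <- smarts_count(c(scaffold_library, substituent_library),
                           planted_motif)
  if (!any(carriers >= 1, na.rm = TRUE)) {
    stop("planted motif matches no library element", call. = FALSE)
  }
  structure(list(scaffold_library = scaffold_library,
                 substituent_library = substituent_library,
                 planted_motif = planted_motif, motif_class = motif_class,
                 enrichment = enrichment, n_compounds = n_compounds,
                 class_balance = class_balance, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic compound library
#'
#' Enumerates the combinatorial scaffold x substituent space (every scaffold
#' with one substituent, and with every ordered substituent pair at two
#' sites), deduplicates by canonical structure, then draws `n_compounds`
#' with the spec's seed. Class labels are assigned so that planted-motif
#' carriers fall into `motif_class` with probability `enrichment`;
#' non-carriers follow `class_balance`.
#'
#' @param spec a `fixture_spec`.
#' @return data.frame with columns `id`, `smiles`, `label`, `scaffold`,
#'   `has_motif`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  frs <- spec$substituent_library
  combos <- list()
  for (sc in spec$scaffold_library) {
    scan <- canonical_smiles(sc)
    smol <- parse_mol(scan)
    for (f in frs) {
      atts <- .assign_sites(smol, f)
      if (is.null(atts)) next
      s <- assemble_structure(smol, atts)
      if (!is.na(s)) combos[[length(combos) + 1L]] <- c(s, scan, "1")
    }
    for (f1 in frs) for (f2 in frs) {
      atts <- .assign_sites(smol, c(f1, f2))
      if (is.null(atts)) next
      s <- assemble_structure(smol, atts)
      if (!is.na(s)) combos[[length(combos) + 1L]] <- c(s, scan, "2")
    }
  }
  pool <- do.call(rbind, combos)
  pool <- pool[!duplicated(pool[, 1]), , drop = FALSE]
  n <- spec$n_compounds
  if (n > nrow(pool)) {
    warning("requested ", n, " compounds but the combinatorial space holds ",
            nrow(pool), "; capping", call. = FALSE)
    n <- nrow(pool)
  }
  # draw mono- and di-substituted compounds in roughly equal numbers, as in
  # an analogue-series library, rather than letting the much larger
  # two-substituent space dominate
  set.seed(spec$seed)
  i1 <- which(pool[, 3] == "1")
  i2 <- which(pool[, 3] == "2")
  n1 <- min(ceiling(n / 2), length(i1))
  n2 <- min(n - n1, length(i2))
  if (n1 + n2 < n) n1 <- min(n - n2, length(i1))
  pick <- sort(c(sample(i1, n1), sample(i2, n2)))
  smiles <- pool[pick, 1]
  scaffold <- pool[pick, 2]
  has_motif <- smarts_count(smiles, spec$planted_motif) >= 1
  classes <- names(spec$class_balance)
  others <- setdiff(classes, spec$motif_class)
  other_w <- spec$class_balance[others] / sum(spec$class_balance[others])
  label <- character(n)
  for (i in seq_len(n)) {
    label[i] <- if (has_motif[i]) {
      if (stats::runif(1) < spec$enrichment) spec$motif_class else
        sample(others, 1, prob = other_w)
    } else {
      sample(classes, 1, prob = spec$class_balance)
    }
  }
  data.frame(id = sprintf("cmpd%04d", seq_len(n)), smiles = smiles,
             label = label, scaffold = scaffold, has_motif = has_motif,
             stringsAsFactors = FALSE)
}

#' Closed-form toy classifier
#'
#' A probability-emitting classifier whose output depends only on the number
#' of planted-motif matches in a molecule: the motif class receives
#' probability `plogis(a * matches + b)` and the remaining probability mass
#' is split equally among the other classes. Expected contrastive behavior
#' values for any foil are therefore computable by hand, which makes this
#' the oracle for scoring tests.
#'
#' @param spec a `fixture_spec` (supplies motif, motif class and class set).
#' @param a,b logistic weights (defaults 2 and -1).
#' @return a `molce_classifier`.
#' @export
toy_classifier <- function(spec, a = 2, b = -1) {
  stopifnot(inherits(spec, "fixture_spec"))
  classes <- sort(names(spec$class_balance))
  motif_class <- spec$motif_class
  motif <- spec$planted_motif
  structure(list(
    predict_proba = function(smiles) {
      cnt <- smarts_count(smiles, motif)
      if (anyNA(cnt)) stop("cannot parse structure for prediction", call. = FALSE)
      pm <- stats::plogis(a * cnt + b)
      pr <- matrix((1 - pm) / (length(classes) - 1), nrow = length(smiles),
                   ncol = length(classes), dimnames = list(NULL, classes))
      pr[, motif_class] <- pm
      pr
    },
    classes = classes, a = a, b = b, motif = motif,
    motif_class = motif_class),
    class = "molce_classifier")
}

#' Generate a potency table realizing designed fold-differences
#'
#' Produces per-target potency records whose fold-differences equal a
#' designed value, optionally with replicate spread (geometric, so the
#' max/min replicate ratio equals `spread` exactly) to exercise the
#' replicate-discard rule.
#'
#' @param fold_design data.frame with columns `compound_id`, `fold`
#'   (potency on target B relative to A; values > 1 make A the more potent
#'   target), optional `smiles` and optional `spread` (replicate max/min
#'   ratio on target A; default 1 = no noise).
#' @param base_nm potency of the more potent target (default 10 nM).
#' @param targets length-2 target names (default A, B).
#' @param measure measurement type recorded (default `Ki`).
#' @return data.frame with columns `compound_id`, `smiles`, `target`,
#'   `measure`, `value_nm` (one row per replicate and target).
#' @export
generate_potency_table <- function(fold_design, base_nm = 10,
                                   targets = c("A", "B"), measure = "Ki") {
  stopifnot(all(c("compound_id", "fold") %in% names(fold_design)))
  smiles <- fold_design$smiles %||% rep("c1ccccc1", nrow(fold_design))
  spread <- fold_design$spread %||% rep(1, nrow(fold_design))
  rows <- list()
  for (i in seq_len(nrow(fold_design))) {
    va <- if (spread[i] > 1) {
      base_nm * c(1 / sqrt(spread[i]), sqrt(spread[i]))
    } else base_nm
    vb <- base_nm * fold_design$fold[i]
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = fold_design$compound_id[i], smiles = smiles[i],
      target = c(rep(targets[1], length(va)), targets[2]),
      measure = measure, value_nm = c(va, vb), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
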