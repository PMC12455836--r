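# Contrastive behavior scoring, ranking, global aggregation, and
# applicability-domain diagnostics.

#' Contrastive behavior of a probability shift
#'
#' Quantifies the normalized shift, between an original prediction `p` and a
#' perturbed-instance prediction `q`, of the fact class's probability share
#' relative to the foil class:
#' `delta = p_fact/(p_fact + p_foil) - q_fact/(q_fact + q_foil)`.
#' A value of 1 is a complete probability shift from fact to foil, 0 is no
#' shift, and negative values reinforce the fact class. All arguments are
#' vectorized.
#'
#' @param p_fact,p_foil fact/foil class probabilities for the original
#'   instance.
#' @param q_fact,q_foil fact/foil class probabilities for the perturbed
#'   instance.
#' @return numeric vector of contrastive behavior values in `[-1, 1]`.
#' @export
contrastive_behavior <- function(p_fact, p_foil, q_fact, q_foil) {
  if (any(c(p_fact, p_foil, q_fact, q_foil) < 0) ||
      any(c(p_fact, p_foil, q_fact, q_foil) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_fact + p_foil <= 0) || any(q_fact + q_foil <= 0)) {
    stop("degenerate probabilities: fact + foil mass must be positive",
         call. = FALSE)
  }
  p_fact / (p_fact + p_foil) - q_fact / (q_fact + q_foil)
}

# Class probabilities from a molce classifier contract.
predict_probabilities <- function(model, smiles) {
  stopifnot(inherits(model, "molce_classifier"))
  pr <- model$predict_proba(smiles)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, model$classes))
  pr
}

# Argmax class with ties broken by class-name order.
.fact_class <- function(probs) {
  cls <- colnames(probs)
  ord <- order(-probs[1, ], cls)
  cls[ord[1]]
}

#' Score foils against a classifier
#'
#' Predicts the original compound and every foil with a probability-emitting
#' classifier, takes the model's argmax on the original as the fact class,
#' and computes the contrastive behavior of each foil towards `foil_class`.
#'
#' @param model a `molce_classifier` (see [toy_classifier()] or
#'   [train_brf()]).
#' @param original_smiles SMILES of the original (fact) compound.
#' @param foils foil data.frame from [substituent_foils()],
#'   [scaffold_foils()] or [generate_foils()].
#' @param foil_class class name to contrast against; must differ from the
#'   fact class.
#' @return the foil data.frame extended with `fact_class`, `foil_class`,
#'   `p_fact`, `p_foil`, `q_fact`, `q_foil`, `delta` (input row order kept).
#' @export
score_foils <- function(model, original_smiles, foils, foil_class) {
  stopifnot(inherits(model, "molce_classifier"))
  p <- predict_probabilities(model, original_smiles)
  if (!foil_class %in% colnames(p)) {
    stop("unknown foil class: ", foil_class, call. = FALSE)
  }
  fact <- .fact_class(p)
  if (identical(fact, foil_class)) {
    stop("foil class equals the fact class (", fact, ")", call. = FALSE)
  }
  out <- foils
  if (nrow(foils) == 0) {
    out$fact_class <- character(0); out$foil_class <- character(0)
    out$p_fact <- out$p_foil <- out$q_fact <- out$q_foil <- out$delta <- numeric(0)
    return(out)
  }
  q <- predict_probabilities(model, foils$structure)
  out$fact_class <- fact
  out$foil_class <- foil_class
  out$p_fact <- p[1, fact]
  out$p_foil <- p[1, foil_class]
  out$q_fact <- q[, fact]
  out$q_foil <- q[, foil_class]
  out$delta <- contrastive_behavior(out$p_fact, out$p_foil,
                                    out$q_fact, out$q_foil)
  out
}

#' Rank scored foils
#'
#' @param scores scored foil data.frame from [score_foils()].
#' @return list with elements `most` (descending delta) and `least`
#'   (ascending delta); ties broken by the canonical `new_fragment` string.
#' @export
rank_foils <- function(scores) {
  if (nrow(scores) == 0) stop("no scores to rank", call. = FALSE)
  most <- scores[order(-scores$delta, scores$new_fragment), , drop = FALSE]
  least <- scores[order(scores$delta, scores$new_fragment), , drop = FALSE]
  rownames(most) <- rownames(least) <- NULL
  list(most = most, least = least)
}

#' Aggregate contrastive behavior globally per fragment
#'
#' Groups scored foils (typically pooled over many compounds and trials) by
#' the replacement fragment and reports the arithmetic mean contrastive
#' behavior per fragment. Substituent aggregation is restricted to foils of
#' parents with a single substitution site, so that a fragment's mean is not
#' confounded by the retained-substituent context; scaffold aggregation uses
#' all scaffold foils.
#'
#' @param scores scored foil data.frame carrying an `n_sites` column (as
#'   produced by [generate_foils()] + [score_foils()]).
#' @param fragment_kind `"substituent"` or `"scaffold"`.
#' @param single_site_only restrict substituent aggregation to single-site
#'   parents (default TRUE; ignored for scaffolds).
#' @return data.frame with columns `fragment`, `fragment_kind`,
#'   `mean_delta`, `n_foils`, sorted by decreasing `mean_delta` (ties by
#'   fragment string).
#' @export
aggregate_global <- function(scores,
                             fragment_kind = c("substituent", "scaffold"),
                             single_site_only = TRUE) {
  fragment_kind <- match.arg(fragment_kind)
  sel <- scores[scores$foil_type == fragment_kind, , drop = FALSE]
  if (fragment_kind == "substituent" && single_site_only) {
    if (is.null(sel$n_sites)) {
      stop("scores lack the n_sites column needed for single-site filtering",
           call. = FALSE)
    }
    sel <- sel[sel$n_sites == 1, , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    return(data.frame(fragment = character(0), fragment_kind = character(0),
                      mean_delta = numeric(0), n_foils = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(sel$delta, by = list(fragment = sel$new_fragment),
                   FUN = mean)
  cnt <- as.data.frame(table(sel$new_fragment), stringsAsFactors = FALSE)
  names(cnt) <- c("fragment", "n_foils")
  out <- merge(agg, cnt, by = "fragment")
  out <- data.frame(fragment = out$fragment, fragment_kind = fragment_kind,
                    mean_delta = out$x, n_foils = as.integer(out$n_foils),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_delta, out$fragment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class substructure occurrence
#'
#' Fraction of compounds in each class containing at least one match of a
#' substructure pattern (SMARTS).
#'
#' @param pattern substructure query (SMARTS string).
#' @param smiles character vector of compound SMILES.
#' @param class class label per compound.
#' @return named numeric vector: per class, fraction of compounds with a
#'   match, in `[0, 1]`.
#' @export
substructure_frequency <- function(pattern, smiles, class) {
  stopifnot(length(smiles) == length(class))
  hits <- smarts_count(smiles, pattern)
  if (anyNA(hits)) {
    warning(sum(is.na(hits)), " unparseable compounds excluded", call. = FALSE)
  }
  ok <- !is.na(hits)
  c(tapply((hits[ok] >= 1) * 1, class[ok], mean))
}

#' Applicability-domain diagnostics
#'
#' For every test instance and foil: the model's highest class probability
#' (a direct confidence measure for forest classifiers) and the maximal and
#' mean Tanimoto similarity to the training instances; foils additionally
#' carry the Tanimoto similarity to their parent compound. Diagnostics and
#' model share the same folded circular fingerprint representation.
#'
#' @param model a `molce_classifier`.
#' @param test data.frame with columns `id`, `smiles` (test instances).
#' @param foils foil data.frame (may be scored or unscored).
#' @param train data.frame with columns `id`, `smiles` (training instances).
#' @param n_bits fingerprint length (default 2048).
#' @return data.frame with columns `id`, `kind` (`"test"`, `"substituent"`,
#'   `"scaffold"`), `max_prob`, `train_sim_max`, `train_sim_mean`,
#'   `parent_sim` (NA for test rows).
#' @export
applicability_diagnostics <- function(model, test, foils, train,
                                      n_bits = 2048) {
  if (is.null(train) || nrow(train) == 0) {
    stop("empty training set", call. = FALSE)
  }
  fp_train <- ecfp4(train$smiles, n_bits)
  fp_test <- ecfp4(test$smiles, n_bits)
  pt <- predict_probabilities(model, test$smiles)
  st <- tanimoto(fp_test, fp_train)
  rows <- data.frame(
    id = test$id, kind = "test",
    max_prob = apply(pt, 1, max),
    train_sim_max = apply(st, 1, max),
    train_sim_mean = rowMeans(st),
    parent_sim = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(foils) && nrow(foils) > 0) {
    fp_foil <- ecfp4(foils$structure, n_bits)
    pf <- predict_probabilities(model, foils$structure)
    sf <- tanimoto(fp_foil, fp_train)
    parent_idx <- match(foils$parent_id, test$id)
    psim <- vapply(seq_len(nrow(foils)), function(i) {
      if (is.na(parent_idx[i])) return(NA_real_)
      tanimoto(fp_foil[i, , drop = FALSE],
               fp_test[parent_idx[i], , drop = FALSE])[1, 1]
    }, numeric(1))
    rows <- rbind(rows, data.frame(
      id = foils$parent_id, kind = foils$foil_type,
      max_prob = apply(pf, 1, max),
      train_sim_max = apply(sf, 1, max),
      train_sim_mean = rowMeans(sf),
      parent_sim = psim, stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

#' Correlation between contrastive shifts and structural similarity
#'
#' Pearson correlation between foil contrastive behavior and the foil-parent
#' Tanimoto similarity. Near-zero values indicate that contrastive shifts
#' reflect defined chemical changes rather than cumulative feature
#' perturbation.
#'
#' @param delta contrastive behavior values.
#' @param similarity foil-parent Tanimoto similarities (same length).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
shift_similarity_correlation <- function(delta, similarity) {
  stopifnot(length(delta) == length(similarity))
  if (length(delta) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(delta) == 0 || stats::sd(similarity) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(delta, similarity, method = "pearson")
}
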