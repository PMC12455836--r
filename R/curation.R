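# Potency aggregation and pairwise selectivity labeling.

#' Aggregate replicate potency measurements
#'
#' Replicates falling within one order of magnitude (max/min ratio at most
#' 10) are averaged arithmetically; more discordant replicates disqualify
#' the measurement.
#'
#' @param values numeric vector of potency values in nM (lower = more
#'   potent); must be positive and nonempty.
#' @param max_ratio largest tolerated max/min replicate ratio (default 10,
#'   one log unit).
#' @return the arithmetic mean, or `NA` when the spread exceeds
#'   `max_ratio` (discard signal).
#' @export
aggregate_potency <- function(values, max_ratio = 10) {
  if (length(values) == 0) stop("empty potency list", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("potency values must be positive", call. = FALSE)
  }
  if (max(values) / min(values) > max_ratio) return(NA_real_)
  mean(values)
}

#' Assign a pairwise selectivity label
#'
#' A compound measured against two targets is selective for the more potent
#' target when the potency fold-difference is at least `selective_fold`
#' (default 100), non-selective when it is at most `nonselective_fold`
#' (default 10), and excluded in the gray zone between the two thresholds.
#'
#' @param pot_a,pot_b aggregated potencies (nM) on targets A and B.
#' @param targets length-2 character vector of target names used to build
#'   the selective labels.
#' @param selective_fold,nonselective_fold the two fold thresholds (both
#'   inclusive).
#' @return data.frame with columns `label` (one of
#'   `selective_for_<A>`, `selective_for_<B>`, `non_selective`, `excluded`)
#'   and `fold_difference`.
#' @export
assign_selectivity <- function(pot_a, pot_b, targets = c("A", "B"),
                               selective_fold = 100, nonselective_fold = 10) {
  stopifnot(length(targets) == 2, pot_a > 0, pot_b > 0)
  fold <- max(pot_a, pot_b) / min(pot_a, pot_b)
  label <- if (fold >= selective_fold) {
    # lower potency value = more potent target
    paste0("selective_for_", if (pot_a < pot_b) targets[1] else targets[2])
  } else if (fold <= nonselective_fold) {
    "non_selective"
  } else {
    "excluded"
  }
  data.frame(label = label, fold_difference = fold, stringsAsFactors = FALSE)
}

# Preferred measurement type when a compound-target pair carries several.
.measure_preference <- c("Ki", "IC50", "Kd")

#' Build a pairwise selectivity data set from potency records
#'
#' Implements the full curation protocol: per (compound, target) the
#' preferred measurement type (Ki over IC50 over Kd) is selected and its
#' replicates aggregated; compounds measured on both targets with both
#' potencies at or below the activity cutoff are labeled selective /
#' non-selective by fold-difference; everything else is excluded with a
#' recorded reason.
#'
#' @param records data.frame with columns `compound_id`, `smiles`, `target`,
#'   `measure` (`Ki`, `IC50` or `Kd`), `value_nm`.
#' @param target_pair length-2 character vector naming targets A and B.
#' @param activity_cutoff_nm potency ceiling, default 10000 nM (10 uM).
#' @param exclusions optional character vector of compound ids to drop
#'   (e.g. an external assay-interference list).
#' @param selective_fold,nonselective_fold passed to [assign_selectivity()].
#' @return list with `data` (data.frame `compound_id`, `smiles`, `label`,
#'   `fold_difference`) and `excluded` (data.frame `compound_id`, `reason`).
#' @export
build_selectivity_dataset <- function(records, target_pair,
                                      activity_cutoff_nm = 10000,
                                      exclusions = NULL,
                                      selective_fold = 100,
                                      nonselective_fold = 10) {
  need <- c("compound_id", "smiles", "target", "measure", "value_nm")
  stopifnot(all(need %in% names(records)), length(target_pair) == 2)
  records <- records[records$target %in% target_pair, , drop = FALSE]
  excluded <- data.frame(compound_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  exclude <- function(id, why) {
    rbind(excluded, data.frame(compound_id = id, reason = why,
                               stringsAsFactors = FALSE))
  }
  rows <- list()
  for (id in unique(records$compound_id)) {
    if (id %in% exclusions) {
      excluded <- exclude(id, "external exclusion list")
      next
    }
    rec <- records[records$compound_id == id, , drop = FALSE]
    if (!all(target_pair %in% rec$target)) {
      excluded <- exclude(id, "missing target")
      next
    }
    pots <- numeric(2)
    bad <- NULL
    for (k in 1:2) {
      rt <- rec[rec$target == target_pair[k], , drop = FALSE]
      meas <- .measure_preference[.measure_preference %in% rt$measure][1]
      if (is.na(meas)) { bad <- "unknown measure type"; break }
      pot <- aggregate_potency(rt$value_nm[rt$measure == meas])
      if (is.na(pot)) { bad <- "replicate spread"; break }
      if (pot > activity_cutoff_nm) { bad <- "activity cutoff"; break }
      pots[k] <- pot
    }
    if (!is.null(bad)) {
      excluded <- exclude(id, bad)
      next
    }
    lab <- assign_selectivity(pots[1], pots[2], targets = target_pair,
                              selective_fold = selective_fold,
                              nonselective_fold = nonselective_fold)
    if (lab$label == "excluded") {
      excluded <- exclude(id, "gray zone fold-difference")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = id, smiles = rec$smiles[1], label = lab$label,
      fold_difference = lab$fold_difference, stringsAsFactors = FALSE)
  }
  data <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(compound_id = character(0), smiles = character(0),
               label = character(0), fold_difference = numeric(0),
               stringsAsFactors = FALSE)
  rownames(data) <- NULL
  if (length(unique(data$label)) < 2) {
    warning("fewer than 2 selectivity classes populated; ",
            "data set not viable for classification", call. = FALSE)
  }
  list(data = data, excluded = excluded)
}
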