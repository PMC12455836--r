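# Virtual analogue (foil) generation by substituent and scaffold replacement.

# Parse a single-attachment fragment SMILES; returns the fragment graph with
# the dummy atom removed, plus the index of the atom that carried it.
parse_fragment <- function(fragment) {
  mol <- parse_mol(fragment)
  star <- which(mol$elem == "*")
  if (length(star) != 1) {
    stop("fragment must carry exactly one '*' attachment marker: ", fragment,
         call. = FALSE)
  }
  at <- mol$bonds[mol$bonds[, 1] == star | mol$bonds[, 2] == star, ,
                  drop = FALSE]
  if (nrow(at) != 1 || at[1, 3] != 1) {
    stop("attachment marker must carry a single bond: ", fragment,
         call. = FALSE)
  }
  attach <- if (at[1, 1] == star) at[1, 2] else at[1, 1]
  keep <- setdiff(seq_len(mol$natoms), star)
  sub <- mol_subgraph(mol, keep)
  list(mol = sub, attach = match(attach, keep))
}

# Attach fragments (list of list(fragment=, site=)) to a scaffold graph.
# Returns canonical SMILES, or NA when the assembly violates valence rules
# or cannot be sanitized.
assemble_structure <- function(scaffold_mol, attachments) {
  mol <- scaffold_mol
  for (att in attachments) {
    fr <- parse_fragment(att$fragment)
    off <- mol$natoms
    bonds <- fr$mol$bonds
    if (nrow(bonds) > 0) {
      bonds[, 1] <- bonds[, 1] + off
      bonds[, 2] <- bonds[, 2] + off
    }
    mol <- list(elem = c(mol$elem, fr$mol$elem),
                bonds = rbind(mol$bonds, bonds,
                              c(att$site, fr$attach + off, 1L)),
                natoms = mol$natoms + fr$mol$natoms)
  }
  if (!mol_valence_ok(mol)) return(NA_character_)
  mol_to_smiles(mol)
}

#' Rebuild a compound from its decomposition
#'
#' Reattaches every extracted substituent at its recorded site on the
#' canonical scaffold. The result is graph-isomorphic to the parent, so its
#' canonical SMILES equals the parent's.
#'
#' @param dec a `molce_decomposition` from [decompose_compound()].
#' @return canonical SMILES of the reassembled molecule.
#' @export
reconstruct_compound <- function(dec) {
  stopifnot(inherits(dec, "molce_decomposition"))
  atts <- lapply(seq_len(nrow(dec$substituents)), function(i) {
    list(fragment = dec$substituents$fragment[i],
         site = dec$substituents$site[i])
  })
  assemble_structure(dec$scaffold_mol, atts)
}

#' Build a substituent pool from a data set
#'
#' Extracts all unique substituent fragments from the decomposable compounds
#' of a data set. These fragments are the replacement vocabulary for
#' substituent-foil generation.
#'
#' @param compounds data.frame with columns `id`, `smiles`, or a character
#'   vector of SMILES.
#' @param source optional data-set identifier stored with the pool.
#' @return object of class `substituent_pool` with fields `fragments`
#'   (sorted unique canonical fragment SMILES) and `source`.
#' @export
build_substituent_pool <- function(compounds, source = NA_character_) {
  smiles <- if (is.data.frame(compounds)) compounds$smiles else compounds
  smiles <- unique(canonical_smiles(smiles))
  smiles <- smiles[!is.na(smiles)]
  frags <- character(0)
  for (s in smiles) {
    dec <- suppressWarnings(decompose_compound(s))
    if (!is.null(dec)) frags <- c(frags, dec$substituents$fragment)
  }
  structure(list(fragments = sort(unique(frags)), source = source),
            class = "substituent_pool")
}

#' @export
print.substituent_pool <- function(x, ...) {
  cat("substituent_pool:", length(x$fragments), "unique fragments\n")
  invisible(x)
}

.empty_foils <- function() {
  data.frame(parent_id = character(0), structure = character(0),
             foil_type = character(0), replaced_fragment = character(0),
             new_fragment = character(0), site = integer(0),
             stringsAsFactors = FALSE)
}

# Drop rows equal to the parent structure and duplicated structures (first
# occurrence, in the deterministic enumeration order, wins).
.finalize_foils <- function(df, parent) {
  df <- df[!is.na(df$structure) & df$structure != parent, , drop = FALSE]
  df <- df[!duplicated(df$structure), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate substituent foils
#'
#' Produces virtual analogues of a decomposed compound by replacing one
#' substituent at a time with each fragment of the pool, preserving the
#' scaffold and all other original substituents. For compounds with a single
#' substitution site the lone substituent is replaced. Assemblies that
#' violate valence rules are dropped; foils identical to the parent are
#' excluded and results are deduplicated by canonical structure.
#'
#' @param dec a `molce_decomposition`.
#' @param pool a `substituent_pool`.
#' @return data.frame with columns `parent_id`, `structure`, `foil_type`,
#'   `replaced_fragment`, `new_fragment`, `site`.
#' @export
substituent_foils <- function(dec, pool) {
  stopifnot(inherits(dec, "molce_decomposition"),
            inherits(pool, "substituent_pool"))
  subs <- dec$substituents
  if (nrow(subs) == 0) {
    warning("compound has no substituents; no substituent foils for ",
            dec$parent_id, call. = FALSE)
    return(.empty_foils())
  }
  rows <- list()
  n_invalid <- 0L
  for (j in seq_len(nrow(subs))) {
    for (f in pool$fragments) {
      if (f == subs$fragment[j]) next
      atts <- lapply(seq_len(nrow(subs)), function(i) {
        list(fragment = if (i == j) f else subs$fragment[i],
             site = subs$site[i])
      })
      s <- assemble_structure(dec$scaffold_mol, atts)
      if (is.na(s)) { n_invalid <- n_invalid + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = dec$parent_id, structure = s, foil_type = "substituent",
        replaced_fragment = subs$fragment[j], new_fragment = f,
        site = subs$site[j], stringsAsFactors = FALSE)
    }
  }
  if (n_invalid > 0) {
    message(n_invalid, " chemically invalid substituent assemblies dropped for ",
            dec$parent_id)
  }
  if (length(rows) == 0) return(.empty_foils())
  .finalize_foils(do.call(rbind, rows), dec$parent)
}

# Deterministic attachment-site assignment on an alternative scaffold:
# substituents are placed, in site order, on the lowest-indexed atoms (atom
# order of the canonical scaffold SMILES) with remaining free valence,
# preferring atoms not already used. Returns attachment list or NULL.
.assign_sites <- function(alt_mol, fragments) {
  fv <- free_valence(alt_mol)
  used <- rep(FALSE, alt_mol$natoms)
  atts <- vector("list", length(fragments))
  for (i in seq_along(fragments)) {
    cand <- which(fv >= 1 & !used)
    if (length(cand) == 0) cand <- which(fv >= 1)
    if (length(cand) == 0) return(NULL)
    site <- cand[1]
    fv[site] <- fv[site] - 1
    used[site] <- TRUE
    atts[[i]] <- list(fragment = fragments[i], site = site)
  }
  atts
}

#' Generate scaffold foils
#'
#' Produces virtual analogues by replacing the scaffold of a decomposed
#' compound with each qualifying alternative scaffold from the dictionary
#' (same reduced carbon skeleton, within the atom-count size filter), while
#' retaining all original substituents. Attachment sites on the alternative
#' scaffold are assigned deterministically to the lowest canonical-rank atoms
#' with free valence. Invalid assemblies are dropped; results are
#' deduplicated by canonical structure.
#'
#' @param dec a `molce_decomposition`.
#' @param dict a `skeleton_dictionary`.
#' @param size_tolerance passed to [query_scaffolds()].
#' @return data.frame as in [substituent_foils()], with `foil_type`
#'   `"scaffold"` and `site` `NA`.
#' @export
scaffold_foils <- function(dec, dict, size_tolerance = 0.15) {
  stopifnot(inherits(dec, "molce_decomposition"))
  alts <- query_scaffolds(dict, dec$scaffold, size_tolerance)
  if (length(alts) == 0) return(.empty_foils())
  rows <- list()
  n_invalid <- 0L
  for (alt in alts) {
    amol <- parse_mol(alt)
    atts <- .assign_sites(amol, dec$substituents$fragment)
    if (is.null(atts)) { n_invalid <- n_invalid + 1L; next }
    s <- assemble_structure(amol, atts)
    if (is.na(s)) { n_invalid <- n_invalid + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = dec$parent_id, structure = s, foil_type = "scaffold",
      replaced_fragment = dec$scaffold, new_fragment = alt,
      site = NA_integer_, stringsAsFactors = FALSE)
  }
  if (n_invalid > 0) {
    message(n_invalid, " scaffold assemblies without a valid site assignment ",
            "dropped for ", dec$parent_id)
  }
  if (length(rows) == 0) return(.empty_foils())
  .finalize_foils(do.call(rbind, rows), dec$parent)
}

#' Generate all foils for a set of test compounds
#'
#' Convenience driver combining [decompose_compound()],
#' [substituent_foils()] and [scaffold_foils()] over a compound table.
#'
#' @param compounds data.frame with columns `id`, `smiles`.
#' @param pool a `substituent_pool`.
#' @param dict a `skeleton_dictionary`.
#' @param size_tolerance passed to [query_scaffolds()].
#' @return data.frame of foils with an extra column `n_sites` (number of
#'   substitution sites of the parent, used by global aggregation).
#' @export
generate_foils <- function(compounds, pool, dict, size_tolerance = 0.15) {
  out <- list()
  for (i in seq_len(nrow(compounds))) {
    dec <- suppressWarnings(decompose_compound(compounds$smiles[i],
                                               id = compounds$id[i]))
    if (is.null(dec)) next
    sf <- if (nrow(dec$substituents) > 0) {
      substituent_foils(dec, pool)
    } else .empty_foils()
    cf <- scaffold_foils(dec, dict, size_tolerance)
    f <- rbind(sf, cf)
    if (nrow(f) > 0) {
      f$n_sites <- nrow(dec$substituents)
      out[[length(out) + 1L]] <- f
    }
  }
  if (length(out) == 0) {
    e <- .empty_foils(); e$n_sites <- integer(0); return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
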