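# Reference dictionary mapping reduced carbon skeletons to scaffold sets.

DICT_SCHEMA_VERSION <- "1"
CANONICALIZATION <- "openbabel-can"

#' Build a reduced carbon-skeleton dictionary
#'
#' Decomposes every compound into its Bemis-Murcko scaffold, converts each
#' unique scaffold to its carbon skeleton and reduced carbon skeleton, and
#' groups scaffolds under their reduced-skeleton key. Querying the dictionary
#' with a scaffold of interest returns topologically closely related
#' alternative scaffolds (same reduced skeleton, similar size).
#'
#' @param compounds data.frame with columns `id`, `smiles`, or a character
#'   vector of SMILES. Duplicate structures are collapsed; acyclic compounds
#'   are skipped and counted.
#' @return object of class `skeleton_dictionary` with fields `entries`
#'   (named list: reduced skeleton -> sorted scaffold vector), `source_size`,
#'   `n_scaffolds`, `n_skeletons`, `n_acyclic_skipped`.
#' @export
build_skeleton_dictionary <- function(compounds) {
  smiles <- if (is.data.frame(compounds)) compounds$smiles else compounds
  can <- unique(canonical_smiles(smiles))
  can <- can[!is.na(can)]
  if (length(can) == 0) {
    warning("no usable compounds; returning an empty dictionary", call. = FALSE)
    return(structure(list(entries = list(), source_size = 0L,
                          n_scaffolds = 0L, n_skeletons = 0L,
                          n_acyclic_skipped = 0L),
                     class = "skeleton_dictionary"))
  }
  scaf <- suppressWarnings(bemis_murcko_scaffold(can))
  n_acyclic <- sum(is.na(scaf))
  scaf <- unique(scaf[!is.na(scaf)])
  entries <- list()
  if (length(scaf) > 0) {
    keys <- reduce_skeleton(carbon_skeleton(scaf))
    entries <- split(scaf, keys)
    entries <- lapply(entries, function(x) sort(unique(x)))
    entries <- entries[sort(names(entries))]
  }
  structure(list(entries = entries, source_size = length(can),
                 n_scaffolds = length(scaf),
                 n_skeletons = length(entries),
                 n_acyclic_skipped = n_acyclic),
            class = "skeleton_dictionary")
}

#' @export
print.skeleton_dictionary <- function(x, ...) {
  cat("skeleton_dictionary:", x$n_skeletons, "reduced skeletons,",
      x$n_scaffolds, "scaffolds from", x$source_size, "compounds\n")
  invisible(x)
}

#' Query alternative scaffolds sharing a reduced carbon skeleton
#'
#' Looks up the reduced carbon skeleton of `scaffold` and returns the other
#' scaffolds stored under that key, subject to an atom-count size filter:
#' a candidate is kept when its heavy-atom count differs from the query's by
#' at most `size_tolerance` (default 15%, i.e. the 85% size cut-off).
#'
#' @param dict a `skeleton_dictionary`.
#' @param scaffold scaffold SMILES to query with.
#' @param size_tolerance maximal relative atom-count deviation, in `[0, 1)`.
#' @return character vector of alternative scaffold SMILES, canonically
#'   sorted; empty when the skeleton is absent or nothing qualifies.
#' @export
query_scaffolds <- function(dict, scaffold, size_tolerance = 0.15) {
  stopifnot(inherits(dict, "skeleton_dictionary"),
            size_tolerance >= 0, size_tolerance < 1)
  scaffold <- canonical_smiles(scaffold)
  if (is.na(scaffold)) stop("cannot parse scaffold", call. = FALSE)
  key <- reduce_skeleton(carbon_skeleton(scaffold))
  cand <- dict$entries[[key]]
  if (is.null(cand)) return(character(0))
  cand <- setdiff(cand, scaffold)
  if (length(cand) == 0) return(character(0))
  n_orig <- heavy_atom_count(scaffold)
  n_alt <- heavy_atom_count(cand)
  sort(cand[abs(n_alt - n_orig) <= size_tolerance * n_orig])
}

#' Save a skeleton dictionary to JSON
#'
#' The file carries a header (schema version, canonicalization algorithm,
#' source counts) followed by the entries as key -> sorted scaffold list.
#'
#' @param dict a `skeleton_dictionary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "skeleton_dictionary"))
  obj <- list(schema_version = DICT_SCHEMA_VERSION,
              canonicalization = CANONICALIZATION,
              source_size = dict$source_size,
              n_scaffolds = dict$n_scaffolds,
              n_skeletons = dict$n_skeletons,
              n_acyclic_skipped = dict$n_acyclic_skipped,
              entries = dict$entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a skeleton dictionary
#'
#' Reads either the JSON format written by [save_dictionary()] or a
#' two-column tab-separated file with header `skeleton<TAB>scaffold`.
#'
#' @param path file path.
#' @return a `skeleton_dictionary`.
#' @export
load_dictionary <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0) stop("empty dictionary file: ", path, call. = FALSE)
  if (grepl("^\\s*\\{", first)) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed dictionary JSON (", conditionMessage(e),
                           ")", call. = FALSE)
                    })
    need <- c("schema_version", "entries")
    if (!all(need %in% names(obj))) {
      stop("malformed dictionary file: missing header fields", call. = FALSE)
    }
    entries <- lapply(obj$entries, function(x) sort(unique(unlist(x))))
    entries <- entries[sort(names(entries))]
    structure(list(entries = entries,
                   source_size = as.integer(obj$source_size %||% NA),
                   n_scaffolds = as.integer(obj$n_scaffolds %||%
                                              length(unlist(entries))),
                   n_skeletons = length(entries),
                   n_acyclic_skipped = as.integer(obj$n_acyclic_skipped %||% 0)),
              class = "skeleton_dictionary")
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr[1:2], c("skeleton", "scaffold"))) {
      stop("malformed dictionary TSV at line 1: expected header ",
           "'skeleton<TAB>scaffold'", call. = FALSE)
    }
    body <- lines[-1]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 2)
    if (length(bad) > 0) {
      stop("malformed dictionary TSV at line ", bad[1] + 1L, call. = FALSE)
    }
    keys <- vapply(parts, `[[`, character(1), 1)
    scafs <- vapply(parts, `[[`, character(1), 2)
    entries <- lapply(split(scafs, keys), function(x) sort(unique(x)))
    entries <- entries[sort(names(entries))]
    structure(list(entries = entries, source_size = NA_integer_,
                   n_scaffolds = length(unique(scafs)),
                   n_skeletons = length(entries),
                   n_acyclic_skipped = 0L),
              class = "skeleton_dictionary")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
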