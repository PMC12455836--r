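# Internal molecular-graph layer on top of OpenBabel (via ChemmineR/ChemmineOB).
#
# Molecules are handled as plain graphs: list(elem = character vector of
# element symbols, bonds = integer matrix with columns (a, b, order),
# natoms = heavy-atom count). Hydrogens are implicit throughout; aromatic
# rings are kept in kekulized form (bond orders 1/2) as emitted by OpenBabel.
# Canonical identity of any structure is its OpenBabel canonical SMILES.

.canon_cache <- new.env(parent = emptyenv())

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings; all structure identity comparisons in the
#' package are on this form.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    hit <- get0(s, envir = .canon_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    res <- if (nzchar(out)) out else NA_character_
    assign(s, res, envir = .canon_cache)
    res
  }, character(1), USE.NAMES = FALSE)
}

is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

# Parse one SMILES into the internal graph representation.
parse_mol <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) {
    stop("cannot parse structure: ", smiles, call. = FALSE)
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elem <- sub("_\\d+$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3])))
  }
  list(elem = elem, bonds = bonds, natoms = length(elem))
}

# Serialize the internal graph as a V2000 molfile (coordinates are not
# meaningful; only connectivity matters downstream).
mol_to_molblock <- function(mol) {
  nb <- nrow(mol$bonds)
  hdr <- sprintf("\n  molce\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 mol$natoms, nb)
  at <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                mol$elem)
  bd <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0",
            mol$bonds[, 1], mol$bonds[, 2], mol$bonds[, 3])
  } else character(0)
  paste(c(hdr, at, bd, "M  END"), collapse = "\n")
}

# Canonical SMILES of an internal graph; NA when OpenBabel rejects it.
mol_to_smiles <- function(mol) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("MOL", "CAN", mol_to_molblock(mol))),
    error = function(e) ""
  )
  out <- sub("[\t\n ].*$", "", out)
  if (nzchar(out)) out else NA_character_
}

mol_degree <- function(mol) {
  deg <- integer(mol$natoms)
  if (nrow(mol$bonds) > 0) {
    tab <- table(factor(c(mol$bonds[, 1], mol$bonds[, 2]),
                        levels = seq_len(mol$natoms)))
    deg <- as.integer(tab)
  }
  deg
}

# Atom indices that are part of at least one ring (endpoints of non-bridge
# edges in the molecular graph).
ring_atoms <- function(mol) {
  if (nrow(mol$bonds) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$natoms) {
    g <- igraph::add_vertices(g, mol$natoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  sort(unique(as.integer(mol$bonds[cyc, 1:2])))
}

# Induced subgraph on `keep` (original atom order preserved within keep).
mol_subgraph <- function(mol, keep) {
  keep <- sort(unique(keep))
  idx <- match(seq_len(mol$natoms), keep)
  sel <- mol$bonds[, 1] %in% keep & mol$bonds[, 2] %in% keep
  bonds <- mol$bonds[sel, , drop = FALSE]
  if (nrow(bonds) > 0) {
    bonds[, 1] <- idx[bonds[, 1]]
    bonds[, 2] <- idx[bonds[, 2]]
  }
  list(elem = mol$elem[keep], bonds = bonds, natoms = length(keep))
}

# Standard maximum valences used to vet assembled structures; the dummy
# attachment atom "*" takes exactly one bond.
.max_valence <- c("H" = 1, "B" = 3, "C" = 4, "N" = 3, "O" = 2, "F" = 1,
                  "Si" = 4, "P" = 5, "S" = 6, "Cl" = 1, "Br" = 1, "I" = 1,
                  "*" = 1)

# Sum of bond orders per atom.
mol_bond_order_sum <- function(mol) {
  v <- numeric(mol$natoms)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      v[mol$bonds[k, 1]] <- v[mol$bonds[k, 1]] + mol$bonds[k, 3]
      v[mol$bonds[k, 2]] <- v[mol$bonds[k, 2]] + mol$bonds[k, 3]
    }
  }
  v
}

# Remaining bonding capacity per atom (unknown elements get capacity 0 extra).
free_valence <- function(mol) {
  cap <- .max_valence[mol$elem]
  cap[is.na(cap)] <- 4
  unname(cap - mol_bond_order_sum(mol))
}

mol_valence_ok <- function(mol) all(free_valence(mol) >= 0)

# Number of unique SMARTS matches per molecule.
smarts_count <- function(smiles, pattern) {
  probe <- tryCatch(
    suppressWarnings(ChemmineOB::smartsSearch_OB(
      ChemmineOB::forEachMol("SMILES", "C", identity), pattern)),
    error = function(e) NULL
  )
  if (is.null(probe)) stop("invalid substructure pattern: ", pattern, call. = FALSE)
  vapply(smiles, function(s) {
    refs <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol("SMILES", s, identity)),
      error = function(e) NULL
    )
    if (is.null(refs) || length(refs) == 0) return(NA_integer_)
    as.integer(suppressWarnings(ChemmineOB::smartsSearch_OB(refs, pattern)))
  }, integer(1), USE.NAMES = FALSE)
}
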