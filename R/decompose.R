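# Bemis-Murcko decomposition and carbon-skeleton transforms.

# Atoms belonging to the Bemis-Murcko scaffold of `mol`: the ring systems
# plus all linker atoms connecting them (iterative pruning of terminal
# atoms), plus exocyclic atoms multiply bonded to a retained atom (e.g. the
# amide carbonyl oxygen), iterated to a fixed point.
scaffold_atoms <- function(mol) {
  if (nrow(mol$bonds) == 0 || length(ring_atoms(mol)) == 0) return(integer(0))
  keep <- seq_len(mol$natoms)
  repeat {
    sub <- mol_subgraph(mol, keep)
    deg <- mol_degree(sub)
    drop <- which(deg <= 1)
    if (length(drop) == 0 || length(keep) == length(drop)) break
    keep <- keep[-drop]
  }
  # re-attach exocyclic multiply-bonded atoms (kept as part of the scaffold)
  repeat {
    multi <- mol$bonds[mol$bonds[, 3] >= 2, , drop = FALSE]
    add <- unique(c(
      multi[multi[, 1] %in% keep & !(multi[, 2] %in% keep), 2],
      multi[multi[, 2] %in% keep & !(multi[, 1] %in% keep), 1]
    ))
    if (length(add) == 0) break
    keep <- sort(c(keep, add))
  }
  sort(keep)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Returns the ring systems of a molecule together with the linker atoms
#' connecting them, with side chains removed. Exocyclic atoms that are
#' multiply bonded to a scaffold atom (such as a carbonyl oxygen on an amide
#' linker) are retained. Acyclic molecules have no scaffold and yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical scaffold SMILES; `NA` for acyclic
#'   or unparseable inputs (unparseable inputs raise an error).
#' @examples
#' bemis_murcko_scaffold("Cc1ccccc1")  # toluene -> benzene
#' @export
bemis_murcko_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is_valid_smiles(s)) {
      stop("cannot parse structure: ", s, call. = FALSE)
    }
    mol <- parse_mol(s)
    keep <- scaffold_atoms(mol)
    if (length(keep) == 0) return(NA_character_)
    mol_to_smiles(mol_subgraph(mol, keep))
  }, character(1), USE.NAMES = FALSE)
}

.elem_codes <- function(elem) as.integer(factor(elem, levels = sort(unique(elem))))

.mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol$natoms, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  }
  g
}

# Map the atoms of `mol` (an internal graph) onto the atom order obtained by
# parsing its canonical SMILES. Returns list(mol = canonical-order graph,
# perm = integer vector, perm[i] = canonical index of atom i). Any one
# element/bond-order preserving isomorphism is valid: ambiguity corresponds
# exactly to a scaffold automorphism, under which attachment sites are
# chemically equivalent.
map_to_canonical <- function(mol) {
  can <- mol_to_smiles(mol)
  if (is.na(can)) stop("structure cannot be canonicalized", call. = FALSE)
  cmol <- parse_mol(can)
  if (cmol$natoms != mol$natoms) {
    stop("canonicalization changed the heavy-atom count", call. = FALSE)
  }
  lev <- sort(unique(c(mol$elem, cmol$elem)))
  vc1 <- as.integer(factor(mol$elem, levels = lev))
  vc2 <- as.integer(factor(cmol$elem, levels = lev))
  iso <- function(ec1, ec2) {
    igraph::graph.get.isomorphisms.vf2(
      .mol_graph(mol), .mol_graph(cmol),
      vertex.color1 = vc1, vertex.color2 = vc2,
      edge.color1 = ec1, edge.color2 = ec2)
  }
  maps <- iso(mol$bonds[, 3], cmol$bonds[, 3])
  if (length(maps) == 0) {
    # aromatic rings may be re-kekulized differently on re-parse; bond
    # orders within rings are then resonance-equivalent, so coarsen them
    ring_edge <- function(m) {
      ra <- ring_atoms(m)
      as.integer(m$bonds[, 1] %in% ra & m$bonds[, 2] %in% ra)
    }
    coarse <- function(m) ifelse(ring_edge(m) == 1, 0L, m$bonds[, 3])
    maps <- iso(coarse(mol), coarse(cmol))
    if (length(maps) > 1) {
      # prefer the mapping preserving the most bond orders, so bonds with
      # fixed (non-resonant) orders are never mismapped
      key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]),
                               b[, 3])
      ck <- key(cmol$bonds)
      score <- vapply(maps, function(p) {
        img <- match(seq_len(mol$natoms), as.integer(p))
        mapped <- cbind(img[mol$bonds[, 1]], img[mol$bonds[, 2]],
                        mol$bonds[, 3])
        sum(key(mapped) %in% ck)
      }, numeric(1))
      maps <- maps[which.max(score)]
    }
  }
  if (length(maps) == 0) {
    stop("internal error: canonical re-parse is not isomorphic", call. = FALSE)
  }
  # vf2 reports, for each cmol vertex, its paired mol vertex; invert so that
  # perm[i] is the canonical index of mol atom i
  perm <- match(seq_len(mol$natoms), as.integer(maps[[1]]))
  list(mol = cmol, perm = perm, smiles = can)
}

#' Decompose a compound into scaffold and substituents
#'
#' Splits a molecule into its Bemis-Murcko scaffold and the maximal connected
#' side-chain fragments attached to it. Each substituent is reported as a
#' canonical fragment SMILES carrying a single `*` attachment marker, together
#' with the scaffold atom index it is bonded to (1-based, in the atom order of
#' the canonical scaffold SMILES).
#'
#' @param smiles a single SMILES string.
#' @param id compound identifier carried through to the result.
#' @return an object of class `molce_decomposition`: a list with elements
#'   `parent_id`, `parent` (canonical SMILES), `scaffold` (canonical SMILES),
#'   `scaffold_mol` (internal graph in canonical atom order) and
#'   `substituents` (data.frame with columns `fragment`, `site`). `NULL` for
#'   acyclic molecules (with a warning).
#' @export
decompose_compound <- function(smiles, id = smiles) {
  if (!is_valid_smiles(smiles)) {
    stop("cannot parse structure: ", smiles, call. = FALSE)
  }
  parent_can <- canonical_smiles(smiles)
  mol <- parse_mol(smiles)
  keep <- scaffold_atoms(mol)
  if (length(keep) == 0) {
    warning("acyclic molecule has no scaffold, skipped: ", id, call. = FALSE)
    return(NULL)
  }
  sub <- mol_subgraph(mol, keep)
  canmap <- map_to_canonical(sub)

  # substituents: connected components of the non-scaffold atoms
  rest <- setdiff(seq_len(mol$natoms), keep)
  subst <- data.frame(fragment = character(0), site = integer(0),
                      stringsAsFactors = FALSE)
  if (length(rest) > 0) {
    gr <- .mol_graph(mol_subgraph(mol, rest))
    comp <- igraph::components(gr)$membership
    for (ci in seq_len(max(comp))) {
      atoms <- rest[comp == ci]
      # the (unique) bond crossing from this component into the scaffold
      cross <- mol$bonds[
        (mol$bonds[, 1] %in% atoms & mol$bonds[, 2] %in% keep) |
        (mol$bonds[, 2] %in% atoms & mol$bonds[, 1] %in% keep), , drop = FALSE]
      if (nrow(cross) != 1 || cross[1, 3] != 1) {
        stop("internal error: substituent with irregular attachment", call. = FALSE)
      }
      sc_atom <- if (cross[1, 1] %in% keep) cross[1, 1] else cross[1, 2]
      fr_atom <- if (cross[1, 1] %in% keep) cross[1, 2] else cross[1, 1]
      # fragment graph: component atoms plus a dummy marker replacing the bond
      fmol <- mol_subgraph(mol, atoms)
      fmol$elem <- c(fmol$elem, "*")
      fmol$natoms <- fmol$natoms + 1L
      fmol$bonds <- rbind(fmol$bonds,
                          c(match(fr_atom, sort(atoms)), fmol$natoms, 1L))
      frag <- mol_to_smiles(fmol)
      site_sub <- match(sc_atom, keep)
      subst <- rbind(subst, data.frame(
        fragment = frag, site = canmap$perm[site_sub],
        stringsAsFactors = FALSE))
    }
    subst <- subst[order(subst$site, subst$fragment), , drop = FALSE]
    rownames(subst) <- NULL
  }
  structure(list(parent_id = id, parent = parent_can,
                 scaffold = canmap$smiles, scaffold_mol = canmap$mol,
                 substituents = subst),
            class = "molce_decomposition")
}

#' Extract substituents relative to a given scaffold
#'
#' Convenience wrapper around [decompose_compound()] that verifies the
#' supplied scaffold is the Bemis-Murcko scaffold of the molecule and returns
#' the substituent table.
#'
#' @param smiles a single SMILES string.
#' @param scaffold scaffold SMILES the decomposition must agree with.
#' @return data.frame with columns `fragment` (canonical, one `*` marker)
#'   and `site` (atom index in the canonical scaffold SMILES).
#' @export
extract_substituents <- function(smiles, scaffold) {
  dec <- decompose_compound(smiles)
  if (is.null(dec)) stop("acyclic molecule has no scaffold", call. = FALSE)
  if (!identical(dec$scaffold, canonical_smiles(scaffold))) {
    stop("supplied scaffold is not the scaffold of the molecule", call. = FALSE)
  }
  dec$substituents
}

#' Carbon skeleton of a scaffold
#'
#' Replaces every atom by carbon and sets every bond order to one, removing
#' aromaticity. The heavy-atom count is preserved.
#'
#' @param smiles character vector of scaffold SMILES.
#' @return character vector of canonical carbon-skeleton SMILES.
#' @export
carbon_skeleton <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- parse_mol(s)
    mol$elem[] <- "C"
    if (nrow(mol$bonds) > 0) mol$bonds[, 3] <- 1L
    mol_to_smiles(mol)
  }, character(1), USE.NAMES = FALSE)
}

#' Reduced carbon skeleton
#'
#' Contracts all acyclic linker atoms with exactly two bonded neighbours out
#' of a carbon skeleton, joining their neighbours directly, iterated to a
#' fixed point. Ring atoms and terminal (degree-1) atoms are never removed,
#' so skeletons differing only in linker lengths collapse to the same
#' reduced skeleton. The operation is idempotent.
#'
#' @param smiles character vector of carbon-skeleton SMILES.
#' @return character vector of canonical reduced-skeleton SMILES.
#' @export
reduce_skeleton <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- parse_mol(s)
    # ring membership is invariant under contraction of acyclic atoms, so
    # it is computed once and carried through the index shifts
    is_ring <- seq_len(mol$natoms) %in% ring_atoms(mol)
    repeat {
      deg <- mol_degree(mol)
      cand <- setdiff(which(deg == 2), which(is_ring))
      if (length(cand) == 0) break
      a <- cand[1]
      nb <- unique(c(mol$bonds[mol$bonds[, 1] == a, 2],
                     mol$bonds[mol$bonds[, 2] == a, 1]))
      keep_bonds <- mol$bonds[mol$bonds[, 1] != a & mol$bonds[, 2] != a, ,
                              drop = FALSE]
      already <- any((keep_bonds[, 1] == nb[1] & keep_bonds[, 2] == nb[2]) |
                     (keep_bonds[, 1] == nb[2] & keep_bonds[, 2] == nb[1]))
      if (!already) keep_bonds <- rbind(keep_bonds, c(nb[1], nb[2], 1L))
      # drop atom a, reindex
      idx <- match(seq_len(mol$natoms), setdiff(seq_len(mol$natoms), a))
      keep_bonds[, 1] <- idx[keep_bonds[, 1]]
      keep_bonds[, 2] <- idx[keep_bonds[, 2]]
      mol <- list(elem = mol$elem[-a], bonds = keep_bonds,
                  natoms = mol$natoms - 1L)
      is_ring <- is_ring[-a]
    }
    mol_to_smiles(mol)
  }, character(1), USE.NAMES = FALSE)
}

#' Heavy-atom count of a structure
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector of heavy-atom (non-hydrogen) counts.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) parse_mol(s)$natoms, integer(1), USE.NAMES = FALSE)
}

#' Decompose a compound table
#'
#' Applies [decompose_compound()] to every row of a compound table and
#' returns one row per (compound, substituent); compounds whose scaffold is
#' the whole molecule appear with an empty fragment entry. Acyclic compounds
#' are skipped with a warning.
#'
#' @param compounds data.frame with columns `id` and `smiles`.
#' @return data.frame with columns `id`, `scaffold`, `fragment`, `site`.
#' @export
decompose_table <- function(compounds) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  out <- lapply(seq_len(nrow(compounds)), function(i) {
    dec <- decompose_compound(compounds$smiles[i], id = compounds$id[i])
    if (is.null(dec)) return(NULL)
    if (nrow(dec$substituents) == 0) {
      data.frame(id = dec$parent_id, scaffold = dec$scaffold,
                 fragment = NA_character_, site = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = dec$parent_id, scaffold = dec$scaffold,
                 fragment = dec$substituents$fragment,
                 site = dec$substituents$site, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
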