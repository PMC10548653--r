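# Bemis-Murcko framework extraction and hierarchical scaffold enumeration.
#
# The level-0 scaffold is the classical ring-plus-linker framework with
# exocyclic multiply-bonded atoms retained.  Deeper levels are produced by
# deleting one peripheral SSSR ring at a time (keeping the remainder
# connected) and re-pruning, which emulates second-level scaffold-network
# extraction without a dependency.

#' Atom indices of the Bemis-Murcko framework
#'
#' Non-ring terminal atoms are pruned iteratively; atoms attached to the
#' remaining framework by a double or triple bond (e.g. a linker carbonyl
#' oxygen) are then restored.
#'
#' @param mol an `shmol` object.
#' @return integer vector of atom indices (empty for acyclic molecules).
#' @export
murcko_atoms <- function(mol) {
  n <- mol_natoms(mol)
  if (!any(mol$ring_atom)) return(integer(0))
  keep <- rep(TRUE, n)
  repeat {
    deg <- rep(0L, n)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
    }
    drop <- keep & deg <= 1L & !mol$ring_atom
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # restore atoms multiply bonded to the framework
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] < 2L || mol$bonds$arom[k]) next
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (keep[i] && !keep[j]) { keep[j] <- TRUE; added <- TRUE }
      else if (keep[j] && !keep[i]) { keep[i] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  which(keep)
}

# scaffold as its own molecule; cut-bond hydrogens restored by mol_subset
murcko_scaffold_mol <- function(mol) {
  at <- murcko_atoms(mol)
  if (length(at) == 0L) return(NULL)
  mol_subset(mol, at)
}

#' Number of SSSR rings in a molecule
#' @param mol an `shmol` object.
#' @return integer scalar.
#' @export
n_rings <- function(mol) length(mol$rings)

# is a given SSSR ring (atom index vector) a bare benzene ring?
is_benzene_ring <- function(mol, ring) {
  length(ring) == 6L && all(mol$elem[ring] == "C") && all(mol$arom[ring])
}

#' Count SSSR rings that are not benzene rings
#' @param mol an `shmol` object.
#' @return integer scalar.
#' @export
n_rings_non_benzene <- function(mol) {
  sum(!vapply(mol$rings, function(r) is_benzene_ring(mol, r), logical(1)))
}

#' A scaffold record for a scaffold SMILES
#'
#' @param smiles scaffold SMILES (canonicalized internally).
#' @param level hierarchy level (0 = Bemis-Murcko framework).
#' @return list with class `scaffold_record`: `smiles`,
#'   `n_rings_non_benzene`, `n_heavy`, `n_rotatable`, `level`.
#' @export
scaffold_record <- function(smiles, level = 0L) {
  m <- parse_smiles(smiles)
  structure(list(smiles = write_smiles(m),
                 n_rings_non_benzene = n_rings_non_benzene(m),
                 n_heavy = n_heavy_atoms(m),
                 n_rotatable = n_rotatable_bonds(m),
                 level = as.integer(level)),
            class = "scaffold_record")
}

#' Extract the hierarchical scaffold set of a molecule
#'
#' Returns the Bemis-Murcko framework plus every sub-scaffold reachable by
#' repeatedly deleting one peripheral ring (a ring whose removal leaves the
#' framework connected) until a single ring remains, deduplicated by
#' canonical SMILES.  Acyclic molecules return an empty list.
#'
#' @param mol an `shmol` object or SMILES string.
#' @return list of [scaffold_record()] objects ordered by level then SMILES.
#' @export
extract_scaffold_hierarchy <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  root <- murcko_scaffold_mol(mol)
  if (is.null(root)) return(list())
  seen <- new.env(hash = TRUE)
  out <- list()
  visit <- function(m, level) {
    smi <- write_smiles(m)
    key <- smi
    if (!is.null(seen[[key]])) {
      if (seen[[key]] <= level) return(invisible(NULL))
    }
    seen[[key]] <- level
    out[[key]] <<- scaffold_record(smi, level)
    if (n_rings(m) <= 1L) return(invisible(NULL))
    for (ri in seq_along(m$rings)) {
      ring <- m$rings[[ri]]
      shared <- unique(unlist(m$rings[-ri]))
      delatoms <- setdiff(ring, shared)
      if (length(delatoms) == 0L) next        # fully fused into others
      rest <- setdiff(seq_len(mol_natoms(m)), delatoms)
      if (length(rest) == 0L) next
      sub <- mol_subset(m, rest)
      if (max(mol_components(sub)) != 1L) next  # removal disconnects
      sub2 <- murcko_scaffold_mol(sub)
      if (is.null(sub2)) next
      visit(sub2, level + 1L)
    }
    invisible(NULL)
  }
  visit(root, 0L)
  recs <- unname(out)
  ord <- order(vapply(recs, `[[`, integer(1), "level"),
               vapply(recs, `[[`, character(1), "smiles"))
  recs[ord]
}

#' The scaffold pass/fail filter
#'
#' A scaffold passes iff it has at least one ring that is not a bare benzene
#' ring, at most `max_heavy` heavy atoms, and at most `max_rotatable`
#' rotatable bonds.
#'
#' @param s a [scaffold_record()] or scaffold SMILES string.
#' @param max_heavy heavy-atom ceiling (default 20).
#' @param max_rotatable rotatable-bond ceiling (default 3).
#' @return logical scalar.
#' @export
filter_scaffold <- function(s, max_heavy = 20L, max_rotatable = 3L) {
  if (is.character(s)) s <- scaffold_record(s)
  s$n_rings_non_benzene >= 1L &&
    s$n_heavy <= max_heavy &&
    s$n_rotatable <= max_rotatable
}

#' Atom indices of a scaffold within its parent molecule
#'
#' Finds one induced substructure match of the scaffold in the molecule.
#' Matches that would leave a ring atom of the molecule unmatched when an
#' equivalent all-ring match exists are not preferred specially; the first
#' match in deterministic VF2 order is returned.
#'
#' @param mol parent `shmol` (or SMILES).
#' @param scaffold scaffold `shmol` (or SMILES).
#' @return ordered integer vector of 1-based atom indices into `mol`.
#' @export
scaffold_atom_mask <- function(mol, scaffold) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.character(scaffold)) scaffold <- parse_smiles(scaffold)
  mm <- match_substructure(scaffold, mol, induced = TRUE, max_matches = 32L)
  if (length(mm) == 0L) {
    # sub-scaffolds produced by deleting a fused aromatic ring are
    # re-kekulized, so their bond types no longer agree with the parent;
    # fall back to connectivity-level matching
    mm <- match_substructure(scaffold, mol, induced = TRUE, max_matches = 32L,
                             match_arom = FALSE, match_bond = FALSE)
  }
  if (length(mm) == 0L)
    stop("inconsistent_pair: scaffold is not a substructure of the molecule")
  # deterministic choice: lexicographically smallest sorted index set
  sets <- lapply(mm, sort)
  keys <- vapply(sets, paste, character(1), collapse = ",")
  sets[[order(keys)[1]]]
}
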