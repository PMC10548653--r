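# Substructure matching (VF2 on colored graphs) and path fingerprints.

mol_to_igraph <- function(mol) {
  n <- mol_natoms(mol)
  if (nrow(mol$bonds) > 0L) {
    el <- rbind(mol$bonds$a1, mol$bonds$a2)
    g <- igraph::make_graph(edges = as.integer(el), n = n, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
  }
  g
}

# integer color encoding shared between pattern and target
match_colors <- function(mols, use_charge = TRUE, use_arom = TRUE,
                         use_bond = TRUE) {
  akeys <- lapply(mols, function(m)
    paste(m$elem,
          if (use_arom) m$arom else "",
          if (use_charge) m$charge else "", sep = "|"))
  bkeys <- lapply(mols, function(m)
    if (nrow(m$bonds) > 0L) {
      if (use_bond) ifelse(m$bonds$arom, "ar", as.character(m$bonds$order))
      else rep("b", nrow(m$bonds))
    } else character(0))
  alev <- sort(unique(unlist(akeys)))
  blev <- sort(unique(unlist(bkeys)))
  list(atom = lapply(akeys, function(k) as.integer(factor(k, levels = alev))),
       bond = lapply(bkeys, function(k) as.integer(factor(k, levels = blev))))
}

#' Find substructure matches of a pattern molecule in a target molecule
#'
#' Matching is a labeled monomorphism (SMARTS-like): elements, aromatic
#' flags, formal charges and bond orders must agree; hydrogen counts are
#' ignored.  With `induced = TRUE` matches whose mapped atom set carries
#' extra target bonds are discarded.
#'
#' @param pattern,target `shmol` objects.
#' @param induced require the mapped subgraph to be induced.
#' @param max_matches stop after this many matches.
#' @param match_arom require aromatic flags to agree (atom and bond level).
#' @param match_bond require bond orders to agree; with `FALSE` any bond
#'   matches any bond (used to locate de-aromatized sub-scaffolds in their
#'   aromatic parent).
#' @return list of integer vectors; element `i` of a vector is the target
#'   atom matched to pattern atom `i`.
#' @export
match_substructure <- function(pattern, target, induced = FALSE,
                               max_matches = 10000L,
                               match_arom = TRUE, match_bond = TRUE) {
  np <- mol_natoms(pattern); nt <- mol_natoms(target)
  if (np > nt) return(list())
  cols <- match_colors(list(pattern, target), use_arom = match_arom,
                       use_bond = match_bond)
  gp <- mol_to_igraph(pattern); gt <- mol_to_igraph(target)
  # color1 belongs to the target graph, color2 to the pattern (igraph order)
  maps <- igraph::subgraph_isomorphisms(
    pattern = gp, target = gt, method = "vf2",
    vertex.color1 = cols$atom[[2]], vertex.color2 = cols$atom[[1]],
    edge.color1 = cols$bond[[2]], edge.color2 = cols$bond[[1]])
  out <- lapply(maps, function(m) as.integer(m))
  if (induced && length(out) > 0L) {
    npb <- nrow(pattern$bonds)
    keep <- vapply(out, function(mp) {
      sub <- target$bonds$a1 %in% mp & target$bonds$a2 %in% mp
      sum(sub) == npb
    }, logical(1))
    out <- out[keep]
  }
  if (length(out) > max_matches) out <- out[seq_len(max_matches)]
  out
}

#' Test whether a pattern occurs as a substructure of a target
#' @inheritParams match_substructure
#' @return logical scalar.
#' @export
has_substructure <- function(pattern, target, induced = FALSE) {
  length(match_substructure(pattern, target, induced = induced,
                            max_matches = 1L)) > 0L
}

# deterministic polynomial string hash modulo a Mersenne prime; all
# intermediates stay below 2^53 so double arithmetic is exact
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

#' Hashed linear-path topological fingerprint
#'
#' Enumerates all simple linear atom paths of length 1..`max_len` bonds,
#' labels each by the element/aromaticity sequence and bond orders along it
#' (in the direction-independent minimal form), and hashes each label into a
#' fixed-size bit set.
#'
#' @param mol an `shmol` object.
#' @param max_len maximum path length in bonds (default 7).
#' @param n_bits fingerprint width (default 2048).
#' @return sorted integer vector of set bit positions (0-based).
#' @export
path_fingerprint <- function(mol, max_len = 7L, n_bits = 2048L) {
  n <- mol_natoms(mol)
  adj <- mol_adjacency(mol)
  bond_of <- function(i, j) which(mol$bonds$a1 == min(i, j) & mol$bonds$a2 == max(i, j))
  atom_lab <- paste0(ifelse(mol$arom, tolower(mol$elem), mol$elem),
                     ifelse(mol$charge != 0L, sprintf("%+d", mol$charge), ""))
  bond_lab_tab <- if (nrow(mol$bonds) > 0L)
    ifelse(mol$bonds$arom, ":", c("-", "=", "#", "$")[mol$bonds$order]) else character(0)

  labels <- character(0)
  # depth-first enumeration of simple paths from every atom
  walk <- function(path, lab) {
    v <- path[length(path)]
    for (u in adj[[v]]) {
      if (u %in% path) next
      k <- bond_of(v, u)
      lab2 <- c(lab, bond_lab_tab[k], atom_lab[u])
      fwd <- paste(lab2, collapse = "")
      rev_ <- paste(rev(lab2), collapse = "")
      labels[[length(labels) + 1L]] <<- if (fwd <= rev_) fwd else rev_
      if ((length(lab2) - 1L) / 2L < max_len) walk(c(path, u), lab2)
    }
  }
  for (a in seq_len(n)) {
    labels[[length(labels) + 1L]] <- atom_lab[a]
    walk(a, atom_lab[a])
  }
  labels <- unique(unlist(labels))
  bits <- vapply(labels, function(l) str_hash(l) %% n_bits, numeric(1))
  sort(unique(as.integer(bits)))
}

#' Tanimoto similarity of two bit sets
#' @param a,b integer vectors of set bit positions.
#' @return numeric in `[0, 1]`; two empty sets have similarity 1.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Tanimoto similarity of two molecules' path fingerprints
#' @param s1,s2 SMILES strings.
#' @param ... passed to [path_fingerprint()].
#' @return numeric in `[0, 1]`.
#' @export
fingerprint_similarity <- function(s1, s2, ...) {
  tanimoto(path_fingerprint(parse_smiles(s1), ...),
           path_fingerprint(parse_smiles(s2), ...))
}
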