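# Molecular graph featurization for the encoder.

one_hot <- function(idx, width) {
  v <- numeric(width)
  if (!is.na(idx) && idx >= 1L && idx <= width) v[idx] <- 1
  v
}

#' Featurize a molecule as a graph for the encoder
#'
#' Node features: atom-type one-hot over the config alphabet (unknown
#' elements map to the reserved `other` slot), degree one-hot (0-5),
#' total-valence one-hot (0-6), formal charge, aromaticity and ring
#' membership flags.  Edge features: bond-type one-hot
#' (single/double/triple/aromatic), conjugation and ring flags.
#' Featurization is deterministic.
#'
#' @param mol an `shmol` object or SMILES string.
#' @param config an [sh_config()].
#' @return a `molecule_graph` list with feature matrices, the directed-edge
#'   index tables and the aggregation matrices used by message passing.
#' @export
featurize <- function(mol, config = sh_config()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  deg <- mol_degree(mol)

  # total valence: heavy-bond order sum (aromatic as 1.5, rounded) plus H
  osum <- rep(0, n)
  unsat <- rep(FALSE, n)
  if (nb > 0L) for (k in seq_len(nb)) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    o <- if (mol$bonds$arom[k]) 1.5 else mol$bonds$order[k]
    osum[i] <- osum[i] + o; osum[j] <- osum[j] + o
    if (mol$bonds$arom[k] || mol$bonds$order[k] >= 2L) { unsat[i] <- TRUE; unsat[j] <- TRUE }
  }
  valence <- as.integer(round(osum)) + mol$hcount

  ntypes <- length(config$atom_types)
  X <- matrix(0, n, config$dx)
  for (a in seq_len(n)) {
    t_idx <- match(mol$elem[a], config$atom_types)
    if (is.na(t_idx)) t_idx <- match("other", config$atom_types)
    X[a, ] <- c(one_hot(t_idx, ntypes),
                one_hot(min(deg[a], 5L) + 1L, 6L),
                one_hot(min(valence[a], 6L) + 1L, 7L),
                mol$charge[a],
                as.numeric(mol$arom[a]),
                as.numeric(mol$ring_atom[a]))
  }

  E <- matrix(0, max(nb, 0L), config$de)
  if (nb > 0L) for (k in seq_len(nb)) {
    type <- if (mol$bonds$arom[k]) 4L else min(mol$bonds$order[k], 3L)
    conj <- mol$bonds$arom[k] ||
      (mol$bonds$order[k] >= 2L) ||
      (unsat[mol$bonds$a1[k]] && unsat[mol$bonds$a2[k]])
    E[k, ] <- c(one_hot(type, 4L), as.numeric(conj),
                as.numeric(mol$ring_bond[k]))
  }

  # directed edges: 2 per bond
  if (nb > 0L) {
    src <- c(mol$bonds$a1, mol$bonds$a2)
    dst <- c(mol$bonds$a2, mol$bonds$a1)
    bond <- c(seq_len(nb), seq_len(nb))
    rev_idx <- c(seq_len(nb) + nb, seq_len(nb))
  } else {
    src <- dst <- bond <- rev_idx <- integer(0)
  }
  ndir <- length(src)

  # Agg[v, k] = 1 iff directed edge k points into v
  Agg <- matrix(0, n, ndir)
  if (ndir > 0L) Agg[cbind(dst, seq_len(ndir))] <- 1
  # Ssrc[k, u] = 1 iff directed edge k starts at u
  Ssrc <- matrix(0, ndir, n)
  if (ndir > 0L) Ssrc[cbind(seq_len(ndir), src)] <- 1
  # B[k, j] = 1 iff edge j feeds edge k: dst(j) == src(k) and j != rev(k)
  B <- matrix(0, ndir, ndir)
  if (ndir > 0L) {
    for (k in seq_len(ndir)) {
      js <- which(dst == src[k])
      js <- js[js != rev_idx[k]]
      B[k, js] <- 1
    }
  }

  structure(list(n = n, nb = nb, ndir = ndir, X = X, E = E,
                 src = src, dst = dst, bond = bond, rev = rev_idx,
                 Agg = Agg, Ssrc = Ssrc, B = B),
            class = "molecule_graph")
}

# reorder the atoms of an shmol (for permutation-invariance testing)
permute_mol <- function(mol, perm) {
  inv <- order(perm)   # inv[old] = new position
  b <- mol$bonds
  na1 <- inv[b$a1]; na2 <- inv[b$a2]
  b$a1 <- pmin(na1, na2); b$a2 <- pmax(na1, na2)
  m <- structure(list(elem = mol$elem[perm], arom = mol$arom[perm],
                      charge = mol$charge[perm], hcount = mol$hcount[perm],
                      bonds = b), class = "shmol")
  rm2 <- ring_membership(m)
  m$ring_atom <- rm2$atom; m$ring_bond <- rm2$bond; m$rings <- rm2$rings
  m
}
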