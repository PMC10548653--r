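# Canonical SMILES generation.
#
# Atom ranks come from BLISS canonical labeling of a colored graph in which
# bond types are encoded as subdivision vertices, so the ranking is a pure
# function of the abstract molecular graph: any atom ordering of the same
# molecule yields the same canonical string, and canonicalization is
# idempotent.

atom_color_key <- function(mol) {
  paste(mol$elem, mol$arom, mol$charge, mol$hcount, sep = "|")
}

bond_color_key <- function(mol) {
  ifelse(mol$bonds$arom, "ar", as.character(mol$bonds$order))
}

# canonical rank per atom (1 = first atom written)
canonical_ranks <- function(mol) {
  n <- mol_natoms(mol)
  if (n == 1L) return(1L)
  nb <- nrow(mol$bonds)
  # build auxiliary graph: atoms 1..n, one subdivision vertex per bond
  edges <- integer(0)
  for (k in seq_len(nb)) {
    bv <- n + k
    edges <- c(edges, mol$bonds$a1[k], bv, bv, mol$bonds$a2[k])
  }
  g <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  akey <- atom_color_key(mol)
  bkey <- paste0("bond:", bond_color_key(mol))
  allkey <- c(akey, bkey)
  colors <- as.integer(factor(allkey, levels = sort(unique(allkey))))
  cp <- igraph::canonical_permutation(g, colors = colors)
  lab <- cp$labeling[seq_len(n)]          # canonical label per atom vertex
  rank(lab)                               # 1..n order among atoms
}

# does this atom need brackets when written in canonical form?
needs_bracket <- function(mol, a, osum, narb, exo) {
  if (mol$charge[a] != 0L) return(TRUE)
  if (!(mol$elem[a] %in% ORGANIC_SUBSET)) return(TRUE)
  implied <- implied_hcount(mol$elem[a], mol$arom[a], 0L, osum[a], narb[a], exo[a])
  implied != mol$hcount[a]
}

atom_token <- function(mol, a, osum, narb, exo) {
  sym <- if (mol$arom[a]) tolower(mol$elem[a]) else mol$elem[a]
  if (!needs_bracket(mol, a, osum, narb, exo)) return(sym)
  h <- mol$hcount[a]
  hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- mol$charge[a]
  cstr <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
  paste0("[", sym, hstr, cstr, "]")
}

bond_token <- function(mol, k, from, to) {
  if (mol$bonds$arom[k]) {
    return("")   # aromatic bonds are implicit between lowercase atoms
  }
  ord <- mol$bonds$order[k]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  if (ord == 4L) return("$")
  # explicit single between two aromatic atoms (biphenyl-type link)
  if (mol$arom[from] && mol$arom[to]) return("-")
  ""
}

#' Write a molecule as canonical SMILES
#'
#' The output is invariant to the atom ordering of the input object and
#' round-trips through [parse_smiles()] (idempotent canonicalization).
#' Aromatic systems are written in lowercase notation; stereochemistry is
#' not emitted.
#'
#' @param mol an `shmol` object.
#' @return a SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  comp <- mol_components(mol)
  rk <- canonical_ranks(mol)
  adj <- mol_adjacency(mol)
  bond_of <- function(i, j) which(mol$bonds$a1 == min(i, j) & mol$bonds$a2 == max(i, j))

  osum <- rep(0, n); narb <- rep(0L, n); exo <- rep(FALSE, n)
  if (nb > 0L) for (k in seq_len(nb)) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    o <- if (mol$bonds$arom[k]) 1.5 else mol$bonds$order[k]
    osum[i] <- osum[i] + o; osum[j] <- osum[j] + o
    if (mol$bonds$arom[k]) { narb[i] <- narb[i] + 1L; narb[j] <- narb[j] + 1L }
    else if (mol$bonds$order[k] >= 2L) { exo[i] <- TRUE; exo[j] <- TRUE }
  }

  # ring-closure bookkeeping
  visited <- rep(FALSE, n)
  closure_digit <- 0L
  open_closures <- list()  # per atom: list of (digit, bondtok)
  ring_bond_pairs <- list()

  # decide DFS tree: ring-closure bonds are back edges discovered on the fly
  frag_strings <- character(0)
  for (cmp in sort(unique(comp))) {
    atoms <- which(comp == cmp)
    start <- atoms[which.min(rk[atoms])]
    used_bond <- rep(FALSE, nb)
    closures <- vector("list", n)

    # first pass: DFS in canonical order, find back edges, assign digits
    order_stack <- list(list(atom = start, parent = NA_integer_))
    dfs_visited <- rep(FALSE, n)
    back_edges <- list()
    dfs <- function(v) {
      dfs_visited[v] <<- TRUE
      nbrs <- adj[[v]]
      nbrs <- nbrs[order(rk[nbrs])]
      for (u in nbrs) {
        k <- bond_of(v, u)
        if (used_bond[k]) next
        if (dfs_visited[u]) {
          used_bond[k] <<- TRUE
          back_edges[[length(back_edges) + 1L]] <<- c(v, u, k)
        } else {
          used_bond[k] <<- TRUE
          dfs(u)
        }
      }
    }
    dfs(start)
    # assign closure digits in deterministic order of discovery
    digit_map <- list()
    for (be in back_edges) {
      closure_digit <- closure_digit + 1L
      d <- closure_digit
      v <- be[1]; u <- be[2]; k <- be[3]
      closures[[v]] <- c(closures[[v]], list(list(digit = d, bond = k, other = u)))
      closures[[u]] <- c(closures[[u]], list(list(digit = d, bond = k, other = v)))
    }

    # second pass: write string
    used_bond2 <- rep(FALSE, nb)
    wr_visited <- rep(FALSE, n)
    digit_str <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
    emit <- function(v, parent_bond) {
      wr_visited[v] <<- TRUE
      out <- atom_token(mol, v, osum, narb, exo)
      # ring-closure digits at this atom
      if (!is.null(closures[[v]])) {
        for (cl in closures[[v]]) {
          k <- cl$bond
          # bond symbol on the closure written at the first endpoint only
          btok <- bond_token(mol, k, v, cl$other)
          if (used_bond2[k]) {
            out <- paste0(out, digit_str(cl$digit))
          } else {
            used_bond2[k] <<- TRUE
            out <- paste0(out, btok, digit_str(cl$digit))
          }
        }
      }
      nbrs <- adj[[v]]
      nbrs <- nbrs[order(rk[nbrs])]
      children <- integer(0)
      for (u in nbrs) {
        k <- bond_of(v, u)
        if (wr_visited[u] || used_bond2[k]) next
        children <- c(children, u)
      }
      for (ci in seq_along(children)) {
        u <- children[ci]
        k <- bond_of(v, u)
        if (used_bond2[k] || wr_visited[u]) next
        used_bond2[k] <- TRUE
        used_bond2[k] <<- TRUE
        sub <- paste0(bond_token(mol, k, v, u), emit(u, k))
        if (ci < length(children)) sub <- paste0("(", sub, ")")
        out <- paste0(out, sub)
      }
      out
    }
    # mark back-edge bonds as "used" so the writer treats them via digits
    for (be in back_edges) used_bond2[be[3]] <- FALSE
    frag_strings <- c(frag_strings, emit(start, NA_integer_))
  }
  paste(frag_strings, collapse = ".")
}

#' Canonicalize a SMILES string
#'
#' Parses and re-writes the SMILES in canonical form.  The map is
#' idempotent: `canonical_smiles(canonical_smiles(s)) == canonical_smiles(s)`.
#'
#' @param s a SMILES string.
#' @return the canonical SMILES string.
#' @export
canonical_smiles <- function(s) write_smiles(parse_smiles(s))
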