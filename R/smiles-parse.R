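# SMILES reading and molecular perception.
#
# Molecules are plain R lists of class "shmol":
#   elem    character element symbols ("C", "N", "Cl", ...)
#   arom    logical aromatic flag per atom
#   charge  integer formal charge per atom
#   hcount  integer total hydrogen count per atom (resolved at parse time)
#   bonds   data.frame(a1, a2, order, arom) with 1-based atom indices, a1 < a2
# Ring perception, aromaticity and hydrogen counts are resolved once at parse
# time; downstream code treats the object as immutable.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

# default valences; vectors allow hypervalent states (smallest feasible is used)
DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904,
  Se = 78.971
)

# single regex shared by the chemistry parser and the decoder tokenizer
SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]",      # bracket atom
  "|Br|Cl",             # two-letter organic elements
  "|%[0-9]{2}",         # two-digit ring closure
  "|[A-Za-z0-9]",       # element letters / aromatic atoms / ring digits
  "|[-=#:$/\\\\().+@*]" # bonds, branches, dot, misc
)

#' Split a SMILES string into syntactic tokens
#'
#' Bracket atoms (`[...]`), two-letter elements (`Cl`, `Br`) and two-digit
#' ring closures (`%NN`) are single tokens; every other character stands
#' alone.  The concatenation of the tokens reproduces the input exactly.
#'
#' @param s a SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokens <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("SMILES must be a non-empty string")
  if (grepl("\\[[^]]*$", s, perl = TRUE))
    stop("unterminated bracket atom in SMILES")
  m <- gregexpr(SMILES_TOKEN_RE, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (paste(toks, collapse = "") != s)
    stop("SMILES contains characters outside the token alphabet: ", s)
  toks
}

parse_bracket_atom <- function(tok) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  re <- "^([0-9]*)([A-Za-z][a-z]?|\\*)((?:@+|@TH[12]|@AL[12])?)(H[0-9]*)?((?:\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9]))?(:[0-9]+)?$"
  mm <- regexec(re, body)
  parts <- regmatches(body, mm)[[1]]
  if (length(parts) == 0L) stop("unparsable bracket atom: ", tok)
  elem_raw <- parts[3]
  arom <- elem_raw %in% AROMATIC_ELEMS
  elem <- if (arom) toupper(elem_raw) else elem_raw
  hpart <- parts[5]
  hcount <- if (is.na(hpart) || !nzchar(hpart)) 0L
            else if (hpart == "H") 1L
            else as.integer(substr(hpart, 2L, nchar(hpart)))
  cpart <- parts[6]
  charge <- 0L
  if (!is.na(cpart) && nzchar(cpart)) {
    if (grepl("^[+-][0-9]$", cpart)) {
      charge <- as.integer(substr(cpart, 2L, 2L))
      if (substr(cpart, 1L, 1L) == "-") charge <- -charge
    } else {
      charge <- nchar(cpart) * (if (substr(cpart, 1L, 1L) == "+") 1L else -1L)
    }
  }
  list(elem = elem, arom = arom, charge = charge, hcount = hcount,
       explicit_h = TRUE)
}

#' Parse a SMILES string into a molecule object
#'
#' Supports the organic subset, bracket atoms with charge and hydrogen
#' counts, branches, ring closures (including `%NN`), aromatic lowercase
#' notation, multi-fragment input via `.` and directional bonds (`/`, `\\`)
#' which are read as single bonds (stereochemistry is not modelled).
#' Aromaticity is perceived on kekulized input, hydrogen counts are filled
#' in from standard valences, and basic valence sanity is enforced.
#'
#' @param s a SMILES string.
#' @return an object of class `shmol`, or an error if unparsable.
#' @export
parse_smiles <- function(s) {
  toks <- smiles_tokens(s)
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hcount <- integer(0); expl_h <- logical(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- integer(0); b_arom <- logical(0)
  b_default <- logical(0)  # bond written without a symbol between aromatic atoms

  prev <- NA_integer_         # atom awaiting the next bond
  stack <- integer(0)         # branch stack
  pending_bond <- NULL        # explicit bond symbol waiting for next atom
  ring_open <- list()         # closure digit -> list(atom, bond)

  add_atom <- function(a) {
    elem <<- c(elem, a$elem); arom <<- c(arom, a$arom)
    charge <<- c(charge, a$charge); hcount <<- c(hcount, a$hcount)
    expl_h <<- c(expl_h, a$explicit_h)
    length(elem)
  }
  add_bond <- function(i, j, sym) {
    if (i == j) stop("self bond in SMILES")
    ord <- 1L; ar <- FALSE; def <- FALSE
    if (is.null(sym)) {
      if (arom[i] && arom[j]) { ar <- TRUE; def <- TRUE }
    } else if (sym == "-") { ord <- 1L
    } else if (sym == "=") { ord <- 2L
    } else if (sym == "#") { ord <- 3L
    } else if (sym == "$") { ord <- 4L
    } else if (sym == ":") { ar <- TRUE
    } else if (sym %in% c("/", "\\")) { ord <- 1L
    } else stop("unknown bond symbol: ", sym)
    b_a1 <<- c(b_a1, min(i, j)); b_a2 <<- c(b_a2, max(i, j))
    b_ord <<- c(b_ord, ord); b_arom <<- c(b_arom, ar); b_default <<- c(b_default, def)
  }

  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first == "[") {
      a <- parse_bracket_atom(tok)
      idx <- add_atom(a)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NULL; prev <- idx
    } else if (tok %in% ORGANIC_SUBSET || tok %in% AROMATIC_ELEMS) {
      a <- list(elem = if (tok %in% AROMATIC_ELEMS) toupper(tok) else tok,
                arom = tok %in% AROMATIC_ELEMS, charge = 0L, hcount = NA_integer_,
                explicit_h = FALSE)
      idx <- add_atom(a)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NULL; prev <- idx
    } else if (grepl("^[0-9]$", tok) || first == "%") {
      key <- if (first == "%") substr(tok, 2L, 3L) else tok
      if (is.na(prev)) stop("ring closure before any atom")
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        sym <- pending_bond
        if (is.null(sym)) sym <- op$bond
        else if (!is.null(op$bond) && op$bond != sym)
          stop("conflicting ring-closure bond symbols")
        add_bond(op$atom, prev, sym)
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NULL
    } else if (tok == "(") {
      if (is.na(prev)) stop("branch open before any atom")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced branch close")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending_bond <- tok
    } else if (tok == ".") {
      prev <- NA_integer_; pending_bond <- NULL
    } else if (tok %in% c("@", "+", "*")) {
      stop("unsupported token outside brackets: ", tok)
    } else {
      stop("unexpected SMILES token: ", tok)
    }
  }
  if (length(stack) > 0L) stop("unbalanced branch open")
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES: ", s)
  if (length(elem) == 0L) stop("SMILES contains no atoms")
  if (!is.null(pending_bond)) stop("dangling bond symbol at end of SMILES")

  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arom)
  if (anyDuplicated(paste(bonds$a1, bonds$a2)))
    stop("duplicate bond in SMILES")
  mol <- structure(list(elem = elem, arom = arom, charge = charge,
                        hcount = hcount, bonds = bonds),
                   class = "shmol")
  mol <- perceive_molecule(mol, default_arom = b_default, explicit_h = expl_h)
  mol
}

mol_natoms <- function(mol) length(mol$elem)

# neighbor list: integer vector of adjacent atoms per atom
mol_adjacency <- function(mol) {
  n <- mol_natoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

mol_degree <- function(mol) {
  n <- mol_natoms(mol)
  tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
}

# connected components; returns integer membership vector
mol_components <- function(mol) {
  n <- mol_natoms(mol)
  comp <- integer(n); cur <- 0L
  adj <- mol_adjacency(mol)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  comp
}

# Smallest-set-of-smallest-rings style cycle basis.  For every non-tree edge
# the shortest cycle through it is found; cycles are then added greedily by
# length subject to GF(2) independence over the edge space.
mol_sssr <- function(mol) {
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  adj <- mol_adjacency(mol)
  bond_idx <- new.env(hash = TRUE)
  for (k in seq_len(nb))
    assign(paste(mol$bonds$a1[k], mol$bonds$a2[k]), k, envir = bond_idx)
  bidx <- function(i, j) get(paste(min(i, j), max(i, j)), envir = bond_idx)

  comp <- mol_components(mol)
  n_rings_expected <- nb - n + length(unique(comp))
  if (n_rings_expected <= 0L) return(list())

  # candidate cycles: shortest cycle through every bond
  candidates <- list()
  for (k in seq_len(nb)) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    # BFS from i to j avoiding bond k
    par <- integer(n); dist <- rep(NA_integer_, n)
    dist[i] <- 0L; queue <- i
    while (length(queue) && is.na(dist[j])) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if ((v == i && u == j) || (v == j && u == i)) next
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; par[u] <- v; queue <- c(queue, u) }
      }
    }
    if (is.na(dist[j])) next
    path <- j
    while (path[1] != i) path <- c(par[path[1]], path)
    atoms <- path
    ebits <- rep(FALSE, nb)
    for (t in seq_len(length(atoms) - 1L)) ebits[bidx(atoms[t], atoms[t + 1L])] <- TRUE
    ebits[k] <- TRUE
    candidates[[length(candidates) + 1L]] <- list(atoms = atoms, ebits = ebits,
                                                  len = sum(ebits))
  }
  if (length(candidates) == 0L) return(list())
  ord <- order(vapply(candidates, `[[`, integer(1), "len"))
  basis <- matrix(FALSE, nrow = 0L, ncol = nb)
  rings <- list()
  for (ci in ord) {
    if (length(rings) >= n_rings_expected) break
    cand <- candidates[[ci]]
    # GF(2) independence check via elimination
    v <- cand$ebits
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1]
      if (v[pivot]) v <- xor(v, basis[r, ])
    }
    if (!any(v)) next
    basis <- rbind(basis, v)
    rings[[length(rings) + 1L]] <- sort(cand$atoms)
  }
  rings
}

ring_membership <- function(mol) {
  n <- mol_natoms(mol)
  rings <- mol_sssr(mol)
  atom_in <- rep(FALSE, n)
  bond_in <- rep(FALSE, nrow(mol$bonds))
  ring_sets <- lapply(rings, identity)
  for (r in rings) atom_in[r] <- TRUE
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      for (r in rings) if (i %in% r && j %in% r) {
        # both endpoints in one ring: bond is a ring bond iff consecutive in
        # that cycle; since rings are stored as atom sets, confirm via the
        # cycle reconstruction below
        bond_in[k] <- TRUE; break
      }
    }
  }
  list(atom = atom_in, bond = bond_in, rings = ring_sets)
}

# pi-bond contribution of an aromatic atom beyond its sigma framework:
# carbon and pyridine-type N/P supply a formal double bond (1 unit); O, S and
# lone-pair donors (N-H, anions) supply a lone pair (0 units)
aromatic_pi_extra <- function(elem, hcount, charge, exo_multiple = FALSE) {
  if (exo_multiple) return(0L)  # pi electron lives in the exocyclic bond
  if (elem == "C") return(if (charge < 0L) 0L else 1L)
  if (elem %in% c("N", "P")) return(if (hcount > 0L || charge < 0L) 0L else 1L)
  0L
}

adjusted_valences <- function(elem, charge) {
  vals <- DEFAULT_VALENCE[[elem]]
  if (is.null(vals)) return(NULL)
  if (charge > 0L && elem %in% c("N", "P", "O", "S", "C")) vals <- vals + charge
  if (charge < 0L) vals <- pmax(vals + charge, 0L)
  vals
}

# implicit hydrogen count for one atom given the sum of its bond orders
# (aromatic bonds counted 1.5 in order_sum); hydrogen-free pi typing is
# assumed for aromatic N/P, which is why pyrrole nitrogen must be written
# [nH] in SMILES
implied_hcount <- function(elem, aromatic, charge, order_sum, n_arom_bonds,
                           exo_multiple = FALSE) {
  vals <- adjusted_valences(elem, charge)
  if (is.null(vals)) return(0L)
  if (aromatic) {
    vals <- vals[1]  # hypervalent states are not aromatic
    used <- (order_sum - 1.5 * n_arom_bonds) + n_arom_bonds +
      aromatic_pi_extra(elem, 0L, charge, exo_multiple)
  } else {
    used <- ceiling(order_sum)
  }
  feas <- vals[vals >= used]
  if (length(feas) == 0L) return(0L)
  as.integer(feas[1] - used)
}

# Perceive aromatic rings, resolve hydrogen counts, validate valences.
perceive_molecule <- function(mol, default_arom = NULL, explicit_h = NULL) {
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  if (is.null(default_arom)) default_arom <- rep(FALSE, nb)
  if (is.null(explicit_h)) explicit_h <- !is.na(mol$hcount)

  rm <- ring_membership(mol)

  # demote aromatic default bonds that are not in any ring (e.g. biphenyl
  # written without the explicit single bond)
  if (nb > 0L) {
    demote <- mol$bonds$arom & default_arom & !rm$bond
    mol$bonds$arom[demote] <- FALSE
    mol$bonds$order[demote] <- 1L
  }

  # aromaticity perception on kekulized rings (simple Hueckel count on SSSR
  # rings of size 5-6; atoms contribute 1 pi electron when double-bonded to
  # another candidate ring atom, 2 for a heteroatom lone pair, and disqualify
  # the ring when saturated or exocyclic-carbonyl carbon)
  if (length(rm$rings) > 0L) {
    adj <- mol_adjacency(mol)
    border <- function(i, j) {
      k <- which((mol$bonds$a1 == min(i, j)) & (mol$bonds$a2 == max(i, j)))
      k
    }
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (ring in rm$rings) {
        sz <- length(ring)
        if (sz < 5L || sz > 6L) next
        if (all(mol$arom[ring])) next
        pi_e <- 0L; ok <- TRUE
        for (a in ring) {
          dbl <- FALSE; exo_carbonyl <- FALSE
          for (u in adj[[a]]) {
            k <- border(a, u)
            if (mol$bonds$order[k] == 2L || mol$bonds$arom[k]) {
              if (u %in% ring || mol$arom[u] || rm$atom[u]) dbl <- TRUE
              else if (mol$elem[u] %in% c("O", "S") && mol$elem[a] == "C")
                exo_carbonyl <- TRUE
            }
            if (mol$bonds$order[k] >= 3L) { ok <- FALSE }
          }
          if (dbl) pi_e <- pi_e + 1L
          else if (exo_carbonyl) { ok <- FALSE }
          else if (mol$elem[a] %in% c("N", "O", "S", "P")) pi_e <- pi_e + 2L
          else if (mol$elem[a] == "C" && mol$charge[a] < 0L) pi_e <- pi_e + 2L
          else ok <- FALSE
          if (!ok) break
        }
        if (ok && pi_e %% 4L == 2L) {
          mol$arom[ring] <- TRUE
          for (t in seq_along(ring)) for (u in ring[-seq_len(t)]) {
            k <- border(ring[t], u)
            if (length(k) == 1L) { mol$bonds$arom[k] <- TRUE; mol$bonds$order[k] <- 1L }
          }
          changed <- TRUE
        }
      }
    }
  }

  # resolve hydrogen counts for atoms without explicit H
  osum <- rep(0, n); narb <- rep(0L, n); exo <- rep(FALSE, n)
  if (nb > 0L) for (k in seq_len(nb)) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    o <- if (mol$bonds$arom[k]) 1.5 else mol$bonds$order[k]
    osum[i] <- osum[i] + o; osum[j] <- osum[j] + o
    if (mol$bonds$arom[k]) { narb[i] <- narb[i] + 1L; narb[j] <- narb[j] + 1L }
    else if (mol$bonds$order[k] >= 2L) { exo[i] <- TRUE; exo[j] <- TRUE }
  }
  for (a in seq_len(n)) {
    if (!explicit_h[a] && is.na(mol$hcount[a]))
      mol$hcount[a] <- implied_hcount(mol$elem[a], mol$arom[a], mol$charge[a],
                                      osum[a], narb[a], exo[a])
  }
  mol$hcount[is.na(mol$hcount)] <- 0L

  # valence sanity for the core organic elements
  for (a in seq_len(n)) {
    vals <- adjusted_valences(mol$elem[a], mol$charge[a])
    if (is.null(vals)) next
    used <- if (mol$arom[a])
      (osum[a] - 1.5 * narb[a]) + narb[a] +
        aromatic_pi_extra(mol$elem[a], mol$hcount[a], mol$charge[a], exo[a])
    else ceiling(osum[a])
    used <- used + mol$hcount[a]
    if (used > max(vals) + 1e-9)
      stop(sprintf("valence violation at atom %d (%s): %s bonds+H",
                   a, mol$elem[a], used))
  }

  mol$ring_atom <- rm$atom
  mol$ring_bond <- rm$bond
  mol$rings <- rm$rings
  mol
}

#' Molecular weight of a molecule (daltons, including hydrogens)
#' @param mol an `shmol` object.
#' @return numeric scalar.
#' @export
mol_weight <- function(mol) {
  m <- ATOMIC_MASS[mol$elem]
  if (anyNA(m)) m[is.na(m)] <- 0
  sum(m) + sum(mol$hcount) * ATOMIC_MASS[["H"]]
}

#' Number of heavy atoms
#' @param mol an `shmol` object.
#' @return integer scalar.
#' @export
n_heavy_atoms <- function(mol) mol_natoms(mol)

#' Count rotatable bonds
#'
#' A rotatable bond is a non-ring single bond between two non-terminal heavy
#' atoms; amide C-N bonds are excluded, following the common convention.
#'
#' @param mol an `shmol` object.
#' @return integer scalar.
#' @export
n_rotatable_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(0L)
  deg <- mol_degree(mol)
  adj <- mol_adjacency(mol)
  is_amide_cn <- function(i, j) {
    # C(=O)-N in either orientation
    for (ord in list(c(i, j), c(j, i))) {
      ci <- ord[1]; ni <- ord[2]
      if (mol$elem[ci] == "C" && mol$elem[ni] == "N") {
        for (u in adj[[ci]]) {
          k <- which(mol$bonds$a1 == min(ci, u) & mol$bonds$a2 == max(ci, u))
          if (mol$elem[u] == "O" && mol$bonds$order[k] == 2L) return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (k in seq_len(nb)) {
    if (mol$ring_bond[k] || mol$bonds$arom[k] || mol$bonds$order[k] != 1L) next
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (is_amide_cn(i, j)) next
    cnt <- cnt + 1L
  }
  cnt
}

# induced submolecule on a set of atom indices (order preserved as given)
mol_subset <- function(mol, atoms) {
  atoms <- as.integer(atoms)
  map <- integer(mol_natoms(mol)); map[atoms] <- seq_along(atoms)
  keep <- mol$bonds$a1 %in% atoms & mol$bonds$a2 %in% atoms
  b <- mol$bonds[keep, , drop = FALSE]
  if (nrow(b) > 0L) {
    na1 <- map[b$a1]; na2 <- map[b$a2]
    b$a1 <- pmin(na1, na2); b$a2 <- pmax(na1, na2)
  }
  rownames(b) <- NULL
  m <- structure(list(elem = mol$elem[atoms], arom = mol$arom[atoms],
                      charge = mol$charge[atoms], hcount = mol$hcount[atoms],
                      bonds = b), class = "shmol")
  # re-derive ring flags; keep hydrogen counts from the parent so cut bonds
  # are replaced by hydrogens implicitly at write-out
  nb_removed <- tabulate(c(mol$bonds$a1[!keep], mol$bonds$a2[!keep]),
                         nbins = mol_natoms(mol))
  ord_removed <- rep(0, mol_natoms(mol))
  for (k in which(!keep)) {
    o <- if (mol$bonds$arom[k]) 1 else mol$bonds$order[k]
    ord_removed[mol$bonds$a1[k]] <- ord_removed[mol$bonds$a1[k]] + o
    ord_removed[mol$bonds$a2[k]] <- ord_removed[mol$bonds$a2[k]] + o
  }
  m$hcount <- m$hcount + as.integer(round(ord_removed[atoms]))
  # atoms that lost their aromatic ring context are de-aromatized; their
  # former aromatic bonds are re-kekulized greedily (alternating doubles)
  # and hydrogen counts rebuilt from standard valences
  if (any(m$arom)) {
    arom_bonds_per_atom <- tabulate(c(m$bonds$a1[m$bonds$arom], m$bonds$a2[m$bonds$arom]),
                                    nbins = length(m$elem))
    lost <- m$arom & arom_bonds_per_atom < 2L
    if (any(lost)) {
      m$arom[lost] <- FALSE
      has_new_double <- rep(FALSE, length(m$elem))
      for (k in seq_len(nrow(m$bonds))) {
        if (!m$bonds$arom[k]) next
        i <- m$bonds$a1[k]; j <- m$bonds$a2[k]
        if (m$arom[i] && m$arom[j]) next
        m$bonds$arom[k] <- FALSE
        if (!m$arom[i] && !m$arom[j] && !has_new_double[i] && !has_new_double[j]) {
          m$bonds$order[k] <- 2L
          has_new_double[i] <- TRUE; has_new_double[j] <- TRUE
        } else {
          m$bonds$order[k] <- 1L
        }
      }
      # rebuild hydrogens on the de-aromatized atoms
      osum <- rep(0, length(m$elem))
      for (k in seq_len(nrow(m$bonds))) {
        o <- if (m$bonds$arom[k]) 1.5 else m$bonds$order[k]
        osum[m$bonds$a1[k]] <- osum[m$bonds$a1[k]] + o
        osum[m$bonds$a2[k]] <- osum[m$bonds$a2[k]] + o
      }
      for (a in which(lost)) {
        vals <- adjusted_valences(m$elem[a], m$charge[a])
        if (is.null(vals)) next
        used <- ceiling(osum[a])
        feas <- vals[vals >= used]
        m$hcount[a] <- if (length(feas)) as.integer(feas[1] - used) else 0L
      }
    }
  }
  rm2 <- ring_membership(m)
  m$ring_atom <- rm2$atom; m$ring_bond <- rm2$bond; m$rings <- rm2$rings
  m
}

#' @export
print.shmol <- function(x, ...) {
  cat(sprintf("<shmol: %d atoms, %d bonds, formula-ish %s>\n",
              mol_natoms(x), nrow(x$bonds),
              paste0(names(table(x$elem)), table(x$elem), collapse = "")))
  invisible(x)
}
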