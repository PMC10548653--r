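# Graph-editing helpers: joining fragments to scaffolds and cutting side
# chains off molecules.  These work directly on `shmol` objects; hydrogen
# counts are adjusted locally so no global re-perception is needed.

# number of hydrogens available for new bonds at each atom
free_valence <- function(mol) mol$hcount

#' Join two molecules with a new bond
#'
#' Creates a single molecule from `a` and `b` connected by a bond of the
#' given order between `site_a` (atom index in `a`) and `site_b` (atom index
#' in `b`).  Both sites must carry at least `order` hydrogens, which are
#' consumed by the new bond.
#'
#' @param a,b `shmol` objects.
#' @param site_a,site_b 1-based atom indices.
#' @param order bond order of the new bond (default 1).
#' @return a new `shmol`; atoms of `a` keep their indices, atoms of `b` are
#'   offset by `n_heavy_atoms(a)`.
#' @export
mol_combine <- function(a, b, site_a, site_b, order = 1L) {
  if (a$hcount[site_a] < order)
    stop("attachment would exceed valence at site_a")
  if (b$hcount[site_b] < order)
    stop("attachment would exceed valence at site_b")
  off <- mol_natoms(a)
  bonds_b <- b$bonds
  if (nrow(bonds_b) > 0L) { bonds_b$a1 <- bonds_b$a1 + off; bonds_b$a2 <- bonds_b$a2 + off }
  newb <- data.frame(a1 = min(site_a, site_b + off),
                     a2 = max(site_a, site_b + off),
                     order = as.integer(order), arom = FALSE)
  m <- structure(list(
    elem = c(a$elem, b$elem), arom = c(a$arom, b$arom),
    charge = c(a$charge, b$charge), hcount = c(a$hcount, b$hcount),
    bonds = rbind(a$bonds, bonds_b, newb)), class = "shmol")
  m$hcount[site_a] <- m$hcount[site_a] - as.integer(order)
  m$hcount[site_b + off] <- m$hcount[site_b + off] - as.integer(order)
  rm <- ring_membership(m)
  m$ring_atom <- rm$atom; m$ring_bond <- rm$bond; m$rings <- rm$rings
  m
}

#' Cut a molecule into scaffold and side-chain fragments
#'
#' Every bond between a scaffold atom (in `mask`) and a non-scaffold atom is
#' cut.  Hydrogens are restored at both cut ends.  Each side-chain fragment
#' records the scaffold atom it was attached to, its own attachment atom and
#' the cut bond's order.
#'
#' @param mol an `shmol` object.
#' @param mask integer vector of scaffold atom indices.
#' @return list with `scaffold` (an `shmol`) and `fragments`, a list of
#'   `list(mol, attach_atom, scaffold_atom, scaffold_atom_local, order)`
#'   where `scaffold_atom_local` indexes into the returned scaffold.
#' @export
mol_decompose <- function(mol, mask) {
  n <- mol_natoms(mol)
  mask <- sort(as.integer(mask))
  if (any(mask < 1L | mask > n)) stop("mask out of range")
  in_mask <- rep(FALSE, n); in_mask[mask] <- TRUE
  cut <- which(xor(in_mask[mol$bonds$a1], in_mask[mol$bonds$a2]))

  scaffold <- mol_subset(mol, mask)
  side_atoms <- setdiff(seq_len(n), mask)
  fragments <- list()
  if (length(side_atoms) > 0L) {
    # connected components of the side-chain atoms
    sub <- mol_subset(mol, side_atoms)
    comp <- mol_components(sub)
    loc2glob <- side_atoms
    for (ci in sort(unique(comp))) {
      glob <- loc2glob[comp == ci]
      fmol <- mol_subset(mol, glob)
      # find the cut bond touching this fragment (exactly one per fragment
      # for tree-like side chains; multiple cuts to one fragment are not
      # supported and raise an error)
      cuts_here <- cut[(mol$bonds$a1[cut] %in% glob) | (mol$bonds$a2[cut] %in% glob)]
      if (length(cuts_here) != 1L)
        stop("side-chain fragment attached at ", length(cuts_here),
             " points; expected exactly 1")
      k <- cuts_here
      sa <- if (in_mask[mol$bonds$a1[k]]) mol$bonds$a1[k] else mol$bonds$a2[k]
      fa <- if (in_mask[mol$bonds$a1[k]]) mol$bonds$a2[k] else mol$bonds$a1[k]
      fragments[[length(fragments) + 1L]] <- list(
        mol = fmol,
        attach_atom = match(fa, glob),
        scaffold_atom = sa,
        scaffold_atom_local = match(sa, mask),
        order = mol$bonds$order[k])
    }
  }
  list(scaffold = scaffold, fragments = fragments)
}

#' Reattach side-chain fragments onto a scaffold
#'
#' @param scaffold an `shmol`.
#' @param fragments list as produced by [mol_decompose()]; each fragment is
#'   attached at `sites[i]` (atom index into the current scaffold assembly).
#' @param sites integer vector, one scaffold atom index per fragment.
#' @return the assembled `shmol`, or an error when a site lacks valence.
#' @export
mol_attach_all <- function(scaffold, fragments, sites) {
  stopifnot(length(fragments) == length(sites))
  m <- scaffold
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    m <- mol_combine(m, fr$mol, sites[i], fr$attach_atom, fr$order)
  }
  m
}
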