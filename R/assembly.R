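# Scaffold hopping: resample the scaffold latent, decode new scaffolds, and
# reattach the reference molecule's side chains by enumeration plus
# fingerprint-similarity selection.

#' Resample the decoder's initial hidden input
#'
#' Builds `concat(Z_side, mu + s * eps)` with `eps ~ N(0, I)`.  In
#' `"literal"` mode (the default) `s = sigma^2`, the model's stated
#' variance-scaled resampling rule; `"standard"` mode uses `s = sigma`.
#'
#' @param Z_side side-chain embedding vector.
#' @param mu,sigma latent posterior parameters.
#' @param rng RNG stream.
#' @param sigma_mode `"literal"` or `"standard"`.
#' @return list with `h0raw` (the concatenated vector) and `eps`.
#' @export
resample_h0 <- function(Z_side, mu, sigma, rng,
                        sigma_mode = c("literal", "standard")) {
  sigma_mode <- match.arg(sigma_mode)
  eps <- rng$rnorm(length(mu))
  s <- if (sigma_mode == "literal") sigma^2 else sigma
  list(h0raw = c(Z_side, mu + s * eps), eps = eps)
}

#' Decompose a reference molecule into scaffold and side chains
#'
#' @param mol_smiles reference molecule SMILES.
#' @param scaffold_smiles its scaffold SMILES.
#' @param mask optional precomputed atom mask; found by
#'   [scaffold_atom_mask()] otherwise.
#' @return list with `scaffold` (`shmol`), `fragments` (see
#'   [mol_decompose()]), `mask`, and the canonical reference/scaffold
#'   SMILES.
#' @export
decompose_reference <- function(mol_smiles, scaffold_smiles, mask = NULL) {
  mol <- parse_smiles(mol_smiles)
  sc <- parse_smiles(scaffold_smiles)
  if (is.null(mask)) mask <- scaffold_atom_mask(mol, sc)
  dec <- mol_decompose(mol, mask)
  list(scaffold = dec$scaffold, fragments = dec$fragments, mask = mask,
       mol_canonical = write_smiles(mol),
       scaffold_canonical = write_smiles(sc))
}

#' Enumerate side-chain attachments on a new scaffold
#'
#' All injective assignments of the fragments to hydrogen-bearing scaffold
#' atoms are enumerated (an atom is eligible for a fragment when its free
#' valence covers the cut bond's order), assembled, and deduplicated by
#' canonical SMILES.  Enumeration order is deterministic (sites in
#' canonical-rank order) and capped.
#'
#' @param new_scaffold `shmol` or SMILES of the sampled scaffold.
#' @param fragments fragment list from [decompose_reference()].
#' @param cap maximum number of assignments explored (default 5000).
#' @return data.frame with columns `smiles` (canonical assembled molecule)
#'   and `sites` (comma-joined scaffold atom indices, one per fragment);
#'   zero rows when no assignment is feasible.
#' @export
enumerate_attachments <- function(new_scaffold, fragments, cap = 5000L) {
  if (is.character(new_scaffold)) new_scaffold <- parse_smiles(new_scaffold)
  nf <- length(fragments)
  if (nf == 0L) {
    return(data.frame(smiles = write_smiles(new_scaffold), sites = "",
                      stringsAsFactors = FALSE))
  }
  # deterministic site ordering by canonical rank
  rk <- canonical_ranks(new_scaffold)
  site_order <- order(rk)
  out_smiles <- character(0); out_sites <- character(0)
  n_explored <- 0L
  # `consumed` tracks hydrogens already claimed at each site so several
  # fragments may share one atom when its valence allows it (gem
  # substitution), which the round-trip contract requires
  consumed <- integer(mol_natoms(new_scaffold))
  rec <- function(i, sites) {
    if (n_explored >= cap) return(invisible(NULL))
    if (i > nf) {
      n_explored <<- n_explored + 1L
      m <- tryCatch(mol_attach_all(new_scaffold, fragments, sites),
                    error = function(e) NULL)
      if (!is.null(m)) {
        out_smiles[[length(out_smiles) + 1L]] <<- write_smiles(m)
        out_sites[[length(out_sites) + 1L]] <<- paste(sites, collapse = ",")
      }
      return(invisible(NULL))
    }
    need <- fragments[[i]]$order
    for (s in site_order) {
      if (new_scaffold$hcount[s] - consumed[s] < need) next
      consumed[s] <<- consumed[s] + need
      rec(i + 1L, c(sites, s))
      consumed[s] <<- consumed[s] - need
      if (n_explored >= cap) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, integer(0))
  if (length(out_smiles) == 0L)
    return(data.frame(smiles = character(0), sites = character(0)))
  keep <- !duplicated(out_smiles)
  data.frame(smiles = out_smiles[keep], sites = out_sites[keep],
             stringsAsFactors = FALSE)
}

#' Select the assembled candidate most similar to the reference
#'
#' Ranks candidates by path-fingerprint Tanimoto similarity to the
#' reference molecule; ties are broken by lexicographic canonical SMILES.
#'
#' @param candidates data.frame from [enumerate_attachments()].
#' @param reference_smiles canonical reference molecule SMILES.
#' @return list with `smiles`, `sites`, `similarity`, or `NULL` when there
#'   are no candidates.
#' @export
select_candidate <- function(candidates, reference_smiles) {
  if (nrow(candidates) == 0L) return(NULL)
  ref_fp <- path_fingerprint(parse_smiles(reference_smiles))
  sims <- vapply(candidates$smiles, function(s)
    tanimoto(path_fingerprint(parse_smiles(s)), ref_fp), numeric(1))
  best <- which(sims == max(sims))
  if (length(best) > 1L) best <- best[order(candidates$smiles[best])[1]]
  list(smiles = candidates$smiles[best], sites = candidates$sites[best],
       similarity = unname(sims[best]))
}

# assemble one scaffold string onto a decomposed reference; returns a
# generated-molecule record
assemble_generated <- function(scaffold_smiles, ref, cap = 5000L) {
  rec <- list(scaffold_smiles = scaffold_smiles, assembled_smiles = NA_character_,
              reference_id = ref$reference_id %||% NA_character_,
              attachment = NA_character_, similarity = NA_real_,
              valid = FALSE, hopped = FALSE)
  sc <- tryCatch(parse_smiles(scaffold_smiles), error = function(e) NULL)
  if (is.null(sc)) return(rec)
  rec$scaffold_smiles <- write_smiles(sc)
  cands <- enumerate_attachments(sc, ref$fragments, cap = cap)
  sel <- select_candidate(cands, ref$mol_canonical)
  if (is.null(sel)) return(rec)
  rec$assembled_smiles <- sel$smiles
  rec$attachment <- sel$sites
  rec$similarity <- sel$similarity
  rec$valid <- TRUE
  rec$hopped <- !identical(rec$scaffold_smiles, ref$scaffold_canonical)
  rec
}

#' Generate scaffold-hopped molecules for a reference compound
#'
#' Encodes the reference once, then draws `n` scaffold samples from the
#' resampled latent (side-chain embedding held fixed), decodes each with
#' the GRU, and reattaches the reference side chains.  Invalid samples are
#' kept in the output with `valid = FALSE`.
#'
#' @param model an `sh_model`.
#' @param mol_smiles,scaffold_smiles the reference molecule and its
#'   scaffold.
#' @param n number of samples.
#' @param seed integer seed.
#' @param temperature sampling temperature.
#' @param reference_id id string carried into the records.
#' @param cap attachment-enumeration cap.
#' @return data.frame with columns `reference_id`, `scaffold_smiles`,
#'   `assembled_smiles`, `similarity`, `valid`, `hopped`.
#' @export
hop <- function(model, mol_smiles, scaffold_smiles, n = 100L, seed = 1L,
                temperature = 1.0, reference_id = "ref", cap = 5000L) {
  cfg <- model$config
  ref <- decompose_reference(mol_smiles, scaffold_smiles)
  ref$reference_id <- reference_id
  mol <- parse_smiles(mol_smiles)
  g <- featurize(mol, cfg)
  e <- encoder_forward(g, ref$mask, model$enc, cfg)
  rng <- make_rng(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- resample_h0(e$Z_side, e$mu, e$sigma, rng, cfg$sigma_mode)
    h0 <- as.vector(bridge_h0(model$dec, matrix(rs$h0raw, 1L)))
    smi <- sample_sequence(model$dec, cfg, model$vocab, h0,
                           temperature = temperature, rng = rng)
    rec <- if (nzchar(smi)) assemble_generated(smi, ref, cap = cap)
           else list(scaffold_smiles = smi, assembled_smiles = NA_character_,
                     reference_id = reference_id, attachment = NA_character_,
                     similarity = NA_real_, valid = FALSE, hopped = FALSE)
    rows[[i]] <- data.frame(reference_id = reference_id,
                            scaffold_smiles = rec$scaffold_smiles,
                            assembled_smiles = rec$assembled_smiles,
                            similarity = rec$similarity,
                            valid = rec$valid, hopped = rec$hopped,
                            stringsAsFactors = FALSE)
  }
  if (n == 0L)
    return(data.frame(reference_id = character(0), scaffold_smiles = character(0),
                      assembled_smiles = character(0), similarity = numeric(0),
                      valid = logical(0), hopped = logical(0)))
  do.call(rbind, rows)
}

#' Write / read generated-molecule tables
#' @param gen data.frame from [hop()].
#' @param path TSV path.
#' @export
write_generated <- function(gen, path) {
  utils::write.table(gen, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_generated
#' @export
read_generated <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "")
}
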