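# Evaluation metrics for generated molecule sets: the seven general
# generative metrics (validity, uniqueness at 1K/5K, filter pass rate,
# novelty, scaffold uniqueness, scaffold novelty) and the four
# scaffold-hopping metrics (active mean, active rate, hop rate, success
# rate) with activity scoring behind a pluggable interface.

#' General generative metrics (GEM) report
#'
#' @param generated character vector of generated SMILES, in generation
#'   order.
#' @param train_mols character vector of training molecule SMILES
#'   (canonicalized internally).
#' @param train_scaffolds character vector of training scaffold SMILES.
#' @param k1,k2 uniqueness window sizes (defaults 1000 and 5000; when the
#'   list is shorter the full list is used, with a warning).
#' @param extra_patterns additional alert patterns for the filter metric.
#' @return list of class `gem_report` with fields `validity`,
#'   `uniqueness1k`, `uniqueness5k`, `filter_rate`, `novelty`,
#'   `scaffold_uniqueness`, `scaffold_novelty`, plus counts.
#' @export
gem_report <- function(generated, train_mols = character(0),
                       train_scaffolds = character(0),
                       k1 = 1000L, k2 = 5000L,
                       extra_patterns = character(0)) {
  n <- length(generated)
  if (k1 > n || k2 > n)
    warning("uniqueness window larger than the generated list; using full list")
  canon <- vapply(generated, function(s)
    tryCatch(canonical_smiles(s), error = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  valid <- !is.na(canon)
  validity <- if (n > 0L) mean(valid) else 0

  uniq_at <- function(k) {
    head_can <- canon[seq_len(min(k, n))]
    vv <- head_can[!is.na(head_can)]
    if (length(vv) == 0L) return(0)
    length(unique(vv)) / length(vv)
  }

  train_canon <- unique(vapply(train_mols, function(s)
    tryCatch(canonical_smiles(s), error = function(e) NA_character_),
    character(1), USE.NAMES = FALSE))
  uniq_valid <- unique(canon[valid])
  novelty <- if (length(uniq_valid) == 0L) 0
             else mean(!(uniq_valid %in% train_canon))

  # filter pass rate over valid molecules
  filter_rate <- if (!any(valid)) 0 else {
    mean(vapply(canon[valid], function(s)
      is.null(screen_alerts(s, extra_patterns)), logical(1)))
  }

  # scaffold metrics on the level-0 framework of each valid molecule
  scafs <- vapply(canon[valid], function(s) {
    m <- murcko_scaffold_mol(parse_smiles(s))
    if (is.null(m)) NA_character_ else write_smiles(m)
  }, character(1), USE.NAMES = FALSE)
  scafs <- scafs[!is.na(scafs)]
  train_scaf_canon <- unique(vapply(train_scaffolds, function(s)
    tryCatch(canonical_smiles(s), error = function(e) NA_character_),
    character(1), USE.NAMES = FALSE))
  scaffold_uniqueness <- if (length(scafs) == 0L) 0
                         else length(unique(scafs)) / length(scafs)
  scaffold_novelty <- if (length(scafs) == 0L) 0
                      else mean(!(unique(scafs) %in% train_scaf_canon))

  structure(list(validity = validity,
                 uniqueness1k = uniq_at(k1), uniqueness5k = uniq_at(k2),
                 filter_rate = filter_rate, novelty = novelty,
                 scaffold_uniqueness = scaffold_uniqueness,
                 scaffold_novelty = scaffold_novelty,
                 n_generated = n, n_valid = sum(valid)),
            class = "gem_report")
}

#' Does a generated molecule count as a scaffold hop?
#'
#' True iff the record is valid, every reference side-chain fragment occurs
#' as a substructure of the assembled molecule, and the generated scaffold's
#' canonical SMILES differs from the reference scaffold's.
#'
#' @param assembled_smiles,scaffold_smiles the generated molecule and its
#'   scaffold.
#' @param ref a [decompose_reference()] result.
#' @param valid validity flag of the record.
#' @return logical scalar.
#' @export
hop_check <- function(assembled_smiles, scaffold_smiles, ref, valid = TRUE) {
  if (!isTRUE(valid) || is.na(assembled_smiles)) return(FALSE)
  sc_can <- tryCatch(canonical_smiles(scaffold_smiles),
                     error = function(e) NA_character_)
  if (is.na(sc_can) || identical(sc_can, ref$scaffold_canonical)) return(FALSE)
  mol <- tryCatch(parse_smiles(assembled_smiles), error = function(e) NULL)
  if (is.null(mol)) return(FALSE)
  for (fr in ref$fragments) {
    if (!has_substructure(fr$mol, mol)) return(FALSE)
  }
  TRUE
}

#' Deterministic mock activity scorer
#'
#' A documented stand-in for external activity engines: a smooth function of
#' heavy-atom count, ring count and heteroatom count, with a small
#' target-dependent deterministic perturbation.  Higher is better
#' (orientation +1).  Identical for canonical and non-canonical SMILES of
#' one molecule; unparsable input scores `-Inf`.
#'
#' @param smiles molecule SMILES.
#' @param target target identifier string (defaults `"default"`).
#' @return numeric score.
#' @export
mock_scorer <- function(smiles, target = "default") {
  can <- tryCatch(canonical_smiles(smiles), error = function(e) NA_character_)
  if (is.na(can)) return(-Inf)
  m <- parse_smiles(can)
  nh <- n_heavy_atoms(m)
  nr <- n_rings(m)
  nhet <- sum(!(m$elem %in% c("C")))
  jit <- (str_hash(paste(can, target, sep = "|")) %% 1000L) / 1000
  5 + 2 * sin(0.35 * nh) + 0.8 * nr + 0.25 * nhet - 0.04 * nh + 0.2 * jit
}

#' Build an activity-scorer interface object
#'
#' @param name scorer name.
#' @param orientation `+1` when higher scores are better (prediction-style),
#'   `-1` when lower is better (docking-style).
#' @param score_fn function `(smiles, target) -> numeric`.
#' @return an `activity_scorer` list.
#' @export
activity_scorer <- function(name, orientation, score_fn) {
  stopifnot(orientation %in% c(-1, 1), is.function(score_fn))
  structure(list(name = name, orientation = orientation, score = score_fn),
            class = "activity_scorer")
}

#' The built-in deterministic mock scorer interface
#' @return an `activity_scorer` wrapping [mock_scorer()].
#' @export
default_scorer <- function() activity_scorer("mock", +1, mock_scorer)

#' Scaffold-hopping metrics (SEM) report
#'
#' Valid generated molecules are ranked by the scorer (respecting its
#' orientation) and restricted to the best `top_fraction`; within that set,
#' `active_mean` is the mean score, `active_rate` the fraction scoring
#' strictly better than the reference compound, `hop_rate` the fraction
#' passing [hop_check()], and `success_rate` the fraction passing both.
#'
#' @param gen data.frame from [hop()].
#' @param ref a [decompose_reference()] result.
#' @param scorer an [activity_scorer()].
#' @param target target id passed to the scorer.
#' @param top_fraction fraction of valid molecules evaluated (default 0.10).
#' @return list of class `sem_report`; `NULL` fields with counts when no
#'   molecule is valid.
#' @export
sem_report <- function(gen, ref, scorer = default_scorer(),
                       target = "default", top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  vgen <- gen[gen$valid & !is.na(gen$assembled_smiles), , drop = FALSE]
  if (nrow(vgen) == 0L) {
    return(structure(list(active_mean = NULL, active_rate = NULL,
                          hop_rate = NULL, success_rate = NULL,
                          n_valid = 0L, n_evaluated = 0L),
                     class = "sem_report"))
  }
  scores <- vapply(vgen$assembled_smiles, scorer$score, numeric(1),
                   target = target, USE.NAMES = FALSE)
  ord <- order(scorer$orientation * scores, decreasing = TRUE)
  n_top <- max(1L, floor(nrow(vgen) * top_fraction))
  top <- ord[seq_len(n_top)]
  ref_score <- scorer$score(ref$mol_canonical, target = target)

  hops <- vapply(top, function(i)
    hop_check(vgen$assembled_smiles[i], vgen$scaffold_smiles[i], ref,
              vgen$valid[i]), logical(1))
  better <- scorer$orientation * scores[top] > scorer$orientation * ref_score
  rep <- structure(list(
    active_mean = mean(scores[top]),
    active_rate = mean(better),
    hop_rate = mean(hops),
    success_rate = mean(better & hops),
    n_valid = nrow(vgen), n_evaluated = n_top,
    reference_score = ref_score), class = "sem_report")
  stopifnot(rep$success_rate <= min(rep$active_rate, rep$hop_rate) + 1e-12)
  rep
}

#' @export
print.gem_report <- function(x, ...) {
  cat("GEM report:\n")
  for (nm in c("validity", "uniqueness1k", "uniqueness5k", "filter_rate",
               "novelty", "scaffold_uniqueness", "scaffold_novelty"))
    cat(sprintf("  %-20s %.4f\n", nm, x[[nm]]))
  cat(sprintf("  (n = %d generated, %d valid)\n", x$n_generated, x$n_valid))
  invisible(x)
}

#' @export
print.sem_report <- function(x, ...) {
  cat("SEM report:\n")
  if (is.null(x$active_mean)) { cat("  no valid molecules\n"); return(invisible(x)) }
  for (nm in c("active_mean", "active_rate", "hop_rate", "success_rate"))
    cat(sprintf("  %-14s %.4f\n", nm, x[[nm]]))
  cat(sprintf("  (top %d of %d valid; reference score %.3f)\n",
              x$n_evaluated, x$n_valid, x$reference_score))
  invisible(x)
}
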