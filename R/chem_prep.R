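# Data preparation: SMILES standardization, structural alert screening, and
# molecule-scaffold pair dataset construction.

#' Default preparation limits
#'
#' Molecular-weight and heavy-atom windows for molecule curation plus the
#' scaffold filter ceilings.  The screening pattern set can be extended with
#' `extra_patterns` (a character vector of SMILES patterns).
#'
#' @param mw_min,mw_max molecular weight window in daltons.
#' @param heavy_min,heavy_max heavy-atom count window.
#' @param scaffold_max_heavy,scaffold_max_rotatable scaffold filter ceilings.
#' @param extra_patterns additional alert patterns (SMILES strings).
#' @return a named list of limits.
#' @export
prep_limits <- function(mw_min = 200, mw_max = 600,
                        heavy_min = 10L, heavy_max = 50L,
                        scaffold_max_heavy = 20L, scaffold_max_rotatable = 3L,
                        extra_patterns = character(0)) {
  list(mw_min = mw_min, mw_max = mw_max,
       heavy_min = heavy_min, heavy_max = heavy_max,
       scaffold_max_heavy = scaffold_max_heavy,
       scaffold_max_rotatable = scaffold_max_rotatable,
       extra_patterns = extra_patterns)
}

# Built-in structural alerts.  Patterns are expressed as SMILES fragments
# and matched as labeled monomorphisms with hydrogen counts ignored -- a
# deliberately small MCF/PAINS-style list covering reactive or promiscuous
# groups; users supply their own patterns for production curation.
ALERT_PATTERNS <- c(
  nitro          = "O=[N+][O-]",
  azo            = "N=N",
  hydrazine      = "NN",
  peroxide       = "OO",
  disulfide      = "SS",
  acyl_halide    = "ClC=O",
  sulfonyl_chloride = "ClS(=O)=O",
  isocyanate     = "N=C=O",
  thiourea       = "NC(=S)N",
  quinone        = "O=C1C=CC(=O)C=C1",
  long_chain     = "CCCCCCCC"
)

alert_molcache <- new.env(hash = TRUE)
alert_patterns_parsed <- function(extra = character(0)) {
  pats <- c(ALERT_PATTERNS, extra)
  if (is.null(names(pats))) names(pats) <- pats
  nm <- names(pats)
  nm[nm == ""] <- pats[nm == ""]
  out <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    key <- pats[[i]]
    if (is.null(alert_molcache[[key]]))
      alert_molcache[[key]] <- parse_smiles(key)
    out[[i]] <- alert_molcache[[key]]
  }
  names(out) <- nm
  out
}

#' Screen a molecule against the structural-alert patterns
#'
#' @param mol an `shmol` or SMILES string.
#' @param extra_patterns additional SMILES patterns.
#' @return `NULL` when clean, otherwise the name of the first pattern hit.
#' @export
screen_alerts <- function(mol, extra_patterns = character(0)) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  pats <- alert_patterns_parsed(extra_patterns)
  for (nm in names(pats)) {
    if (has_substructure(pats[[nm]], mol)) return(nm)
  }
  NULL
}

# neutralize protonation-state charges where a hydrogen shift suffices;
# anions adjacent to a fixed cation (nitro, N-oxide, betaine) are kept so
# the group's charge pattern survives for the alert screen
neutralize_charges <- function(mol) {
  adj <- mol_adjacency(mol)
  for (a in seq_len(mol_natoms(mol))) {
    ch <- mol$charge[a]
    if (ch > 0L && mol$hcount[a] >= ch &&
        mol$elem[a] %in% c("N", "O", "S", "P")) {
      mol$hcount[a] <- mol$hcount[a] - ch
      mol$charge[a] <- 0L
    } else if (ch < 0L && mol$elem[a] %in% c("O", "N", "S", "C")) {
      if (any(mol$charge[adj[[a]]] > 0L)) next
      mol$hcount[a] <- mol$hcount[a] - ch
      mol$charge[a] <- 0L
    }
  }
  mol
}

rejection <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "sh_rejection")
}

#' Is an object a rejection?
#' @param x object returned by [standardize_molecule()].
#' @return logical scalar.
#' @export
is_rejection <- function(x) inherits(x, "sh_rejection")

#' Standardize one raw SMILES into a molecule record
#'
#' Keeps the largest fragment, neutralizes protonation charges, rejects
#' metals/unsupported elements, enforces the molecular-weight and heavy-atom
#' windows, and screens against the structural alerts.
#'
#' @param raw a SMILES string.
#' @param limits a [prep_limits()] list.
#' @param id identifier carried into the record.
#' @return a `molecule_record` (fields `id`, `smiles`, `n_heavy`,
#'   `mol_weight`) or an `sh_rejection` with reason `invalid`, `metal`,
#'   `mw_out_of_range` or `filter_hit`.
#' @export
standardize_molecule <- function(raw, limits = prep_limits(), id = NA_character_) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("raw SMILES must be a non-empty string")
  mol <- tryCatch(parse_smiles(raw), error = function(e) NULL)
  if (is.null(mol)) return(rejection("invalid", raw))

  if (any(!(mol$elem %in% ORGANIC_SUBSET)))
    return(rejection("metal", paste(setdiff(unique(mol$elem), ORGANIC_SUBSET),
                                    collapse = ",")))

  comp <- mol_components(mol)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie-break on canonical SMILES for determinism
      frags <- vapply(best, function(ci)
        write_smiles(mol_subset(mol, which(comp == ci))), character(1))
      best <- best[order(frags)[1]]
    }
    mol <- mol_subset(mol, which(comp == best[1]))
  }
  mol <- neutralize_charges(mol)

  mw <- mol_weight(mol); nh <- n_heavy_atoms(mol)
  if (mw < limits$mw_min || mw > limits$mw_max ||
      nh < limits$heavy_min || nh > limits$heavy_max)
    return(rejection("mw_out_of_range", sprintf("mw=%.1f n_heavy=%d", mw, nh)))

  hit <- screen_alerts(mol, limits$extra_patterns)
  if (!is.null(hit)) return(rejection("filter_hit", hit))

  structure(list(id = id, smiles = write_smiles(mol),
                 n_heavy = nh, mol_weight = mw),
            class = "molecule_record")
}

#' Build molecule-scaffold pair datasets
#'
#' Runs hierarchical scaffold extraction on each molecule, applies the
#' scaffold filter, and emits pairs.  In `pretrain` mode one passing
#' scaffold is chosen uniformly at random per molecule; in `finetune` mode
#' every passing scaffold yields a pair.  Molecules with no passing scaffold
#' are dropped and counted.
#'
#' @param mols list of `molecule_record` objects (see
#'   [standardize_molecule()]).
#' @param mode `"pretrain"` or `"finetune"`.
#' @param seed integer seed controlling the random scaffold choice.
#' @param limits a [prep_limits()] list.
#' @return list with `pairs` (a data.frame with columns `mol_id`,
#'   `mol_smiles`, `scaffold_smiles`, `scaffold_atoms`) and `n_dropped`.
#' @export
build_pair_dataset <- function(mols, mode = c("pretrain", "finetune"),
                               seed = 1L, limits = prep_limits()) {
  mode <- match.arg(mode)
  rng <- make_rng(seed)
  rows <- list(); n_dropped <- 0L
  for (mr in mols) {
    mol <- parse_smiles(mr$smiles)
    hier <- extract_scaffold_hierarchy(mol)
    passing <- Filter(function(s)
      filter_scaffold(s, limits$scaffold_max_heavy, limits$scaffold_max_rotatable),
      hier)
    if (length(passing) == 0L) { n_dropped <- n_dropped + 1L; next }
    chosen <- if (mode == "pretrain")
      passing[rng$sample_int(length(passing), 1L)] else passing
    for (s in chosen) {
      mask <- scaffold_atom_mask(mol, parse_smiles(s$smiles))
      rows[[length(rows) + 1L]] <- data.frame(
        mol_id = as.character(mr$id), mol_smiles = mr$smiles,
        scaffold_smiles = s$smiles,
        scaffold_atoms = paste(mask - 1L, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(mol_id = character(0), mol_smiles = character(0),
                           scaffold_smiles = character(0),
                           scaffold_atoms = character(0))
  list(pairs = pairs, n_dropped = n_dropped)
}

#' Read a .smi file
#'
#' One SMILES per line with an optional tab-separated identifier; blank
#' lines and lines starting with `#` are ignored.  Missing identifiers are
#' filled with `mol<line>`.
#'
#' @param path file path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1L),
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("mol", i),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Write a .smi file
#' @param df data.frame with columns `smiles` and `id`.
#' @param path output path.
#' @export
write_smi <- function(df, path) {
  writeLines(paste(df$smiles, df$id, sep = "\t"), path)
}

#' Write a molecule-scaffold pairs table as TSV
#' @param pairs data.frame from [build_pair_dataset()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a molecule-scaffold pairs TSV
#' @param path file path.
#' @return data.frame with the pair columns.
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "")
}

# parse the 0-based comma-joined atom index column into 1-based indices
pair_mask <- function(pair_row) {
  as.integer(strsplit(pair_row$scaffold_atoms, ",", fixed = TRUE)[[1]]) + 1L
}

#' Standardize a whole input table and build pairs, with a report
#'
#' @param input data.frame from [read_smi()].
#' @param mode `"pretrain"` or `"finetune"`.
#' @param seed integer seed.
#' @param limits a [prep_limits()] list.
#' @return list with `pairs`, `report` (rejection counts by reason,
#'   molecules kept/dropped), and `records`.
#' @export
prepare_dataset <- function(input, mode = "pretrain", seed = 1L,
                            limits = prep_limits()) {
  recs <- list(); reasons <- character(0)
  seen <- new.env(hash = TRUE)
  n_dup <- 0L
  for (i in seq_len(nrow(input))) {
    r <- standardize_molecule(input$smiles[i], limits, id = input$id[i])
    if (is_rejection(r)) { reasons <- c(reasons, r$reason); next }
    if (!is.null(seen[[r$smiles]])) { n_dup <- n_dup + 1L; next }
    seen[[r$smiles]] <- TRUE
    recs[[length(recs) + 1L]] <- r
  }
  ds <- build_pair_dataset(recs, mode, seed, limits)
  report <- list(
    n_input = nrow(input),
    n_standardized = length(recs),
    n_duplicates = n_dup,
    rejections = as.list(table(factor(reasons,
      levels = c("invalid", "metal", "mw_out_of_range", "filter_hit")))),
    n_no_passing_scaffold = ds$n_dropped,
    n_pairs = nrow(ds$pairs),
    mode = mode, seed = seed)
  list(pairs = ds$pairs, report = report, records = recs)
}
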