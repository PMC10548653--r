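# Deterministic synthetic SMILES corpora with known scaffold/side-chain
# ground truth.  The generator builds molecules as "one core ring system
# plus 0-3 substituents", which mirrors the molecule = scaffold + side-chain
# decomposition the rest of the package operates on.  Property distributions
# of real screening libraries (ChEMBL-like MW/logP profiles) are NOT
# emulated.

# ring-system core library: drug-like heterocycles that pass the scaffold
# filter, plus deliberate failers (benzene-only systems, oversized systems,
# over-flexible linkers) so the filter sees both classes
FIXTURE_CORES <- c(
  # passing single heterocycles
  pyridine        = "c1ccncc1",
  pyrimidine      = "c1cncnc1",
  pyrazine        = "c1cnccn1",
  pyridazine      = "c1ccnnc1",
  piperidine      = "C1CCNCC1",
  piperazine      = "C1CNCCN1",
  morpholine      = "C1COCCN1",
  pyrrolidine     = "C1CCNC1",
  tetrahydrofuran = "C1CCOC1",
  thiophene       = "c1ccsc1",
  furan           = "c1ccoc1",
  pyrrole         = "c1cc[nH]c1",
  imidazole       = "c1c[nH]cn1",
  pyrazole        = "c1cc[nH]n1",
  oxazole         = "c1cnco1",
  thiazole        = "c1cncs1",
  cyclohexane     = "C1CCCCC1",
  cyclopentane    = "C1CCCC1",
  # passing fused / linked systems
  indole          = "c1ccc2[nH]ccc2c1",
  benzimidazole   = "c1ccc2[nH]cnc2c1",
  quinoline       = "c1ccc2ncccc2c1",
  isoquinoline    = "c1ccc2cnccc2c1",
  benzothiophene  = "c1ccc2sccc2c1",
  benzofuran      = "c1ccc2occc2c1",
  quinazoline     = "c1ccc2ncncc2c1",
  tetralin        = "C1CCc2ccccc2C1",
  norbornane      = "C1CC2CCC1C2",
  phenylpiperidine = "c1ccc(C2CCNCC2)cc1",
  phenylpyrimidine = "c1ccc(-c2ncccn2)cc1",
  # filter failers
  benzene         = "c1ccccc1",
  naphthalene     = "c1ccc2ccccc2c1",
  biphenyl        = "c1ccc(-c2ccccc2)cc1",
  oversize        = "C1CCN(CC1)C1CCN(CC1)C1CCN(CC1)C1CCNCC1",   # > 20 heavy atoms
  flexible        = "C1CCN(CC1)CCCCCN1CCCCC1"                   # > 3 rotatable bonds
)

# substituent library; attachment is always through atom 1 of the fragment
FIXTURE_SIDECHAINS <- c(
  methyl   = "C",
  ethyl    = "CC",
  isopropyl = "C(C)C",
  hydroxyl = "O",
  methoxy  = "OC",
  amino    = "N",
  dimethylamino = "N(C)C",
  fluoro   = "F",
  chloro   = "Cl",
  bromo    = "Br",
  nitrile  = "C#N",
  amide    = "C(N)=O",
  acetyl   = "C(C)=O",
  trifluoromethyl = "C(F)(F)F",
  methylsulfonyl  = "S(C)(=O)=O"
)

#' Specification for a synthetic fixture corpus
#'
#' @param seed integer seed; identical specs give byte-identical corpora.
#' @param n_molecules number of molecules to emit.
#' @param cores named character vector of core SMILES.
#' @param sidechains named character vector of substituent SMILES
#'   (attachment atom is always atom 1).
#' @param attach_probs probability weights for 0, 1, 2, 3 substituents.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7L, n_molecules = 100L,
                         cores = FIXTURE_CORES,
                         sidechains = FIXTURE_SIDECHAINS,
                         attach_probs = c(0.1, 0.35, 0.35, 0.2)) {
  stopifnot(length(cores) > 0L, length(sidechains) > 0L,
            length(attach_probs) == 4L)
  structure(list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
                 cores = cores, sidechains = sidechains,
                 attach_probs = attach_probs / sum(attach_probs)),
            class = "fixture_spec")
}

#' Generate a synthetic corpus with scaffold ground truth
#'
#' Each molecule is a core from the spec's library with 0-3 substituents
#' attached at random hydrogen-bearing sites.  Impossible attachments are
#' resampled with bounded retries, then skipped.
#'
#' @param spec a [fixture_spec()].
#' @return list with `corpus` (data.frame `smiles`, `id`) and `truth`
#'   (data.frame `id`, `smiles`, `core`, `core_smiles`, `sidechains`).
#' @export
generate_corpus <- function(spec = fixture_spec()) {
  rng <- make_rng(spec$seed)
  core_mols <- lapply(spec$cores, parse_smiles)
  side_mols <- lapply(spec$sidechains, parse_smiles)
  rows <- list(); truths <- list()
  for (i in seq_len(spec$n_molecules)) {
    ci <- rng$sample_int(length(core_mols), 1L)
    core <- core_mols[[ci]]
    # weighted choice of substituent count 0..3
    u <- rng$runif(1)
    k <- findInterval(u, cumsum(spec$attach_probs)) # 0..3
    mol <- core
    used_names <- character(0)
    tries <- 0L
    while (length(used_names) < k && tries < 20L) {
      tries <- tries + 1L
      si <- rng$sample_int(length(side_mols), 1L)
      frag <- side_mols[[si]]
      sites <- which(free_valence(mol)[seq_len(mol_natoms(core))] >= 1L)
      if (length(sites) == 0L) break
      site <- sites[rng$sample_int(length(sites), 1L)]
      if (frag$hcount[1] < 1L) next
      mol <- mol_combine(mol, frag, site, 1L, 1L)
      used_names <- c(used_names, names(spec$sidechains)[si])
    }
    id <- sprintf("fix%04d", i)
    smi <- write_smiles(mol)
    rows[[i]] <- data.frame(smiles = smi, id = id, stringsAsFactors = FALSE)
    truths[[i]] <- data.frame(
      id = id, smiles = smi,
      core = names(spec$cores)[ci],
      core_smiles = write_smiles(core_mols[[ci]]),
      sidechains = paste(used_names, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(corpus = do.call(rbind, rows), truth = do.call(rbind, truths))
}
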