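# Standardization, scaffold hierarchy, filters and pair datasets.

test_that("standardize_molecule handles the contract cases", {
  lim <- prep_limits(mw_min = 0, heavy_min = 1L)
  r1 <- standardize_molecule("C1CC", lim)
  expect_true(is_rejection(r1)); expect_equal(r1$reason, "invalid")

  r2 <- standardize_molecule("CCO.Cl", lim)
  expect_s3_class(r2, "molecule_record")
  expect_identical(r2$smiles, canonical_smiles("CCO"))
  expect_equal(r2$n_heavy, 3L)

  r3 <- standardize_molecule("[Na]Cl", lim)
  expect_true(is_rejection(r3)); expect_equal(r3$reason, "metal")

  r4 <- standardize_molecule("CCO", prep_limits())  # below the MW window
  expect_true(is_rejection(r4)); expect_equal(r4$reason, "mw_out_of_range")

  r5 <- standardize_molecule("O=[N+]([O-])c1ccc(CCCCC(N)CCCC)cc1", lim)
  expect_true(is_rejection(r5)); expect_equal(r5$reason, "filter_hit")
  expect_equal(r5$detail, "nitro")

  expect_error(standardize_molecule(""), "non-empty")

  # charge neutralization: protonated amine and carboxylate
  r6 <- standardize_molecule("[NH3+]CCCC([O-])=O", lim)
  expect_identical(r6$smiles, canonical_smiles("NCCCC(O)=O"))
})

test_that("standardization is idempotent", {
  lim <- prep_limits(mw_min = 0, heavy_min = 1L)
  for (s in c("CCO.Cl", "c1ccc(cc1)C(=O)NC1CCNCC1", "[NH3+]CCc1ccccc1")) {
    r <- standardize_molecule(s, lim)
    r2 <- standardize_molecule(r$smiles, lim)
    expect_identical(r2$smiles, r$smiles, label = s)
  }
})

test_that("scaffold hierarchy matches brute-force expectations", {
  expect_equal(extract_scaffold_hierarchy("CCCC"), list())
  tol <- extract_scaffold_hierarchy("Cc1ccccc1")
  expect_equal(length(tol), 1L)
  expect_identical(tol[[1]]$smiles, canonical_smiles("c1ccccc1"))

  h <- extract_scaffold_hierarchy("c1ccc(-c2ccncc2)cc1")
  smis <- vapply(h, `[[`, character(1), "smiles")
  expect_setequal(smis, c(canonical_smiles("c1ccc(-c2ccncc2)cc1"),
                          canonical_smiles("c1ccccc1"),
                          canonical_smiles("c1ccncc1")))
  lvls <- vapply(h, `[[`, integer(1), "level")
  expect_equal(sort(lvls), c(0L, 1L, 1L))
})

test_that("every hierarchy scaffold is a substructure of its parent", {
  gen <- fixture_corpus(60L)
  for (i in seq_len(20L)) {
    mol <- parse_smiles(gen$corpus$smiles[i])
    for (s in extract_scaffold_hierarchy(mol)) {
      mask <- scaffold_atom_mask(mol, parse_smiles(s$smiles))
      expect_equal(length(mask), s$n_heavy)
    }
  }
})

test_that("scaffold filter implements the three printed rules", {
  expect_false(filter_scaffold("c1ccccc1"))          # benzene-only
  expect_true(filter_scaffold("C1CCNCC1"))           # piperidine
  expect_false(filter_scaffold("c1ccncc1CCCCc1ccncc1"))  # too flexible
  # rule interactions
  rec <- scaffold_record("C1CCNCC1")
  expect_equal(rec$n_rings_non_benzene, 1L)
  expect_equal(rec$n_heavy, 6L)
  expect_equal(rec$n_rotatable, 0L)
  # filter is a pure predicate: repeated calls agree
  expect_identical(filter_scaffold("C1CCNCC1"), filter_scaffold("C1CCNCC1"))
})

test_that("scaffold_atom_mask returns a consistent induced match", {
  mask <- scaffold_atom_mask("Cc1ccccc1", "c1ccccc1")
  expect_equal(sort(mask), 2:7)
  expect_equal(scaffold_atom_mask("c1ccncc1", "c1ccncc1"), 1:6)
  expect_error(scaffold_atom_mask("CCO", "c1ccccc1"), "inconsistent_pair")
})

test_that("pair datasets respect mode semantics and determinism", {
  gen <- fixture_corpus(60L)
  lim <- open_limits()
  recs <- list()
  for (i in 1:30) {
    r <- standardize_molecule(gen$corpus$smiles[i], lim, id = gen$corpus$id[i])
    if (!is_rejection(r)) recs[[length(recs) + 1L]] <- r
  }
  ft <- build_pair_dataset(recs, "finetune", seed = 2L, limits = lim)
  pt <- build_pair_dataset(recs, "pretrain", seed = 2L, limits = lim)
  # pretrain: exactly one pair per kept molecule
  expect_equal(nrow(pt$pairs), length(recs) - pt$n_dropped)
  # finetune pair count = sum over molecules of passing scaffolds
  per_mol <- vapply(recs, function(r) {
    sum(vapply(extract_scaffold_hierarchy(r$smiles), filter_scaffold, logical(1)))
  }, numeric(1))
  expect_equal(nrow(ft$pairs), sum(per_mol))
  expect_equal(ft$n_dropped, sum(per_mol == 0))
  # determinism
  pt2 <- build_pair_dataset(recs, "pretrain", seed = 2L, limits = lim)
  expect_identical(pt$pairs, pt2$pairs)
  # empty input
  expect_equal(nrow(build_pair_dataset(list(), "pretrain", 1L)$pairs), 0L)
})

test_that("smi and pairs files round-trip", {
  dir <- withr::local_tempdir()
  df <- data.frame(smiles = c("CCO", "c1ccccc1"), id = c("a", "b"))
  write_smi(df, file.path(dir, "x.smi"))
  writeLines(c("# comment", "", readLines(file.path(dir, "x.smi"))),
             file.path(dir, "y.smi"))
  back <- read_smi(file.path(dir, "y.smi"))
  expect_equal(back$smiles, df$smiles)
  expect_equal(back$id, df$id)

  pairs <- fixture_pairs(60L, seed = 21L)
  write_pairs(pairs, file.path(dir, "p.tsv"))
  back2 <- read_pairs(file.path(dir, "p.tsv"))
  expect_equal(back2$mol_smiles, pairs$mol_smiles)
  expect_equal(back2$scaffold_atoms, pairs$scaffold_atoms)
})
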