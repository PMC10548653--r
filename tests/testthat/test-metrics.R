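# Generation-set metrics and the activity-scorer interface.

test_that("gem_report reproduces the worked example", {
  suppressWarnings(r <- gem_report(c("CCO", "CCO", "CCC", "C1CC")))
  expect_equal(r$validity, 0.75)
  expect_equal(r$uniqueness1k, 2 / 3)
  expect_equal(r$n_valid, 3L)
  # all molecules in the training set: novelty 0
  suppressWarnings(r2 <- gem_report(c("CCO", "CCC"), train_mols = c("OCC", "CCC")))
  expect_equal(r2$novelty, 0)
})

test_that("gem metrics equal an independent set-arithmetic oracle", {
  pool_valid <- c("CCO", "CCC", "c1ccccc1", "C1CCNCC1", "Cc1ccncc1",
                  "CC(C)O", "c1ccncc1", "CC(=O)N", "C1CCOC1", "CCN")
  pool_invalid <- c("C1CC", "xyz", "C((C", "[Qq]")
  train <- c("CCO", "C1CCNCC1")
  train_scaf <- c("c1ccccc1")
  rng <- make_rng(2024L)
  for (rep in 1:3) {
    gen <- c(pool_valid[rng$sample_int(10L, 600L, replace = TRUE)],
             pool_invalid[rng$sample_int(4L, 400L, replace = TRUE)])
    gen <- rng$shuffle(gen)
    r <- gem_report(gen, train, train_scaf, k1 = 300L, k2 = 1000L)

    canon <- vapply(gen, function(s)
      tryCatch(canonical_smiles(s), error = function(e) NA_character_),
      character(1), USE.NAMES = FALSE)
    valid <- !is.na(canon)
    expect_equal(r$validity, sum(valid) / length(gen), tolerance = 1e-12)
    u_at <- function(k) {
      cc <- canon[1:k]; cc <- cc[!is.na(cc)]
      length(unique(cc)) / length(cc)
    }
    expect_equal(r$uniqueness1k, u_at(300L), tolerance = 1e-12)
    expect_equal(r$uniqueness5k, u_at(1000L), tolerance = 1e-12)
    tc <- vapply(train, canonical_smiles, character(1), USE.NAMES = FALSE)
    uv <- unique(canon[valid])
    expect_equal(r$novelty, sum(!(uv %in% tc)) / length(uv), tolerance = 1e-12)
    scafs <- vapply(canon[valid], function(s) {
      m <- murcko_scaffold_mol(parse_smiles(s))
      if (is.null(m)) NA_character_ else write_smiles(m)
    }, character(1), USE.NAMES = FALSE)
    scafs <- scafs[!is.na(scafs)]
    expect_equal(r$scaffold_uniqueness, length(unique(scafs)) / length(scafs),
                 tolerance = 1e-12)
    tsc <- vapply(train_scaf, canonical_smiles, character(1), USE.NAMES = FALSE)
    expect_equal(r$scaffold_novelty,
                 sum(!(unique(scafs) %in% tsc)) / length(unique(scafs)),
                 tolerance = 1e-12)
  }
})

test_that("gem_report is invariant to kekulized vs aromatic formatting", {
  arom <- c("c1ccccc1", "Cc1ccncc1", "c1cc[nH]c1")
  kek <- c("C1=CC=CC=C1", "CC1=CC=NC=C1", "C1=CC=CN1")
  suppressWarnings({
    r1 <- gem_report(arom, train_mols = "c1ccccc1", train_scaffolds = "c1ccccc1")
    r2 <- gem_report(kek, train_mols = "c1ccccc1", train_scaffolds = "c1ccccc1")
  })
  for (nm in c("validity", "uniqueness1k", "filter_rate", "novelty",
               "scaffold_uniqueness", "scaffold_novelty"))
    expect_equal(r1[[nm]], r2[[nm]], label = nm)
})

test_that("hop_check enforces scaffold change plus side-chain retention", {
  ref <- decompose_reference("Cc1ccncc1", "c1ccncc1")
  expect_false(hop_check("Cc1ccncc1", "c1ccncc1", ref))           # same scaffold
  expect_true(hop_check("Cc1ccsc1", "c1ccsc1", ref))              # hopped, chain kept
  expect_false(hop_check("c1ccsc1", "c1ccsc1", ref))              # chain lost
  expect_false(hop_check("Cc1ccsc1", "c1ccsc1", ref, valid = FALSE))
  expect_false(hop_check(NA_character_, "c1ccsc1", ref))
})

test_that("mock scorer is deterministic and representation-invariant", {
  expect_identical(mock_scorer("CCO"), mock_scorer("CCO"))
  expect_identical(mock_scorer("OCC"), mock_scorer("CCO"))
  expect_identical(mock_scorer("C1=CC=CC=C1"), mock_scorer("c1ccccc1"))
  expect_equal(mock_scorer("no-parse"), -Inf)
  expect_false(identical(mock_scorer("CCO", "t1"), mock_scorer("CCO", "t2")))
  # ordering of a reference panel is frozen (regression guard)
  panel <- c("C", "CCO", "c1ccccc1", "C1CCNCC1", "Cc1ccncc1")
  expect_identical(order(vapply(panel, mock_scorer, numeric(1))),
                   order(vapply(panel, mock_scorer, numeric(1))))
})

test_that("sem_report matches a hand-computed 20-molecule case", {
  ref <- decompose_reference("Cc1ccncc1", "c1ccncc1")
  # build 20 records: 12 valid (6 hopped), 8 invalid
  hop_smis <- c("Cc1ccsc1", "Cc1ccoc1", "Cc1cc[nH]c1", "Cc1cncnc1",
                "Cc1ccc(F)nc1", "CC1CCNCC1")
  same_smis <- c("Cc1ccncc1", "Cc1ccncc1", "Cc1ccncc1",
                 "Cc1cnccc1", "Cc1ccncc1", "Cc1ccncc1")
  gen <- data.frame(
    reference_id = "r",
    scaffold_smiles = c(vapply(hop_smis, function(s)
      write_smiles(murcko_scaffold_mol(parse_smiles(s))), character(1)),
      rep(canonical_smiles("c1ccncc1"), 6), rep("bad(", 8)),
    assembled_smiles = c(hop_smis, same_smis, rep(NA_character_, 8)),
    similarity = 0.5,
    valid = c(rep(TRUE, 12), rep(FALSE, 8)),
    hopped = c(rep(TRUE, 6), rep(FALSE, 6), rep(FALSE, 8)),
    stringsAsFactors = FALSE)
  scorer <- default_scorer()
  r <- sem_report(gen, ref, scorer, top_fraction = 1.0)
  # hand computation over the 12 valid molecules
  scores <- vapply(gen$assembled_smiles[1:12], scorer$score, numeric(1))
  ref_score <- scorer$score(ref$mol_canonical)
  hops <- vapply(1:12, function(i)
    hop_check(gen$assembled_smiles[i], gen$scaffold_smiles[i], ref), logical(1))
  expect_equal(r$active_mean, mean(scores), tolerance = 1e-12)
  expect_equal(r$active_rate, mean(scores > ref_score), tolerance = 1e-12)
  expect_equal(r$hop_rate, mean(hops), tolerance = 1e-12)
  expect_equal(r$success_rate, mean(hops & scores > ref_score), tolerance = 1e-12)
  expect_lte(r$success_rate, min(r$active_rate, r$hop_rate))
  # constant scorer: nothing is strictly better than the reference
  const <- activity_scorer("const", +1, function(s, target = "x") 1.0)
  rc <- sem_report(gen, ref, const, top_fraction = 1.0)
  expect_equal(rc$active_rate, 0)
  # zero valid molecules: null report with counts
  r0 <- sem_report(gen[13:20, ], ref)
  expect_null(r0$active_mean)
  expect_equal(r0$n_valid, 0L)
})

test_that("success_rate is bounded by both rates on random sets", {
  rng <- make_rng(31L)
  ref <- decompose_reference("Cc1ccncc1", "c1ccncc1")
  base <- c("Cc1ccsc1", "Cc1ccoc1", "Cc1ccncc1", "CC1CCNCC1", "Cc1cncnc1")
  for (rep in 1:25) {
    idx <- rng$sample_int(5L, 12L, replace = TRUE)
    smis <- base[idx]
    gen <- data.frame(
      reference_id = "r",
      scaffold_smiles = vapply(smis, function(s)
        write_smiles(murcko_scaffold_mol(parse_smiles(s))), character(1)),
      assembled_smiles = smis, similarity = 0.5,
      valid = TRUE,
      hopped = NA, stringsAsFactors = FALSE)
    r <- sem_report(gen, ref, top_fraction = rng$runif(1, 0.2, 1))
    expect_lte(r$success_rate, min(r$active_rate, r$hop_rate) + 1e-12)
  }
})
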