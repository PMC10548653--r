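# Featurization, message passing and the attention readout.

test_that("featurize produces the documented shapes and flags", {
  cfg <- test_config()
  g1 <- featurize("C", cfg)
  expect_equal(g1$n, 1L); expect_equal(g1$nb, 0L); expect_equal(g1$ndir, 0L)
  g2 <- featurize("CC", cfg)
  expect_equal(g2$n, 2L); expect_equal(g2$nb, 1L); expect_equal(g2$ndir, 2L)
  g3 <- featurize("c1ccccc1", cfg)
  expect_equal(g3$n, 6L); expect_equal(g3$nb, 6L)
  # aromatic flag column is the second-to-last node feature
  expect_true(all(g3$X[, cfg$dx - 1L] == 1))
  # aromatic bond one-hot slot 4 set on every bond
  expect_true(all(g3$E[, 4] == 1))
  expect_equal(dim(g3$X), c(6L, cfg$dx))
  expect_equal(dim(g3$E), c(6L, cfg$de))
})

test_that("message passing matches the naive oracle on molecules", {
  cfg <- test_config(n_layers = 2L)
  rng <- make_rng(77L)
  params <- encoder_init(cfg, rng)
  for (s in c("CC", "CCO", "C1CC1", "CC(N)=O", "c1ccncc1")) {
    g <- featurize(s, cfg)
    fwd <- encoder_forward(g, mask = seq_len(g$n), params, cfg)
    oracle <- naive_message_pass(g, params, cfg$n_layers)
    expect_equal(fwd$cache$H_nout, oracle$H_nout, tolerance = 1e-10, label = s)
    expect_equal(fwd$cache$H_eout, oracle$H_eout, tolerance = 1e-10, label = s)
  }
})

test_that("isolated node and single-bond limits behave per the equations", {
  cfg <- test_config(n_layers = 1L)
  rng <- make_rng(5L)
  params <- encoder_init(cfg, rng)
  g <- featurize("C", cfg)
  fwd <- encoder_forward(g, mask = 1L, params, cfg)
  # empty neighborhood: h^{l+1} = ReLU(0 + h^0) = h^0 (h^0 is already >= 0)
  expect_equal(fwd$cache$H_nout, fwd$cache$H0n)
  # edge view of a single bond: both directed sums are empty
  g2 <- featurize("CC", cfg)
  fwd2 <- encoder_forward(g2, mask = 1:2, params, cfg)
  expect_equal(fwd2$cache$He[[2]], fwd2$cache$H0e)
})

test_that("attention weights are distributions and the readout has fixed size", {
  cfg <- test_config()
  rng <- make_rng(9L)
  params <- encoder_init(cfg, rng)
  for (s in c("CCO", "CC(C)Cc1ccncc1", "C1CCNCC1")) {
    g <- featurize(s, cfg)
    mask <- seq_len(min(3L, g$n))
    fwd <- encoder_forward(g, mask, params, cfg)
    expect_equal(length(fwd$Z_sca), cfg$r * cfg$d_out)
    expect_equal(length(fwd$Z_side), cfg$r * cfg$d_out)
    expect_equal(rowSums(fwd$cache$att_sca$A), rep(1, cfg$r), tolerance = 1e-9)
  }
  # single scaffold atom: each head's weight is exactly 1, Z_sca stacks that row
  g <- featurize("CC", cfg)
  fwd <- encoder_forward(g, mask = 1L, params, cfg)
  expect_equal(as.vector(fwd$cache$att_sca$A), rep(1, cfg$r))
  expect_equal(fwd$Z_sca, rep(fwd$cache$Hfull[1, ], cfg$r))
  # all-scaffold molecule: Z_side is the zero vector
  fwd2 <- encoder_forward(g, mask = 1:2, params, cfg)
  expect_equal(fwd2$Z_side, numeric(cfg$r * cfg$d_out))
})

test_that("embeddings are invariant under atom permutations", {
  cfg <- test_config()
  rng <- make_rng(13L)
  params <- encoder_init(cfg, rng)
  mol <- parse_smiles("CC(N)=O")
  base <- NULL
  g0 <- featurize(mol, cfg)
  mask0 <- c(1L, 2L)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4L), , drop = FALSE]
  for (ri in seq_len(nrow(perms))) {
    p <- as.integer(perms[ri, ])
    inv <- order(p)
    m2 <- scafhop:::permute_mol(mol, p)
    fwd <- encoder_forward(featurize(m2, cfg), sort(inv[mask0]), params, cfg)
    if (is.null(base)) base <- fwd
    expect_equal(fwd$Z_sca, base$Z_sca, tolerance = 1e-9)
    expect_equal(fwd$Z_side, base$Z_side, tolerance = 1e-9)
    expect_equal(fwd$mu, base$mu, tolerance = 1e-9)
    expect_equal(fwd$sigma, base$sigma, tolerance = 1e-9)
  }
})

test_that("latent head gives positive sigma and responds to input", {
  cfg <- test_config()
  rng <- make_rng(3L)
  params <- encoder_init(cfg, rng)
  g1 <- featurize("CCO", cfg); g2 <- featurize("c1ccncc1", cfg)
  f1 <- encoder_forward(g1, 1:3, params, cfg)
  f2 <- encoder_forward(g2, 1:6, params, cfg)
  expect_true(all(f1$sigma > 0))
  expect_false(isTRUE(all.equal(f1$mu, f2$mu)))
  # zero heads give mu = 0, sigma = 1
  p0 <- params; p0$W_mu[] <- 0; p0$b_mu[] <- 0; p0$W_lv[] <- 0; p0$b_lv[] <- 0
  f0 <- encoder_forward(g1, 1:3, p0, cfg)
  expect_equal(f0$mu, numeric(cfg$d_z))
  expect_equal(f0$sigma, rep(1, cfg$d_z))
})

test_that("encoder gradients match finite differences", {
  cfg <- sh_config(h_node = 5L, h_edge = 4L, n_layers = 2L, r = 2L,
                   d_attn = 3L, d_z = 3L, emb_dim = 4L, gru_hidden = 6L,
                   gru_layers = 1L, max_len = 20L)
  rng <- make_rng(31L)
  params <- encoder_init(cfg, rng)
  g <- featurize("CC(N)=O", cfg)
  mask <- c(1L, 2L)
  wmu <- rng$rnorm(cfg$d_z); wlv <- rng$rnorm(cfg$d_z)
  wzs <- rng$rnorm(cfg$r * cfg$d_out)
  lossf <- function(p) {
    f <- encoder_forward(g, mask, p, cfg)
    sum(wmu * f$mu) + sum(wlv * f$logv) + sum(wzs * f$Z_side)
  }
  fwd <- encoder_forward(g, mask, params, cfg)
  grads <- encoder_backward(fwd, dmu = wmu, dlogv = wlv, dZ_side = wzs,
                            params = params, config = cfg,
                            grads = scafhop:::encoder_grad_zero(params))
  h <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    idx <- round(seq(1, length(p), length.out = min(4, length(p))))
    for (ii in idx) {
      p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + h
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - h
      num <- (lossf(p1) - lossf(p2)) / (2 * h)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("d%s[%d]", nm, ii))
    }
  }
})
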