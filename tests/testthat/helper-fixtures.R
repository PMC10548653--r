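# Shared test fixtures, built lazily and memoized for the whole run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# small model geometry used throughout the tests; widths are scaled down
# from the package defaults to keep CPU time inside the suite budget
test_config <- function(...) {
  args <- list(h_node = 16L, h_edge = 16L, n_layers = 2L, r = 2L, d_attn = 8L,
               d_z = 8L, emb_dim = 16L, gru_hidden = 48L, gru_layers = 2L,
               max_len = 60L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sh_config, args)
}

# permissive limits: fixture molecules are small, so the drug-like MW window
# is opened up for pipeline tests
open_limits <- function() {
  prep_limits(mw_min = 0, mw_max = 1e4, heavy_min = 1L, heavy_max = 100L)
}

fixture_corpus <- function(n = 120L, seed = 11L) {
  memo(sprintf("corpus_%d_%d", n, seed), function()
    generate_corpus(fixture_spec(seed = seed, n_molecules = n)))
}

fixture_pairs <- function(n = 120L, seed = 11L, mode = "pretrain") {
  memo(sprintf("pairs_%d_%d_%s", n, seed, mode), function() {
    gen <- fixture_corpus(n, seed)
    prepare_dataset(gen$corpus, mode = mode, seed = 5L,
                    limits = open_limits())$pairs
  })
}

# a tiny trained model shared by decoder/assembly tests (quick, loose fit)
tiny_model <- function() {
  memo("tiny_model", function() {
    pairs <- fixture_pairs(60L, seed = 21L)
    train_model(pairs,
                train_config(epochs = 25L, batch_size = 32L, lr = 3e-3,
                             beta_start = 0, beta_end = 0.02, seed = 3L),
                model_config = test_config())$model
  })
}

# naive nested-loop re-implementation of the message-passing equations,
# independent of the vectorized encoder path (the oracle for equivalence
# tests); operates directly on a molecule_graph and encoder params
naive_message_pass <- function(g, params, L) {
  n <- g$n
  relu0 <- function(x) pmax(x, 0)
  H0 <- matrix(0, n, nrow(params$W_nin))
  for (v in seq_len(n)) H0[v, ] <- relu0(params$W_nin %*% g$X[v, ])
  H <- H0
  for (l in seq_len(L)) {
    Hn <- matrix(0, n, ncol(H))
    for (v in seq_len(n)) {
      s <- numeric(ncol(H) + ncol(g$E))
      for (k in seq_len(g$ndir)) {
        if (g$dst[k] == v) {
          u <- g$src[k]
          s <- s + c(H[u, ], g$E[g$bond[k], ])
        }
      }
      Hn[v, ] <- relu0(params$W_node %*% s + H0[v, ])
    }
    H <- Hn
  }
  # edge-central view
  He0 <- matrix(0, g$ndir, nrow(params$W_ein))
  for (k in seq_len(g$ndir)) He0[k, ] <- relu0(params$W_ein %*% g$E[g$bond[k], ])
  He <- He0
  for (l in seq_len(L)) {
    Hen <- matrix(0, g$ndir, ncol(He))
    for (k in seq_len(g$ndir)) {
      v <- g$src[k]; w <- g$dst[k]
      s <- numeric(ncol(He) + ncol(g$X))
      for (j in seq_len(g$ndir)) {
        if (g$dst[j] == v && j != g$rev[k]) {
          s <- s + c(He[j, ], g$X[g$src[j], ])
        }
      }
      Hen[k, ] <- relu0(params$W_edge %*% s + He0[k, ])
    }
    He <- Hen
  }
  Hout <- matrix(0, n, nrow(params$W_eout))
  for (v in seq_len(n)) {
    s <- numeric(ncol(He) + ncol(g$X))
    for (k in seq_len(g$ndir)) {
      if (g$dst[k] == v) s <- s + c(He[k, ], g$X[g$src[k], ])
    }
    Hout[v, ] <- relu0(params$W_eout %*% s)
  }
  list(H_nout = H, H_eout = Hout)
}

# molecule_graph for an arbitrary abstract graph with random features (for
# oracle tests that range over all small graphs, not only chemical ones)
graph_fixture <- function(edges, n, dx, de, rng) {
  X <- matrix(rng$runif(n * dx, -1, 1), n, dx)
  nb <- nrow(edges)
  E <- matrix(if (nb > 0L) rng$runif(nb * de, -1, 1) else numeric(0), max(nb, 0L), de)
  if (nb > 0L) {
    src <- c(edges[, 1], edges[, 2]); dst <- c(edges[, 2], edges[, 1])
    bond <- c(seq_len(nb), seq_len(nb)); rev_idx <- c(seq_len(nb) + nb, seq_len(nb))
  } else src <- dst <- bond <- rev_idx <- integer(0)
  ndir <- length(src)
  Agg <- matrix(0, n, ndir); if (ndir) Agg[cbind(dst, seq_len(ndir))] <- 1
  Ssrc <- matrix(0, ndir, n); if (ndir) Ssrc[cbind(seq_len(ndir), src)] <- 1
  B <- matrix(0, ndir, ndir)
  for (k in seq_len(ndir)) {
    js <- which(dst == src[k]); js <- js[js != rev_idx[k]]
    B[k, js] <- 1
  }
  structure(list(n = n, nb = nb, ndir = ndir, X = X, E = E, src = src,
                 dst = dst, bond = bond, rev = rev_idx, Agg = Agg,
                 Ssrc = Ssrc, B = B), class = "molecule_graph")
}

tokenize_safe <- function(s) {
  if (!nzchar(s)) return(character(0))
  tryCatch(tokenize(s), error = function(e) strsplit(s, "")[[1]])
}

# all connected labeled graphs on n nodes, as edge matrices
connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1L)) > 0L)
    edges <- pairs[sel, , drop = FALSE]
    # connectivity check
    adj <- vector("list", n)
    for (i in seq_len(nrow(edges))) {
      adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
      adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
    }
    seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    if (all(seen)) out[[length(out) + 1L]] <- edges
  }
  out
}
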