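# Multi-view message-passing encoder with masked self-attention readout.
#
# Two message-passing views are run over the molecular graph: a node-central
# view (hidden node states aggregate neighbor states concatenated with raw
# bond features, plus a residual to the initial state) and an edge-central
# view over directed bond states with backtracking excluded.  Per-node
# outputs of the two views are concatenated and pooled separately over
# scaffold and side-chain atoms by shared multi-head structured
# self-attention, giving fixed-length embeddings Z_sca and Z_side.  Z_sca is
# mapped to the mean and log-variance of a diagonal Gaussian latent.
#
# Forward passes cache every intermediate needed by the manual backward
# pass; gradients are verified against finite differences in the test
# suite.

relu <- function(x) { x[x < 0] <- 0; x }

#' Initialize encoder parameters
#' @param config an [sh_config()].
#' @param rng an RNG stream from [make_rng()].
#' @return named list of weight matrices.
#' @export
encoder_init <- function(config, rng) {
  list(
    W_nin  = init_mat(rng, config$h_node, config$dx),
    W_ein  = init_mat(rng, config$h_edge, config$de),
    W_node = init_mat(rng, config$h_node, config$h_node + config$de),
    W_edge = init_mat(rng, config$h_edge, config$h_edge + config$dx),
    W_eout = init_mat(rng, config$h_edge, config$h_edge + config$dx),
    W1     = init_mat(rng, config$d_attn, config$d_out),
    W2     = init_mat(rng, config$r, config$d_attn),
    W_mu   = init_mat(rng, config$d_z, config$r * config$d_out),
    b_mu   = zeros(config$d_z),
    W_lv   = init_mat(rng, config$d_z, config$r * config$d_out),
    b_lv   = zeros(config$d_z)
  )
}

# row-wise softmax
softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# attention readout over a row subset of the concatenated node matrix;
# returns flattened r*(d_out) vector plus caches
attention_readout <- function(Hs, params) {
  Tm <- tanh(params$W1 %*% t(Hs))          # d_attn x m
  S  <- params$W2 %*% Tm                   # r x m
  A  <- softmax_rows(S)                    # rows sum to 1 over atoms
  Z  <- A %*% Hs                           # r x d_out
  list(z = as.vector(t(Z)), A = A, Tm = Tm, Hs = Hs, Z = Z)
}

attention_backward <- function(dz, cache, params, grads) {
  r <- nrow(cache$A); d_out <- ncol(cache$Hs)
  dZ <- matrix(dz, nrow = d_out, ncol = r)   # inverse of as.vector(t(Z))
  dZ <- t(dZ)
  dA  <- dZ %*% t(cache$Hs)
  dHs <- t(cache$A) %*% dZ
  dS  <- cache$A * (dA - rowSums(dA * cache$A))
  grads$W2 <- grads$W2 + dS %*% t(cache$Tm)
  dT <- t(params$W2) %*% dS
  dpre <- dT * (1 - cache$Tm^2)
  grads$W1 <- grads$W1 + dpre %*% cache$Hs
  dHs <- dHs + t(t(params$W1) %*% dpre)
  list(dHs = dHs, grads = grads)
}

#' Encoder forward pass for one molecule
#'
#' @param g a `molecule_graph` from [featurize()].
#' @param mask integer vector of scaffold atom indices (1-based).
#' @param params encoder parameter list.
#' @param config an [sh_config()].
#' @return list with `Z_sca`, `Z_side`, `mu`, `logv`, `sigma` and a cache
#'   for the backward pass.  When all atoms are scaffold atoms, `Z_side` is
#'   the zero vector.
#' @export
encoder_forward <- function(g, mask, params, config) {
  n <- g$n
  if (n == 0L) stop("empty molecule")
  if (length(mask) == 0L) stop("empty scaffold mask")
  L <- config$n_layers

  # node-central view
  H0n <- relu(g$X %*% t(params$W_nin))                   # n x h_node
  Hn <- list(H0n)
  Pn <- list()
  for (l in seq_len(L)) {
    H <- Hn[[l]]
    if (g$ndir > 0L) {
      P <- cbind(H[g$src, , drop = FALSE], g$E[g$bond, , drop = FALSE])
      M <- g$Agg %*% P
    } else {
      P <- matrix(0, 0L, config$h_node + config$de)
      M <- matrix(0, n, config$h_node + config$de)
    }
    Pn[[l]] <- M
    Hn[[l + 1L]] <- relu(M %*% t(params$W_node) + H0n)
  }
  H_nout <- Hn[[L + 1L]]

  # edge-central view (directed states)
  if (g$ndir > 0L) {
    E0dir <- g$E[g$bond, , drop = FALSE]
    H0e <- relu(E0dir %*% t(params$W_ein))               # ndir x h_edge
    Xsrc <- g$X[g$src, , drop = FALSE]
    He <- list(H0e)
    Pe <- list()
    for (l in seq_len(L)) {
      Me <- g$B %*% cbind(He[[l]], Xsrc)
      Pe[[l]] <- Me
      He[[l + 1L]] <- relu(Me %*% t(params$W_edge) + H0e)
    }
    Nagg <- g$Agg %*% cbind(He[[L + 1L]], Xsrc)
    H_eout <- relu(Nagg %*% t(params$W_eout))
  } else {
    E0dir <- matrix(0, 0L, config$de); H0e <- matrix(0, 0L, config$h_edge)
    Xsrc <- matrix(0, 0L, config$dx); He <- list(H0e); Pe <- list()
    Nagg <- matrix(0, n, config$h_edge + config$dx)
    H_eout <- relu(Nagg %*% t(params$W_eout))
  }

  Hfull <- cbind(H_nout, H_eout)                         # n x d_out

  side <- setdiff(seq_len(n), mask)
  att_sca <- attention_readout(Hfull[mask, , drop = FALSE], params)
  if (length(side) > 0L) {
    att_side <- attention_readout(Hfull[side, , drop = FALSE], params)
    Z_side <- att_side$z
  } else {
    att_side <- NULL
    Z_side <- numeric(config$r * config$d_out)
  }
  Z_sca <- att_sca$z

  mu   <- as.vector(params$W_mu %*% Z_sca + params$b_mu)
  logv <- as.vector(params$W_lv %*% Z_sca + params$b_lv)

  list(Z_sca = Z_sca, Z_side = Z_side, mu = mu, logv = logv,
       sigma = exp(logv / 2),
       cache = list(g = g, mask = mask, side = side, Hn = Hn, Pn = Pn,
                    He = He, Pe = Pe, H0n = H0n, H0e = H0e, E0dir = E0dir,
                    Xsrc = Xsrc, Nagg = Nagg, H_nout = H_nout,
                    H_eout = H_eout, Hfull = Hfull,
                    att_sca = att_sca, att_side = att_side))
}

# zero-filled gradient container matching encoder params
encoder_grad_zero <- function(params) lapply(params, function(p) p * 0)

#' Encoder backward pass
#'
#' @param fwd output of [encoder_forward()].
#' @param dmu,dlogv,dZ_sca,dZ_side upstream gradients (vectors; may be NULL
#'   for zero).
#' @param params encoder parameters.
#' @param config an [sh_config()].
#' @param grads accumulator created by `encoder_grad_zero()`.
#' @return updated gradient accumulator.
#' @export
encoder_backward <- function(fwd, dmu = NULL, dlogv = NULL,
                             dZ_sca = NULL, dZ_side = NULL,
                             params, config, grads) {
  cc <- fwd$cache
  g <- cc$g; n <- g$n; L <- config$n_layers

  dZs <- if (is.null(dZ_sca)) numeric(config$r * config$d_out) else dZ_sca
  if (!is.null(dmu)) {
    grads$W_mu <- grads$W_mu + outer(dmu, fwd$Z_sca)
    grads$b_mu <- grads$b_mu + dmu
    dZs <- dZs + as.vector(t(params$W_mu) %*% dmu)
  }
  if (!is.null(dlogv)) {
    grads$W_lv <- grads$W_lv + outer(dlogv, fwd$Z_sca)
    grads$b_lv <- grads$b_lv + dlogv
    dZs <- dZs + as.vector(t(params$W_lv) %*% dlogv)
  }

  dHfull <- matrix(0, n, config$d_out)
  ab <- attention_backward(dZs, cc$att_sca, params, grads)
  grads <- ab$grads
  dHfull[cc$mask, ] <- dHfull[cc$mask, ] + ab$dHs
  if (!is.null(cc$att_side) && !is.null(dZ_side)) {
    ab2 <- attention_backward(dZ_side, cc$att_side, params, grads)
    grads <- ab2$grads
    dHfull[cc$side, ] <- dHfull[cc$side, ] + ab2$dHs
  }

  dH_nout <- dHfull[, seq_len(config$h_node), drop = FALSE]
  dH_eout <- dHfull[, config$h_node + seq_len(config$h_edge), drop = FALSE]

  # edge view backward
  if (g$ndir > 0L) {
    dpre <- dH_eout * (cc$H_eout > 0)
    grads$W_eout <- grads$W_eout + t(dpre) %*% cc$Nagg
    dN <- dpre %*% params$W_eout
    dcb <- t(g$Agg) %*% dN
    dHe <- dcb[, seq_len(config$h_edge), drop = FALSE]
    dH0e <- matrix(0, g$ndir, config$h_edge)
    for (l in rev(seq_len(L))) {
      act <- cc$He[[l + 1L]]
      dpre <- dHe * (act > 0)
      grads$W_edge <- grads$W_edge + t(dpre) %*% cc$Pe[[l]]
      dH0e <- dH0e + dpre
      dMe <- dpre %*% params$W_edge
      dcb <- t(g$B) %*% dMe
      dHe <- dcb[, seq_len(config$h_edge), drop = FALSE]
    }
    dH0e <- dH0e + dHe                       # He[[1]] is H0e itself
    dpre0 <- dH0e * (cc$H0e > 0)
    grads$W_ein <- grads$W_ein + t(dpre0) %*% cc$E0dir
  }

  # node view backward
  dHn <- dH_nout
  dH0n <- matrix(0, n, config$h_node)
  for (l in rev(seq_len(L))) {
    act <- cc$Hn[[l + 1L]]
    dpre <- dHn * (act > 0)
    grads$W_node <- grads$W_node + t(dpre) %*% cc$Pn[[l]]
    dH0n <- dH0n + dpre                      # residual connection
    dM <- dpre %*% params$W_node
    if (g$ndir > 0L) {
      dP <- t(g$Agg) %*% dM                  # ndir x (h_node + de)
      dHn <- t(g$Ssrc) %*% dP[, seq_len(config$h_node), drop = FALSE]
    } else {
      dHn <- matrix(0, n, config$h_node)
    }
  }
  dH0n <- dH0n + dHn                         # Hn[[1]] is H0n itself
  dpre0 <- dH0n * (cc$H0n > 0)
  grads$W_nin <- grads$W_nin + t(dpre0) %*% g$X
  grads
}
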