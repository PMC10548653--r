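# SMILES-token GRU decoder.
#
# Scaffold SMILES are tokenized with the standard regex scheme, embedded,
# and decoded by a stack of GRU layers whose gates follow the update-gate
# sign convention h_t = (1 - f_t) * h_{t-1} + f_t * hhat_t.  The initial
# hidden state of every layer is a learned linear projection of
# concat(Z_side, z).

BOS <- "<bos>"; EOS <- "<eos>"; PAD <- "<pad>"
RESERVED_TOKENS <- c(BOS, EOS, PAD)

#' Tokenize a SMILES string for the decoder
#'
#' Same token alphabet as [smiles_tokens()]: bracket atoms, two-letter
#' elements and `%NN` closures are single tokens.  The concatenation of the
#' tokens reproduces the input exactly.
#'
#' @param s a SMILES string.
#' @return character vector of tokens.
#' @export
tokenize <- function(s) smiles_tokens(s)

#' Build a token vocabulary from a scaffold corpus
#'
#' The vocabulary is the three reserved tokens (`<bos>`, `<eos>`, `<pad>` at
#' fixed indices 1-3) followed by the sorted unique tokens of the corpus.
#'
#' @param corpus character vector of SMILES strings.
#' @return a `vocabulary` list with `tokens` and lookup functions.
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- sort(unique(unlist(lapply(corpus, tokenize))))
  tokens <- c(RESERVED_TOKENS, toks)
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "vocabulary")
}

#' Vocabulary size
#' @param vocab a `vocabulary`.
#' @return integer scalar.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode a SMILES string as vocabulary indices
#' @param vocab a `vocabulary`.
#' @param s SMILES string.
#' @param add_bos,add_eos wrap the sequence in sentinels.
#' @return integer vector of indices.
#' @export
encode_tokens <- function(vocab, s, add_bos = TRUE, add_eos = TRUE) {
  toks <- tokenize(s)
  idx <- vocab$index[toks]
  if (anyNA(idx))
    stop("unknown_token: '", paste(toks[is.na(idx)], collapse = "','"),
         "' in ", s)
  out <- unname(idx)
  if (add_bos) out <- c(vocab$index[[BOS]], out)
  if (add_eos) out <- c(out, vocab$index[[EOS]])
  out
}

#' Decode vocabulary indices back to a SMILES string
#' @param vocab a `vocabulary`.
#' @param idx integer vector.
#' @return the concatenated string (sentinels and padding stripped).
#' @export
decode_tokens <- function(vocab, idx) {
  toks <- vocab$tokens[idx]
  toks <- toks[!(toks %in% RESERVED_TOKENS)]
  paste(toks, collapse = "")
}

#' Serialize / restore a vocabulary as a JSON token list
#' @param vocab a `vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
}

#' @rdname write_vocabulary
#' @return `read_vocabulary` returns the restored `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  tokens <- unlist(jsonlite::read_json(path))
  stopifnot(identical(tokens[1:3], RESERVED_TOKENS))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "vocabulary")
}

#' Initialize decoder parameters
#' @param config an [sh_config()].
#' @param vocab_n vocabulary size.
#' @param rng RNG stream.
#' @return named list: embedding, per-layer gate weights, output head and
#'   the h0 bridge from `concat(Z_side, z)`.
#' @export
decoder_init <- function(config, vocab_n, rng) {
  hid <- config$gru_hidden
  layers <- vector("list", config$gru_layers)
  for (l in seq_len(config$gru_layers)) {
    ind <- if (l == 1L) config$emb_dim else hid
    layers[[l]] <- list(
      Wf = init_mat(rng, hid, ind), Uf = init_mat(rng, hid, hid), bf = zeros(hid),
      Wr = init_mat(rng, hid, ind), Ur = init_mat(rng, hid, hid), br = zeros(hid),
      Wh = init_mat(rng, hid, ind), Uh = init_mat(rng, hid, hid), bh = zeros(hid))
  }
  bridge_in <- config$r * config$d_out + config$d_z
  list(Emb = init_mat(rng, vocab_n, config$emb_dim),
       layers = layers,
       W_out = init_mat(rng, vocab_n, hid), b_out = zeros(vocab_n),
       W_b = init_mat(rng, hid, bridge_in), b_b = zeros(hid))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU step for a batch
#'
#' Gates: `f = sigmoid(Wf x + Uf h + bf)` (update), `r` analogous (reset),
#' candidate `hhat = tanh(Wh x + Uh (r * h) + bh)`, new state
#' `h' = (1 - f) * h + f * hhat`.
#'
#' @param x batch x input matrix.
#' @param h batch x hidden matrix.
#' @param lp one layer's parameter list.
#' @return list with `h` and the gate cache.
#' @export
gru_step <- function(x, h, lp) {
  f  <- sigmoid(x %*% t(lp$Wf) + h %*% t(lp$Uf) +
                  matrix(lp$bf, nrow(x), length(lp$bf), byrow = TRUE))
  r  <- sigmoid(x %*% t(lp$Wr) + h %*% t(lp$Ur) +
                  matrix(lp$br, nrow(x), length(lp$br), byrow = TRUE))
  rh <- r * h
  hh <- tanh(x %*% t(lp$Wh) + rh %*% t(lp$Uh) +
               matrix(lp$bh, nrow(x), length(lp$bh), byrow = TRUE))
  hnew <- (1 - f) * h + f * hh
  list(h = hnew, f = f, r = r, hh = hh, rh = rh, x = x, h_prev = h)
}

gru_step_backward <- function(dh, cache, lp, gl) {
  f <- cache$f; r <- cache$r; hh <- cache$hh
  dhh <- dh * f
  df  <- dh * (hh - cache$h_prev)
  dh_prev <- dh * (1 - f)
  da_h <- dhh * (1 - hh^2)
  gl$Wh <- gl$Wh + t(da_h) %*% cache$x
  gl$Uh <- gl$Uh + t(da_h) %*% cache$rh
  gl$bh <- gl$bh + colSums(da_h)
  drh <- da_h %*% lp$Uh
  dr <- drh * cache$h_prev
  dh_prev <- dh_prev + drh * r
  da_f <- df * f * (1 - f)
  da_r <- dr * r * (1 - r)
  gl$Wf <- gl$Wf + t(da_f) %*% cache$x
  gl$Uf <- gl$Uf + t(da_f) %*% cache$h_prev
  gl$bf <- gl$bf + colSums(da_f)
  gl$Wr <- gl$Wr + t(da_r) %*% cache$x
  gl$Ur <- gl$Ur + t(da_r) %*% cache$h_prev
  gl$br <- gl$br + colSums(da_r)
  dx <- da_f %*% lp$Wf + da_r %*% lp$Wr + da_h %*% lp$Wh
  dh_prev <- dh_prev + da_f %*% lp$Uf + da_r %*% lp$Ur
  list(dx = dx, dh_prev = dh_prev, gl = gl)
}

# project concat(Z_side, z) to the shared initial hidden state
bridge_h0 <- function(dec, h0raw_mat) {
  h0raw_mat %*% t(dec$W_b) +
    matrix(dec$b_b, nrow(h0raw_mat), length(dec$b_b), byrow = TRUE)
}

#' Teacher-forced decoder forward pass
#'
#' @param dec decoder parameters.
#' @param config an [sh_config()].
#' @param h0 batch x hidden matrix of initial states (used by all layers).
#' @param inputs batch x T integer matrix of input token indices.
#' @return list with `logits` (batch x T x V array) and caches.
#' @export
decoder_forward <- function(dec, config, h0, inputs) {
  Tlen <- ncol(inputs); Bn <- nrow(inputs)
  if (Tlen > config$max_len + 1L) stop("target longer than max_len")
  V <- nrow(dec$Emb); hid <- config$gru_hidden; nl <- config$gru_layers
  h <- replicate(nl, h0, simplify = FALSE)
  caches <- vector("list", Tlen)
  logits <- array(0, c(Bn, Tlen, V))
  for (t in seq_len(Tlen)) {
    x <- dec$Emb[inputs[, t], , drop = FALSE]
    step_caches <- vector("list", nl)
    for (l in seq_len(nl)) {
      st <- gru_step(x, h[[l]], dec$layers[[l]])
      step_caches[[l]] <- st
      h[[l]] <- st$h
      x <- st$h
    }
    caches[[t]] <- step_caches
    logits[, t, ] <- x %*% t(dec$W_out) +
      matrix(dec$b_out, Bn, V, byrow = TRUE)
  }
  list(logits = logits, caches = caches, inputs = inputs, h_final = h)
}

decoder_grad_zero <- function(dec) {
  g <- list(Emb = dec$Emb * 0,
            layers = lapply(dec$layers, function(l) lapply(l, function(p) p * 0)),
            W_out = dec$W_out * 0, b_out = dec$b_out * 0,
            W_b = dec$W_b * 0, b_b = dec$b_b * 0)
  g
}

# backward through the teacher-forced decoder given dlogits (B x T x V);
# returns gradient list plus dh0 (B x hid, summed over layers)
decoder_backward <- function(dec, config, fwd, dlogits) {
  Tlen <- dim(dlogits)[2]; Bn <- dim(dlogits)[1]
  nl <- config$gru_layers; hid <- config$gru_hidden
  g <- decoder_grad_zero(dec)
  dh_next <- replicate(nl, matrix(0, Bn, hid), simplify = FALSE)
  for (t in rev(seq_len(Tlen))) {
    dl <- matrix(dlogits[, t, ], nrow = Bn)
    top <- fwd$caches[[t]][[nl]]$h
    g$W_out <- g$W_out + t(dl) %*% top
    g$b_out <- g$b_out + colSums(dl)
    dtop <- dl %*% dec$W_out
    dx_up <- dtop
    for (l in rev(seq_len(nl))) {
      dh <- dh_next[[l]] + dx_up
      st <- fwd$caches[[t]][[l]]
      bk <- gru_step_backward(dh, st, dec$layers[[l]], g$layers[[l]])
      g$layers[[l]] <- bk$gl
      dh_next[[l]] <- bk$dh_prev
      dx_up <- bk$dx
    }
    # dx_up now carries gradient to the embedded input token
    idx <- fwd$inputs[, t]
    for (bi in seq_len(Bn))
      g$Emb[idx[bi], ] <- g$Emb[idx[bi], ] + dx_up[bi, ]
  }
  dh0 <- Reduce(`+`, dh_next)
  list(grads = g, dh0 = dh0)
}

#' Sample a scaffold SMILES autoregressively
#'
#' @param dec decoder parameters.
#' @param config an [sh_config()].
#' @param vocab a `vocabulary`.
#' @param h0 numeric hidden vector (initial state for all layers).
#' @param max_len maximum number of generated tokens.
#' @param temperature softmax temperature; `0` means greedy argmax.
#' @param rng RNG stream (unused when greedy).
#' @return the generated string (may be an invalid SMILES; validity is the
#'   caller's concern).
#' @export
sample_sequence <- function(dec, config, vocab, h0,
                            max_len = config$max_len, temperature = 1.0,
                            rng = make_rng(1L)) {
  nl <- config$gru_layers
  h <- replicate(nl, matrix(h0, 1L), simplify = FALSE)
  tok <- vocab$index[[BOS]]
  out <- integer(0)
  for (t in seq_len(max_len)) {
    x <- dec$Emb[tok, , drop = FALSE]
    for (l in seq_len(nl)) {
      st <- gru_step(x, h[[l]], dec$layers[[l]])
      h[[l]] <- st$h
      x <- st$h
    }
    logit <- as.vector(x %*% t(dec$W_out)) + dec$b_out
    if (temperature <= 0) {
      tok <- which.max(logit)
    } else {
      p <- logit / temperature
      p <- exp(p - max(p)); p <- p / sum(p)
      u <- rng$runif(1)
      tok <- findInterval(u, cumsum(p)) + 1L
      if (tok > length(p)) tok <- length(p)
    }
    if (tok == vocab$index[[EOS]]) break
    out <- c(out, tok)
  }
  decode_tokens(vocab, out)
}
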