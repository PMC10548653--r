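# VAE training: reconstruction + beta-weighted KL, Adam, annealing schedule,
# pretraining and fine-tuning loops, checkpointing.

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param beta_start,beta_end endpoints of the linear KL-weight schedule.
#' @param seed integer seed controlling shuffling, latent noise and
#'   initialization.
#' @param clip_norm global gradient-norm clip.
#' @param checkpoint_every epoch cadence for checkpoint writing (0 = only at
#'   the end).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 64L, lr = 1e-3,
                         beta_start = 0, beta_end = 1, seed = 1L,
                         clip_norm = 5, checkpoint_every = 0L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta_start = beta_start, beta_end = beta_end,
                 seed = as.integer(seed), clip_norm = clip_norm,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Token-level reconstruction loss (mean cross-entropy in nats)
#'
#' @param logits batch x T x V array.
#' @param targets batch x T integer matrix of target indices.
#' @param pad_idx index of the padding token; padded positions are excluded.
#' @return list with `loss` (mean nats per non-pad token), `dlogits`
#'   (gradient of the mean loss), `n_tokens`.
#' @export
reconstruction_loss <- function(logits, targets, pad_idx) {
  Bn <- dim(logits)[1]; Tlen <- dim(logits)[2]; V <- dim(logits)[3]
  mask <- targets != pad_idx
  ntok <- sum(mask)
  if (ntok == 0L) stop("all-PAD target")
  dlogits <- array(0, dim(logits))
  total <- 0
  for (t in seq_len(Tlen)) {
    lg <- matrix(logits[, t, ], nrow = Bn)
    mx <- apply(lg, 1L, max)
    ex <- exp(lg - mx)
    p <- ex / rowSums(ex)
    tgt <- targets[, t]
    mvec <- mask[, t]
    if (any(mvec)) {
      rows <- which(mvec)
      total <- total - sum(log(p[cbind(rows, tgt[rows])]))
      dp <- p
      dp[cbind(rows, tgt[rows])] <- dp[cbind(rows, tgt[rows])] - 1
      dp[!mvec, ] <- 0
      dlogits[, t, ] <- dp / ntok
    }
  }
  list(loss = total / ntok, dlogits = dlogits, n_tokens = ntok)
}

#' Closed-form KL divergence to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) = 1/2 * sum(mu^2 + sigma^2 - 1 -
#' log sigma^2)`, in nats.
#'
#' @param mu mean vector.
#' @param sigma positive scale vector.
#' @return numeric scalar.
#' @export
kl_loss <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

#' KL annealing weight for an epoch
#'
#' Linear, monotone non-decreasing schedule from `beta_start` at epoch 0 to
#' `beta_end` at the final epoch.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return numeric beta.
#' @export
beta_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0L, epoch < cfg$epochs)
  if (cfg$epochs == 1L) return(cfg$beta_end)
  cfg$beta_start + (cfg$beta_end - cfg$beta_start) * epoch / (cfg$epochs - 1L)
}

# ---- Adam over nested parameter lists --------------------------------------

flat_walk <- function(x, f) {
  if (is.list(x)) lapply(x, flat_walk, f = f) else f(x)
}
walk2 <- function(a, b, f) {
  if (is.list(a)) mapply(walk2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(a, b)
}
walk3 <- function(a, b, c, f) {
  if (is.list(a)) mapply(walk3, a, b, c, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(a, b, c)
}

adam_init <- function(params) {
  list(m = flat_walk(params, function(p) p * 0),
       v = flat_walk(params, function(p) p * 0), t = 0L)
}

grad_global_norm <- function(grads) {
  acc <- 0
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else acc <<- acc + sum(x^2)
    invisible(NULL)
  }
  rec(grads)
  sqrt(acc)
}

adam_update <- function(params, grads, state, lr, clip_norm = 5,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- grad_global_norm(grads)
  if (is.finite(clip_norm) && gn > clip_norm)
    grads <- flat_walk(grads, function(g) g * (clip_norm / gn))
  state$t <- state$t + 1L
  state$m <- walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- walk3(params, state$m, state$v, function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = params, state = state)
}

# ---- model bundle ----------------------------------------------------------

#' Create a fresh model bundle
#'
#' @param config an [sh_config()].
#' @param vocab a `vocabulary`.
#' @param seed initialization seed.
#' @return a `sh_model` list with `config`, `vocab`, `enc`, `dec`.
#' @export
model_init <- function(config, vocab, seed = 1L) {
  rng <- make_rng(seed)
  structure(list(config = config, vocab = vocab,
                 enc = encoder_init(config, rng),
                 dec = decoder_init(config, vocab_size(vocab), rng),
                 lr_trained = NA_real_),
            class = "sh_model")
}

#' Save / load a model checkpoint
#'
#' The parameter bundle is serialized with `saveRDS`; a JSON sidecar
#' `<path>.json` records the config and a vocabulary hash for integrity
#' checking at load time.
#'
#' @param model an `sh_model`.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config)[
                 setdiff(names(model$config), c("atom_types"))],
               atom_types = model$config$atom_types,
               vocab_hash = str_hash(paste(model$vocab$tokens, collapse = "\x01")),
               lr_trained = model$lr_trained)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `sh_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    h <- str_hash(paste(model$vocab$tokens, collapse = "\x01"))
    if (!identical(as.numeric(side$vocab_hash), as.numeric(h)))
      stop("checkpoint sidecar vocabulary hash mismatch")
  }
  model
}

# prepare one pair row for training: graph, mask, token indices
compile_pair <- function(row, config, vocab) {
  mol <- parse_smiles(row$mol_smiles)
  g <- featurize(mol, config)
  mask <- as.integer(strsplit(row$scaffold_atoms, ",", fixed = TRUE)[[1]]) + 1L
  seqs <- encode_tokens(vocab, row$scaffold_smiles)
  list(g = g, mask = mask, seq = seqs)
}

# loss + gradients for one minibatch of compiled pairs
batch_step <- function(model, batch, beta, eps_mat, compute_grads = TRUE) {
  cfg <- model$config; vocab <- model$vocab
  Bn <- length(batch)
  pad <- vocab$index[[PAD]]
  d_z <- cfg$d_z

  encs <- vector("list", Bn)
  H0raw <- matrix(0, Bn, cfg$r * cfg$d_out + d_z)
  kl_sum <- 0
  for (i in seq_len(Bn)) {
    e <- encoder_forward(batch[[i]]$g, batch[[i]]$mask, model$enc, cfg)
    encs[[i]] <- e
    z <- e$mu + e$sigma * eps_mat[i, ]
    H0raw[i, ] <- c(e$Z_side, z)
    kl_sum <- kl_sum + kl_loss(e$mu, e$sigma)
  }
  kl_mean <- kl_sum / Bn

  h0 <- bridge_h0(model$dec, H0raw)
  lens <- vapply(batch, function(b) length(b$seq), integer(1))
  Tlen <- max(lens) - 1L
  inputs <- matrix(pad, Bn, Tlen)
  targets <- matrix(pad, Bn, Tlen)
  for (i in seq_len(Bn)) {
    s <- batch[[i]]$seq
    inputs[i, seq_len(lens[i] - 1L)] <- s[-lens[i]]
    targets[i, seq_len(lens[i] - 1L)] <- s[-1L]
  }
  fwd <- decoder_forward(model$dec, cfg, h0, inputs)
  rec <- reconstruction_loss(fwd$logits, targets, pad)
  out <- list(recon = rec$loss, kl = kl_mean,
              total = rec$loss + beta * kl_mean)
  if (!compute_grads) return(out)

  bk <- decoder_backward(model$dec, cfg, fwd, rec$dlogits)
  dgrads <- bk$grads
  # bridge backward
  dgrads$W_b <- dgrads$W_b + t(bk$dh0) %*% H0raw
  dgrads$b_b <- dgrads$b_b + colSums(bk$dh0)
  dH0raw <- bk$dh0 %*% model$dec$W_b

  egrads <- encoder_grad_zero(model$enc)
  nz <- cfg$r * cfg$d_out
  for (i in seq_len(Bn)) {
    e <- encs[[i]]
    dZ_side <- dH0raw[i, seq_len(nz)]
    dz <- dH0raw[i, nz + seq_len(d_z)]
    dmu <- dz + beta * e$mu / Bn
    dlogv <- dz * eps_mat[i, ] * e$sigma / 2 +
      beta * 0.5 * (e$sigma^2 - 1) / Bn
    egrads <- encoder_backward(e, dmu = dmu, dlogv = dlogv,
                               dZ_side = dZ_side, params = model$enc,
                               config = cfg, grads = egrads)
  }
  out$enc_grads <- egrads
  out$dec_grads <- dgrads
  out
}

#' Train (or fine-tune) the scaffold VAE
#'
#' Runs minibatch Adam on the joint reconstruction + beta-annealed KL loss.
#' Both the encoder and the decoder receive gradients.  Fine-tuning is the
#' same loop warm-started from an existing model; its learning rate must be
#' strictly smaller than the rate the checkpoint was trained with.
#'
#' @param pairs data.frame of molecule-scaffold pairs (see
#'   [build_pair_dataset()]).
#' @param cfg a [train_config()].
#' @param model_config an [sh_config()]; ignored when `init` is given.
#' @param init optional `sh_model` to warm-start from (fine-tuning).
#' @param log_file optional CSV path for the per-epoch loss log.
#' @param checkpoint_dir optional directory for cadence checkpoints.
#' @param verbose print per-epoch losses.
#' @return list with `model` and `log` (data.frame epoch, L_recon, L_kl,
#'   beta, total).
#' @export
train_model <- function(pairs, cfg = train_config(),
                        model_config = sh_config(), init = NULL,
                        log_file = NULL, checkpoint_dir = NULL,
                        verbose = FALSE) {
  stopifnot(nrow(pairs) > 0L)
  if (!is.null(init)) {
    model <- init
    if (!is.na(model$lr_trained) && cfg$lr >= model$lr_trained)
      stop("fine-tuning learning rate (", cfg$lr,
           ") must be smaller than the pretraining rate (",
           model$lr_trained, ")")
    # all scaffold tokens must be known to the existing vocabulary
    for (s in unique(pairs$scaffold_smiles)) encode_tokens(model$vocab, s)
  } else {
    vocab <- build_vocabulary(unique(pairs$scaffold_smiles))
    model <- model_init(model_config, vocab, seed = cfg$seed)
  }
  config <- model$config

  compiled <- lapply(seq_len(nrow(pairs)), function(i)
    compile_pair(pairs[i, ], config, model$vocab))

  rng <- make_rng(cfg$seed)
  astate <- list(enc = adam_init(model$enc), dec = adam_init(model$dec))
  log <- data.frame()
  if (cfg$epochs == 0L) return(list(model = model, log = log))

  for (epoch in seq_len(cfg$epochs) - 1L) {
    beta <- beta_schedule(epoch, cfg)
    ord <- rng$shuffle(seq_along(compiled))
    ep_recon <- 0; ep_kl <- 0; nb <- 0L
    for (bstart in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[bstart:min(bstart + cfg$batch_size - 1L, length(ord))]
      batch <- compiled[idx]
      eps_mat <- matrix(rng$rnorm(length(idx) * config$d_z),
                        length(idx), config$d_z)
      st <- batch_step(model, batch, beta, eps_mat)
      up_e <- adam_update(model$enc, st$enc_grads, astate$enc, cfg$lr, cfg$clip_norm)
      model$enc <- up_e$params; astate$enc <- up_e$state
      up_d <- adam_update(model$dec, st$dec_grads, astate$dec, cfg$lr, cfg$clip_norm)
      model$dec <- up_d$params; astate$dec <- up_d$state
      ep_recon <- ep_recon + st$recon; ep_kl <- ep_kl + st$kl; nb <- nb + 1L
    }
    row <- data.frame(epoch = epoch, L_recon = ep_recon / nb,
                      L_kl = ep_kl / nb, beta = beta,
                      total = ep_recon / nb + beta * (ep_kl / nb))
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d: recon %.4f kl %.4f beta %.3f",
                      epoch, row$L_recon, row$L_kl, beta))
    if (!is.null(checkpoint_dir) && cfg$checkpoint_every > 0L &&
        (epoch + 1L) %% cfg$checkpoint_every == 0L) {
      model$lr_trained <- cfg$lr
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("epoch%04d.rds", epoch + 1L)))
    }
  }
  model$lr_trained <- cfg$lr
  if (!is.null(log_file))
    utils::write.csv(log, log_file, row.names = FALSE)
  list(model = model, log = log)
}

#' Greedy scaffold reconstruction rate
#'
#' Encodes each pair with `z = mu` (no sampling) and decodes greedily;
#' returns the fraction of pairs whose decoded string equals the scaffold
#' SMILES exactly.
#'
#' @param model an `sh_model`.
#' @param pairs pair data.frame.
#' @return numeric in `[0, 1]`.
#' @export
greedy_reconstruction_rate <- function(model, pairs) {
  cfg <- model$config
  hits <- 0L
  for (i in seq_len(nrow(pairs))) {
    row <- pairs[i, ]
    cp <- compile_pair(row, cfg, model$vocab)
    e <- encoder_forward(cp$g, cp$mask, model$enc, cfg)
    h0raw <- matrix(c(e$Z_side, e$mu), 1L)
    h0 <- as.vector(bridge_h0(model$dec, h0raw))
    out <- sample_sequence(model$dec, cfg, model$vocab, h0, temperature = 0)
    if (identical(out, row$scaffold_smiles)) hits <- hits + 1L
  }
  hits / nrow(pairs)
}
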