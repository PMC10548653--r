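# Model configuration and parameter containers.

#' Model hyperparameter configuration
#'
#' Defaults: a 128-dim token embedding feeding 3 GRU layers of 512 units,
#' 3 message-passing iterations at width 128 per view, a 4-head attention
#' readout and a 128-dim latent.  Every value can be overridden, and the
#' test-suite configs use smaller widths to stay within CPU budgets.
#'
#' @param h_node,h_edge hidden widths of the node-view and edge-view
#'   message-passing states.
#' @param n_layers number of message-passing iterations L.
#' @param r number of attention heads in the readout.
#' @param d_attn attention projection width.
#' @param d_z latent dimensionality of the scaffold posterior.
#' @param emb_dim decoder token-embedding width.
#' @param gru_hidden units per GRU layer.
#' @param gru_layers number of GRU layers.
#' @param max_len maximum decoded token count.
#' @param sigma_mode `"literal"` resamples the latent with sigma^2 scaling
#'   at generation time (the model's stated resampling rule), `"standard"`
#'   uses sigma.
#' @param atom_types ordered atom-type alphabet; anything else maps to the
#'   reserved `"other"` slot.
#' @return a named list of class `sh_config`.
#' @export
sh_config <- function(h_node = 128L, h_edge = 128L, n_layers = 3L,
                      r = 4L, d_attn = 64L, d_z = 128L,
                      emb_dim = 128L, gru_hidden = 512L, gru_layers = 3L,
                      max_len = 100L, sigma_mode = c("literal", "standard"),
                      atom_types = c("C", "N", "O", "S", "P", "F", "Cl",
                                     "Br", "I", "B", "other")) {
  sigma_mode <- match.arg(sigma_mode)
  cfg <- list(h_node = as.integer(h_node), h_edge = as.integer(h_edge),
              n_layers = as.integer(n_layers), r = as.integer(r),
              d_attn = as.integer(d_attn), d_z = as.integer(d_z),
              emb_dim = as.integer(emb_dim), gru_hidden = as.integer(gru_hidden),
              gru_layers = as.integer(gru_layers), max_len = as.integer(max_len),
              sigma_mode = sigma_mode, atom_types = atom_types)
  cfg$dx <- length(atom_types) + 6L + 7L + 3L   # node feature width
  cfg$de <- 4L + 2L                             # edge feature width
  cfg$d_out <- cfg$h_node + cfg$h_edge
  class(cfg) <- "sh_config"
  cfg
}

# uniform Glorot-style init, seeded through an isolated rng stream
init_mat <- function(rng, nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(rng$runif(nrow * ncol, -s, s), nrow = nrow, ncol = ncol)
}

zeros <- function(nrow, ncol = NULL) {
  if (is.null(ncol)) numeric(nrow) else matrix(0, nrow, ncol)
}
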