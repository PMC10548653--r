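Package: scafhop
Title: Scaffold Hopping with a Multi-View Graph Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("scafhop", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Generative scaffold hopping for small molecules.  Molecules are
    encoded by a multi-view message-passing network over the molecular
    graph, split into scaffold and side-chain embeddings by masked
    self-attention readout, and the scaffold embedding is mapped to a
    Gaussian latent.  New scaffolds are decoded from resampled latents by a
    GRU language model over SMILES tokens and the reference molecule's side
    chains are reattached by enumeration with fingerprint-similarity
    selection.  Includes a self-contained SMILES chemistry core
    (parsing, aromaticity perception, canonicalization, substructure
    matching, Bemis-Murcko scaffold hierarchies, path fingerprints),
    dataset preparation with structural-alert screening, training with
    KL-weight annealing, generation-set metrics, a deterministic synthetic
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
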