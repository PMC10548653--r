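---
title: "Scaffold hopping with a multi-view graph VAE: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold hopping with a multi-view graph VAE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scaffold hopping asks for a new core ring framework that carries a known
molecule's substituents (its side chains) while preserving, ideally, its
biological activity.  `scafhop` implements a generative approach: a
variational autoencoder whose encoder sees the whole molecular graph but
whose latent bottleneck covers only the scaffold part, so that sampling the
latent replaces the scaffold while the side-chain context conditions the
decoder.

## Model

**Encoder.** A molecule is featurized as an undirected graph with per-atom
features (atom-type one-hot, degree, total valence, formal charge,
aromaticity, ring membership) and per-bond features (bond-type one-hot,
conjugation, ring membership).  Two message-passing views run for `L`
iterations:

* *node-central*: `h_v^{l+1} = ReLU(W_node (sum_{u in N(v)} [h_u^l ; e_vu]) + h_v^0)`
  with `h_v^0 = ReLU(W_nin x_v)`;
* *edge-central*, over directed bond states: `h_vw^{l+1} =
  ReLU(W_edge (sum_{u in N(v) \ w} [h_uv^l ; x_u]) + h_vw^0)`, the exclusion
  of the reverse edge being the usual directed-MPNN guard against immediate
  backtracking.  A readin step maps final directed states back to nodes.

The per-node outputs of the two views are concatenated into an
`n x (h_node + h_edge)` matrix.  A binary scaffold mask (atom indices of
the scaffold substructure match) splits the rows into scaffold and
side-chain blocks.  Each block is pooled by shared structured
self-attention, `A = softmax(W2 tanh(W1 H^T))` with `r` heads, and
flattened into fixed-length embeddings `Z_sca` and `Z_side`.  Linear heads
on `Z_sca` give the mean and log-variance of a diagonal Gaussian latent.

Two readings of the attention geometry are possible (which projection
applies first, and whether the second projection is `d_attn x r` or
`r x d_attn`); we implement the standard structured self-attention
(first `W1: d_attn x d_out`, then `W2: r x d_attn`), the only reading
under which the matrices play their intended roles — `W1` projects node
embeddings into the attention space, `W2` scores the importance of nodes
per head.

The latent model can be viewed as a Gaussian *mixture* only in the
aggregate: each molecule contributes one diagonal Gaussian posterior.  The
training loss carries a single KL term against a standard-normal prior; no
explicit mixture prior is fitted.

**Decoder.** Scaffold SMILES are tokenized by the standard regex scheme
(bracket atoms, `Cl`/`Br`, `%NN` closures as single tokens), embedded
(128-dim by default) and decoded by a GRU stack (3 x 512 by default) with
the update-gate convention `h_t = (1 - f_t) h_{t-1} + f_t hhat_t`, a
sign-convention variant of the standard GRU that we keep literally.  The
initial hidden state is a learned linear map of `concat(Z_side, z)`
shared by all layers; a single linear bridge applied to every layer is
the minimal choice that leaves all dimensions free.

**Training.** Loss = mean token cross-entropy over non-PAD positions +
`beta *` KL, with `beta` annealed linearly across epochs (defaults 0 to 1).
PAD positions are masked because unmasked padding dominates short
scaffolds.  The latent uses the standard reparameterization
`z = mu + sigma * eps` during training.  Optimizer settings (Adam,
grad-norm clip 5, batch 64) are free choices exposed in
`train_config()`.  Fine-tuning is the same loop warm-started from a
checkpoint; its learning rate must be strictly below the pretraining rate,
which is enforced.

**Generation.** For a reference molecule the scaffold latent is resampled
as `mu + sigma^2 * eps` — variance-scaled rather than the usual
standard-deviation scaling.  The default follows this rule literally
(wider exploration when `sigma > 1`, tighter when `sigma < 1`);
`sigma_mode = "standard"` in `sh_config()` switches to `sigma` scaling.
Decoded scaffolds are reattached to the reference side
chains by enumerating assignments of fragments to hydrogen-bearing scaffold
atoms, assembling each candidate, and keeping the one with maximal
path-fingerprint Tanimoto similarity to the reference (ties broken by
lexicographic canonical SMILES).  Enumeration is capacity-aware: several
fragments may share an atom while its valence lasts, because strict
one-atom-one-fragment assignment cannot reproduce gem-disubstituted
references.  Unparsable samples and samples with no feasible attachment are
kept in the output flagged invalid.

## Chemistry core

No cheminformatics toolkit exists in the dependency budget, so the package
carries its own: a SMILES parser for the organic subset plus bracket atoms,
simplified Hückel aromaticity perception on 5/6-rings, implicit-hydrogen
resolution from standard valences, canonical SMILES via BLISS canonical
labeling of a colored graph (bond types encoded as subdivision vertices),
VF2 substructure matching with element/charge/aromaticity/bond colors,
Bemis-Murcko frameworks with exocyclic multiple bonds retained, a
peripheral-ring-deletion scaffold hierarchy, and hashed linear-path
fingerprints (paths <= 7 bonds, 2048 bits).  The canonicalization was
validated against an external toolkit during development on a panel of
drug molecules; the test suite asserts idempotence and atom-order
invariance, which are the properties the pipeline relies on.

Known limitations of the core: stereochemistry is parsed but discarded
(canonical forms are achiral); aromaticity perception covers the common
5/6-ring systems, not exotic polycycles, and lowercase aromatic input is
trusted rather than re-derived by a full Hückel analysis, so the validity
metric is slightly more permissive than a strict toolkit (a decoded
`c1cccc[nH]1`, for instance, parses here); the structural-alert screen is
a small built-in list of SMILES-expressible patterns (nitro, azo,
peroxide, acyl halide, long aliphatic chain, ...), not a full MCF/PAINS
set — users supply their own patterns for production curation.

Side-chain surgery requires each fragment to touch the scaffold at exactly
one atom.  When a *sub*-scaffold of a fused ring system is chosen as the
reference scaffold, the remainder of the ring system is attached at two
atoms; `mol_decompose()` refuses such references with an error rather than
invent a two-point reattachment.  These pairs remain perfectly usable for
training — only `hop()` on such a reference is rejected.

## Data preparation

Raw SMILES are standardized: largest fragment kept (ties broken by
canonical SMILES), protonation charges neutralized where a hydrogen shift
suffices, molecules with elements outside the organic subset rejected,
molecular-weight and heavy-atom windows applied (defaults 200-600 Da and
10-50 heavy atoms, both config keys in `prep_limits()` since reasonable
curation windows are corpus-dependent), and the alert screen applied.
Scaffolds from the hierarchy are filtered by three rules: at least one
ring that is not a bare benzene ring (interpreted per ring, so a scaffold
whose only rings are benzenes fails — benzene is too ubiquitous to define
a scaffold class), at most 20 heavy atoms, at most 3 rotatable bonds
(non-ring single bond between non-terminal heavy atoms, amide C–N
excluded — the common medicinal-chemistry convention, stated explicitly
because several exist).  Pretraining keeps one random passing
scaffold per molecule; fine-tuning keeps all of them.

## Synthetic fixtures

`generate_corpus()` emits molecules built as one core ring system from a
~35-entry library (drug-like heterocycles plus deliberate filter failers)
with 0-3 substituents from a 15-entry side-chain library attached at random
hydrogen-bearing core sites (count weights 0.1/0.35/0.35/0.2).  This
realizes exactly the "molecule = scaffold + side chains" structure the
pipeline assumes and gives every molecule a known ground-truth scaffold.
It does **not** emulate ChEMBL property distributions, ring-system
diversity, or realistic side-chain complexity, so green pipeline tests
establish mechanical correctness (decomposition, reattachment, training
convergence, metric arithmetic) — not chemical performance at library
scale.

## Numerical choices

* Gradients for both networks are hand-written and verified against central
  finite differences in the test suite (tolerance 1e-4 on sampled
  coordinates).
* Softmax computations subtract the row maximum; temperature-0 sampling is
  exact argmax.
* KL uses the closed form `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`,
  cross-checked against a 1e5-sample Monte-Carlo estimate.
* All randomness flows through isolated seeded Mersenne-Twister streams
  (`make_rng()`), so training logs are bitwise reproducible for a fixed
  seed on one CPU and library code never disturbs the caller's RNG.
* Test and acceptance configurations use reduced widths (e.g. 16-32 hidden
  units, GRU 48-128) purely to stay within CPU budgets; the package
  defaults (`sh_config()`) are full-scale.

## What the acceptance tests establish

The nine acceptance criteria are property-based: closed-form vs
Monte-Carlo KL agreement; exact equivalence of the vectorized message
passing with a naive nested-loop oracle on all connected graphs of up to 5
nodes; permutation invariance of the embeddings; an exactly hand-labeled
30-scaffold filter truth table; a >= 99% decompose/reattach round trip over
1000 fixture molecules; memorization capacity (>= 90% greedy reconstruction
of 32 pairs, majority of 3 seeds); exact agreement of the seven generation
metrics with an independent set-arithmetic implementation; the
success-rate <= min(active, hop) bound plus a hand-computed report; and an
end-to-end fixtures-to-metrics smoke run producing valid, hopped
molecules.  Published headline numbers (validity approx. 0.90 at 100k-scale
sampling, hop rates of 1.0 under external docking scorers) require the
full pretraining corpus and external scoring engines and are deliberately
out of scope.
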