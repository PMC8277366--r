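# Small in-code fixtures shared across test files.

tiny_basic <- function() {
  tibble::tibble(
    head = c("etanercept", "aspirin", "warfarin", "p1"),
    relation = c("hasTarget", "hasTarget", "hasEnzyme", "isPresentIn"),
    tail = c("lymphotoxin-alpha", "p1", "p1", "pw1")
  )
}

tiny_vocab <- function() {
  label_vocabulary(c("bleeding", "enhance", "toxicity", "anemia"))
}

tiny_ddi <- function() {
  tibble::tibble(
    drug_u = c("aspirin", "warfarin"),
    drug_v = c("warfarin", "etanercept"),
    labels = list(c("bleeding", "enhance"), c("toxicity"))
  )
}

tiny_kg <- function() {
  build_kg(tiny_basic(), tiny_ddi(), tiny_vocab())
}

# a small but trainable synthetic configuration (full drug eligibility so
# negative-pair pools stay comfortable)
small_synth_config <- function(seed = 5, ...) {
  synth_config(n_drugs = 24, n_proteins = 12, n_pathways = 3,
               n_phenotypes = 2, n_basic = 60, n_ddi_pairs = 20,
               vocab_size = 12, n_clusters = 3, labels_per_ddi = 3,
               latent_dim = 8, ddi_drug_fraction = 1, seed = seed, ...)
}

small_hparams <- function(iterations = 30, seed = 2, gamma = 0.05,
                          lr = 0.001, ...) {
  prd_hparams(k = 8, d = 6, c_neg = 3, gamma = gamma, beta = 3, lr = lr,
              iterations = iterations, batch_size = 32, seed = seed, ...)
}

# jitter parameters away from initialization kinks (unit-norm rows sit
# exactly on the soft-constraint hinge)
jitter_params <- function(params, sd = 0.05, seed = 99) {
  flat <- prddi:::params_flatten(params)
  set.seed(seed)
  prddi:::params_unflatten(flat + stats::rnorm(length(flat), 0, sd), params)
}
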