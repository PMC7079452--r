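# Shared desk-scale fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_transformer_config <- function(...) {
  transformer_config(n_layers = 1L, n_heads = 2L, d_model = 16L, d_ff = 32L,
                     dropout = 0, max_len = 40L, label_smoothing = 0, ...)
}

tiny_encoder <- function() {
  cached("tiny_encoder", function()
    build_canonicalizer(tiny_transformer_config(), seed = 101L))
}

small_library <- function() {
  cached("small_library", function()
    generate_toy_library(toy_library_spec(n_molecules = 60L, seed = 7L)))
}

# A small trained regression QSAR model over the halogen-count rule; used by
# prediction, consensus and relevance tests.
tiny_qsar <- function() {
  cached("tiny_qsar", function() {
    lib <- generate_toy_library(toy_library_spec(n_molecules = 40L, seed = 5L))
    ds <- make_planted_dataset(lib, planted_property(), seed = 5L)
    cfg <- cnn_head_config(kernel_sizes = 1:3, filter_counts = rep(8L, 3),
                           dense_width = 16L, learning_rate = 1e-3,
                           max_epochs = 8L, patience = 8L, seed = 6L)
    train_qsar(ds$records, tiny_encoder(), cfg,
               augmentation_policy(n_augment = 2L, seed = 6L),
               grammar_oracle())
  })
}

# Drug-like SMILES (rings, stereo, brackets) used for tokenizer and
# char-atom-map coverage beyond the acyclic toy grammar.
drug_smiles <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                       # aspirin
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",                # caffeine
  "C[C@H](N)C(=O)O",                             # L-alanine
  "O=[N+]([O-])c1ccc(Br)cc1",                    # 1-bromo-4-nitrobenzene
  "C(/F)=C\\Cl",                                 # cis/trans example
  "OC(=O)c1ccccc1O"                              # salicylic acid
)
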