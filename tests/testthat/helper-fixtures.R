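# Shared fixtures: tiny cohorts and models sized for fast, exact checks.

tiny_cohort <- function(seed = 1L, ...) {
  generate_unpaired_cohort(synth_config(
    n_rna_samples = 60L, n_meth_samples = 40L, n_genes = 60L,
    n_informative_rna = 8L, n_informative_meth = 8L,
    effect_size = 1.5, missing_rate = 0, seed = seed, ...))
}

tiny_arch <- function(p_rna = 60L, p_meth = 60L, ...) {
  arch_config(input_dim_rna = p_rna, input_dim_meth = p_meth,
              ae_hidden_dim = 16L, n_tokens = 2L, d_model = 4L,
              n_heads = 2L, n_encoder_layers = 2L, ffn_hidden_dim = 8L,
              mlp_hidden_dims = 8L, ...)
}

tiny_model <- function(seed = 1L, ...) init_model(tiny_arch(...), seed = seed)

# Brute-force Mann-Whitney concordance with ties counted one half:
# the independent oracle for the trapezoidal AUC.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
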