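# Published worked-example table: five groups of oppositely charged
# pentapeptide pairs with their component, concatenated-decapeptide and
# mixed-system AP values and normalized hydrophilicities.
table1 <- data.frame(
  pen1 = c("NRMMR", "DMTAL", "RLNCK", "LRLRL", "IVNRR"),
  pen2 = c("DMGID", "IAGAK", "ADMGE", "IQDEC", "EEEQS"),
  ap_pen1 = c(1.150, 1.155, 1.167, 1.480, 1.174),
  ap_pen2 = c(1.144, 1.031, 1.125, 1.103, 1.035),
  ap_avepen = c(1.147, 1.093, 1.146, 1.292, 1.105),
  logp_pen1 = c(0.474, 0.451, 0.511, 0.360, 0.466),
  logp_pen2 = c(0.597, 0.498, 0.653, 0.606, 0.788),
  ap_deca = c(1.659, 1.542, 1.591, 1.731, 1.531),
  ap_mixpen = c(1.612, 1.366, 1.606, 1.735, 1.490),
  stringsAsFactors = FALSE)

# tiny architecture for fast unit tests (same topology as the presets)
tiny_config <- function(model_length = 3L, dropout = 0) {
  trn_config("scaled", model_length = model_length, dropout = dropout,
             embed_dim = 8L, n_blocks = 2L, n_heads = 2L, head_dim = 4L,
             ffn_dim = 16L, mlp_dims = c(8L, 4L, 1L))
}

# noiseless additive surrogate (no pairwise or charge terms)
additive_params <- function() {
  surrogate_params(pair_bonus = 0, charge_penalty = 0, mix_boost = 0,
                   noise_sd = 0)
}
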