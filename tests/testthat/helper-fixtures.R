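# small networks and parameter sets shared across tests

# one translatable unit with maturation, all rates numeric (no lookup)
one_unit_network <- function(kf_tx = 0.01, kr_tx = 0.1, kf_rbs = 0.01,
                             kr_rbs = 1, kf_nuc = 0.01, kr_nuc = 0.5,
                             k_deg = 0.02, k_mat = 0.002,
                             transcript_length = 900, protein_length = 300,
                             resources = resource_spec(),
                             toxin = toxin_config("TL_TL", b = 0.1,
                                                  k_toxin = 0.001,
                                                  toxin_threshold = 50)) {
  pr <- promoter_spec("T7_strong", "T7", kf_tx = kf_tx, kr_tx = kr_tx)
  u <- transcription_unit("gene", pr, transcript_length,
                          translatable = TRUE, protein_length = protein_length,
                          kf_rbs = kf_rbs, kr_rbs = kr_rbs,
                          kf_nuc = kf_nuc, kr_nuc = kr_nuc, k_deg = k_deg,
                          k_mat = k_mat, readout = "mature_protein")
  build_network(list(u), resources, toxin)
}

# globals-only parameter set for networks whose unit rates are numeric
global_params <- function(k_tx_elong = 50, k_tl_elong = 4,
                          K_NTP = 1e5, K_AA = 1e5) {
  c(k_tx_elong = k_tx_elong, k_tl_elong = k_tl_elong,
    K_NTP = K_NTP, K_AA = K_AA)
}

fixture_params <- function() default_parameters()

# a parameter set with the toxin mechanism silenced
no_toxin_params <- function() {
  p <- default_parameters()
  p["k_toxin"] <- 0
  p["b"] <- 0
  p
}
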