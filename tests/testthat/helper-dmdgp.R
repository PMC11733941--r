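# Shared fixtures, built in code. Jittered geometry frees the nominally
# planar peptide positions, mirroring experimental non-planarity.

planted_instance <- function(n, seed, policy = default_policy(),
                             jitter = 0, sampler = NULL) {
  params <- geometry_params(omega_jitter = jitter)
  conf <- sample_conformation(n, params, sampler, seed = seed)
  list(conf = conf, instance = build_instance(conf, policy))
}

# a law over HA-10-H windows of a 3-residue order; position 10 (repeated CA)
# carries a fixed 0, so planted sequences keep a 0 there
ha10_law <- function() {
  list(sequences = c("0101100", "0011001", "0000101"),
       probs = c(0.7, 0.2, 0.1))
}

law_instance <- function(seed, law = ha10_law(), jitter = 5) {
  ord <- build_order(3)
  s <- bit_sampler_seq_law(ord, "HA-10-H", law$sequences, law$probs)
  conf <- sample_conformation(3, geometry_params(omega_jitter = jitter),
                              s, seed = seed)
  build_instance(conf, policy = "HA-10-H")
}

# global bit string carrying a given HA-10-H window sequence (3-residue order)
global_with_window <- function(seq_chr) {
  bits <- integer(15)
  bits[5:11] <- as.integer(strsplit(seq_chr, "")[[1L]])
  dmdgp:::new_bits(bits, 1L, repeated = seq_len(15) == 10L)
}

expect_point_equal <- function(p, q, tol = 1e-9) {
  expect_lt(max(abs(p - q)), tol)
}
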