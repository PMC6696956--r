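# Attachment-site sequences of the two V. natriegens prophages, used as
# fixed fixtures throughout the suite.
VNP1_CORE <- "TAGATTTGTGTGGT"
VNP2_ATTL <- "CAGCCCACTTTTTTCTTCTTTGATTA"
VNP2_ATTR <- "CAGCCGACATTCTTCTTCTTTGACTA"
VNP2_ATTP <- "CAGCCGACATTCTTCTTCTTTGATTA"

# Small two-prophage truth used where a full 200-kb chromosome would be
# needless; keeps the default induction/burst asymmetry (10x vs 70x).
small_truth <- function(seed = 1L, ...) {
  generate_host_genome(
    length = 60000,
    regions_spec = prophage_spec(
      name = c("VNP1", "VNP2"), start = c(12000, 35000),
      length = c(9000, 11000),
      att_core = c(VNP1_CORE, VNP2_ATTL),
      induced_fraction = c(0.1, 0.1), burst_size = c(100, 700)),
    seed = seed, ...)
}
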