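# Seeded random test instances: small networks with mixed antagonism
# and synergy, sized from the seed so the family spans 4-10 viruses and
# 3-8 hosts.

random_instance <- function(seed) {
  nv <- 4L + (seed %% 7L)   # 4..10 viruses
  nh <- 3L + (seed %% 6L)   # 3..8 hosts
  qpbin <- randomQPBIN(nv, nh, targetFill = 0.35, seed = seed)
  qppin <- randomQPPIN(virusNames(qpbin), pAntagonism = 0.2, pSynergy = 0.1,
                       seed = seed + 10000L)
  list(qpbin = qpbin, qppin = qppin)
}

# Modular instance: each phage owns a disjoint two-host block, with
# distinct virulences so orderings are unambiguous.
modular_instance <- function() {
  nv <- 4L
  v <- matrix(0, nv, 2L * nv)
  for (i in seq_len(nv)) {
    v[i, 2L * i - 1L] <- 0.4 + 0.1 * i
    v[i, 2L * i] <- 0.3 + 0.1 * i
  }
  QPBIN(v, virusNames = paste0("p", seq_len(nv)),
        hostNames = paste0("h", seq_len(2L * nv)))
}
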