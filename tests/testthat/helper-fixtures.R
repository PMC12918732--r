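## Shared fixtures, all built in code at test time.

## A random normalised profile HMM with Dirichlet-ish rows; used for the
## brute-force-vs-DP oracle sweeps.
rand_tiny_hmm <- function(M) {
  rdir <- function(n, k) { x <- matrix(rgamma(n * k, 1), n, k); x / rowSums(x) }
  profile_hmm(name = "rand", M = M, match = rdir(M, 20), insert = rdir(M, 20),
              trans = cbind(rdir(M, 3), rdir(M, 2), rdir(M, 2)),
              trans0 = c(rdir(1, 3), rdir(1, 2), rdir(1, 2)),
              background = as.numeric(rdir(1, 20)))
}

rand_aa <- function(L) paste(sample(amino_alphabet(), L, TRUE), collapse = "")

## Fabricate a hit table row without running a search.
mk_hit <- function(genome = "G1", protein = "p1", hmm = "m1",
                   bits = 50, e = 1e-10) {
  data.frame(genome_id = genome, protein_id = protein, hmm_name = hmm,
             bit_score = bits, e_value = e, engine = "internal",
             stringsAsFactors = FALSE)
}

## Hits covering `k` distinct member HMMs of a module definition.
hits_for_subunits <- function(def, k, genome = "G1") {
  do.call(rbind, lapply(seq_len(k), function(i)
    mk_hit(genome, sprintf("%s_p%d", genome, i), def$members[i])))
}

## All 64 boolean rule inputs over the six raw flags
## (ack_pta, acs, rnf, ech, fpo_prime, fpoF) plus the derived Fpo flags.
all_boolean_profiles <- function() {
  grid <- expand.grid(ack_pta = c(FALSE, TRUE), acs = c(FALSE, TRUE),
                      rnf = c(FALSE, TRUE), ech = c(FALSE, TRUE),
                      fpo_prime = c(FALSE, TRUE), fpoF = c(FALSE, TRUE))
  grid$fpo_full <- grid$fpo_prime & grid$fpoF
  grid$fpo_prime_only <- grid$fpo_prime & !grid$fpoF
  grid
}

## Frozen copy of the module genes each planting pattern carries; the
## ground truth tests score the generator and pipeline against.
category_patterns_test <- function() {
  rnf <- c("rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG")
  ech <- c("echA", "echB", "echC", "echD", "echE", "echF")
  fpo <- c("fpoA", "fpoB", "fpoC", "fpoD", "fpoH", "fpoI", "fpoJ")
  list("I" = c("acs", fpo),
       "II-rnf" = c("ack", "pta", rnf, fpo, "fpoF"),
       "II-ech" = c("ack", "pta", ech),
       "III" = c("acs", rnf, fpo, "fpoF"),
       "IV" = c("ack", "pta", fpo),
       "unclassified" = character(0))
}

## A small conforming community (observed patterns only, no category IV).
conforming_spec <- function(divergence = 0, seed = 1701)
  community_spec(n_per_category = c("I" = 3, "II-rnf" = 3, "II-ech" = 2,
                                    "III" = 2, "unclassified" = 2),
                 decoys_per_genome = 10, divergence = divergence, seed = seed)
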