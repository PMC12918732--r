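## Proteome-vs-model search and the survey's hit-filtering rules.

two_hmms <- function() list(make_hmm("ACDEFGHIKLMN", seed = 1, name = "m1"),
                            make_hmm("MNPQRSTVWYAC", seed = 2, name = "m2"))

toy_proteomes <- function() {
  set.seed(77)
  data.frame(genome_id = rep(c("G1", "G2"), each = 3),
             protein_id = paste0("p", 1:6),
             seq = replicate(6, rand_aa(30)), stringsAsFactors = FALSE)
}

test_that("internal search scores every (protein, model) pair deterministically", {
  prot <- toy_proteomes(); hmms <- two_hmms()
  h1 <- run_search(prot, hmms)
  expect_equal(nrow(h1), 12L)  # 2 genomes x 3 proteins x 2 models
  expect_true(all(h1$engine == "internal"))
  expect_true(all(is.finite(h1$bit_score)))
  expect_true(all(h1$e_value >= 0))
  h2 <- run_search(prot, hmms)
  expect_identical(h1, h2)
})

test_that("a planted consensus protein is its model's top hit in its genome", {
  hmms <- two_hmms()
  prot <- toy_proteomes()
  prot$seq[2] <- hmm_consensus(hmms[[1]])
  hits <- run_search(prot, hmms)
  g1m1 <- hits[hits$genome_id == "G1" & hits$hmm_name == "m1", ]
  expect_equal(g1m1$protein_id[which.max(g1m1$bit_score)], "p2")
})

test_that("models without Gumbel calibration warn and fall back to score-only", {
  hmm <- two_hmms()[[1]]
  hmm$stats <- NULL
  prot <- toy_proteomes()[1:2, ]
  expect_warning(hits <- run_search(prot, list(hmm)), "Gumbel")
  expect_true(all(is.infinite(hits$e_value)))
})

test_that("filtering applies the E-value ceiling and NC bit cutoff jointly", {
  hmm <- make_hmm("ACDEFGHIK", seed = 3, name = "mod")
  nc <- hmm$cutoffs$NC[1]
  hits <- rbind(
    mk_hit("G1", "keep",      "mod", bits = nc + 5, e = 5e-4),
    mk_hit("G1", "at_nc",     "mod", bits = nc,     e = 5e-4),
    mk_hit("G1", "bad_e",     "mod", bits = nc + 50, e = 1e-2),
    mk_hit("G1", "below_nc",  "mod", bits = nc - 1, e = 1e-6),
    mk_hit("G1", "at_ceiling", "mod", bits = nc + 50, e = 1e-3))
  out <- filter_hits(hits, list(hmm))
  expect_setequal(out$protein_id, c("keep", "at_nc"))  # >= NC kept, E < 1e-3 strict
  expect_true(all(out$passed))
  ## idempotence and subset
  expect_equal(filter_hits(out, list(hmm))[names(out)], out)
  ## non-strict ceiling keeps the boundary hit
  out2 <- filter_hits(hits, list(hmm), search_config(evalue_strict = FALSE))
  expect_true("at_ceiling" %in% out2$protein_id)
  ## unknown model name is an error
  expect_error(filter_hits(mk_hit(hmm = "nope"), list(hmm)), "unknown model")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(88)
  hmm <- make_hmm("ACDEFGHIKLMN", seed = 4, name = "mod")
  hits <- do.call(rbind, lapply(1:50, function(i)
    mk_hit("G1", paste0("p", i), "mod",
           bits = runif(1, hmm$cutoffs$NC[1] - 20, hmm$cutoffs$NC[1] + 20),
           e = 10^runif(1, -8, 0))))
  strict <- filter_hits(hits, list(hmm), search_config(evalue_max = 1e-3, cutoff_key = "NC"))
  looser_e <- filter_hits(hits, list(hmm), search_config(evalue_max = 1e-1, cutoff_key = "NC"))
  no_cut <- filter_hits(hits, list(hmm), search_config(evalue_max = 1e-3, cutoff_key = "none"))
  expect_true(all(strict$protein_id %in% looser_e$protein_id))
  expect_true(all(strict$protein_id %in% no_cut$protein_id))
})

test_that("a missing cutoff key walks the NC -> GA -> TC -> none chain with a warning", {
  hmm <- make_hmm("ACDEFGHIK", seed = 6, name = "mod")
  tc <- hmm$cutoffs$TC[1]
  hmm$cutoffs$NC <- NULL; hmm$cutoffs$GA <- NULL
  hits <- rbind(mk_hit("G1", "hi", "mod", bits = tc + 1),
                mk_hit("G1", "lo", "mod", bits = tc - 1))
  expect_warning(out <- filter_hits(hits, list(hmm)), "falling back to TC")
  expect_equal(out$protein_id, "hi")
  hmm$cutoffs <- NULL
  expect_warning(out2 <- filter_hits(hits, list(hmm)), "E-value-only")
  expect_setequal(out2$protein_id, c("hi", "lo"))
})

test_that("best-hit selection deduplicates and resolves ties deterministically", {
  dup <- rbind(mk_hit("G1", "p1", "m1", bits = 10, e = 1e-5),
               mk_hit("G1", "p1", "m1", bits = 12, e = 1e-6),
               mk_hit("G1", "p1", "m1", bits = 12, e = 1e-6))
  out <- best_hit_per_protein(dup)
  expect_equal(nrow(out), 1L)
  expect_equal(out$bit_score, 12)
  expect_lte(nrow(best_hit_per_protein(dup)), nrow(dup))
  ## different proteins are different records and both survive
  two <- rbind(mk_hit("G1", "pB", "m1", bits = 10), mk_hit("G1", "pA", "m1", bits = 10))
  outt <- best_hit_per_protein(two)
  expect_equal(outt$protein_id, c("pA", "pB"))  # sorted, lexicographic ties
})

test_that("NC thresholds retain sampled positives and reject shuffled decoys", {
  comm <- make_community(conforming_spec(divergence = 0.05, seed = 424))
  hits <- filter_hits(run_search(comm$proteomes, comm$hmms), comm$hmms)
  truth <- comm$truth$genomes
  planted <- unlist(lapply(names(truth), function(g) {
    p <- unlist(truth[[g]]$planted_proteins)
    if (length(p)) paste(g, p, sep = "\r") else character(0)
  }))
  retained <- paste(hits$genome_id, hits$protein_id, sep = "\r")
  ## every planted gene recovered by its own model at default divergence
  expect_gte(mean(planted %in% retained), 0.99)
  ## no decoy protein passes any model's NC threshold
  expect_false(any(grepl("decoy", hits$protein_id)))
})

test_that("the hmmsearch engine agrees with the internal engine on planted genes", {
  comm <- make_community(community_spec(
    n_per_category = c("I" = 1, "II-rnf" = 1), decoys_per_genome = 3,
    divergence = 0, seed = 99))
  internal <- filter_hits(run_search(comm$proteomes, comm$hmms), comm$hmms)
  external <- run_search(comm$proteomes, comm$hmms,
                         search_config(engine = "hmmsearch"))
  expect_true(all(external$engine == "hmmsearch"))
  ## every planted (genome, model) pair found internally has its top
  ## external hit on the same protein
  for (g in names(comm$truth$genomes)) {
    for (m in comm$truth$genomes[[g]]$planted_hmms) {
      ext <- external[external$genome_id == g & external$hmm_name == m, ]
      expect_gt(nrow(ext), 0)
      expect_equal(ext$protein_id[which.max(ext$bit_score)],
                   comm$truth$genomes[[g]]$planted_proteins[[m]])
    }
  }
})
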