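## Seeded generators for every fixture the pipeline needs: peaked profile
## HMMs with constructed NC/GA/TC cutoffs, proteomes with module genes
## planted per a chosen category composition, taxonomy tables and trees
## consistent with genus groupings, and OD600 growth curves with lag,
## exponential and stationary phases. Ground truth is recorded alongside so
## any pipeline stage can be scored without re-reading fixture internals.

rand_consensus <- function(length) paste(sample(AMINO, length, TRUE), collapse = "")

mutate_seq <- function(seq, divergence) {
  if (divergence == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  chars[hit] <- vapply(chars[hit],
                       function(a) sample(setdiff(AMINO, a), 1), character(1))
  paste(chars, collapse = "")
}

shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

sample_from_hmm <- function(hmm) {
  paste(AMINO[apply(hmm$match, 1, function(p) sample.int(20, 1, prob = p))],
        collapse = "")
}

make_hmm_core <- function(consensus, peak, n_cal, n_gumbel, calibrate = TRUE) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  M <- length(chars)
  if (M == 0) stop("consensus must be non-empty")
  ci <- match(chars, AMINO)
  if (anyNA(ci)) stop("consensus contains letters outside the amino alphabet")
  match_em <- matrix((1 - peak) / 19, M, 20)
  match_em[cbind(seq_len(M), ci)] <- peak
  insert_em <- matrix(1 / 20, M, 20)
  trans <- matrix(rep(c(0.95, 0.02, 0.03, 0.90, 0.10, 0.90, 0.10), each = M),
                  M, 7)
  trans[M, ] <- c(0.98, 0.02, 0, 0.90, 0.10, 1, 0)  # no delete past last node
  hmm <- profile_hmm(name = "synthetic", M = M, match = match_em,
                     insert = insert_em, trans = trans,
                     trans0 = c(0.95, 0.02, 0.03, 0.90, 0.10, 1, 0),
                     background = rep(1 / 20, 20))
  if (!calibrate) return(hmm)
  # seeded score distributions: positives sampled from the match emissions,
  # decoys are residue shuffles of the positives (composition-preserving)
  pos_seqs <- replicate(n_cal, sample_from_hmm(hmm))
  dec_seqs <- vapply(pos_seqs, shuffle_seq, character(1), USE.NAMES = FALSE)
  pos <- vapply(pos_seqs, function(s) viterbi_bitscore(hmm, s)$bit_score,
                numeric(1), USE.NAMES = FALSE)
  dec <- vapply(dec_seqs, function(s) viterbi_bitscore(hmm, s)$bit_score,
                numeric(1), USE.NAMES = FALSE)
  if (min(pos) <= max(dec))
    warning("positive and decoy score distributions overlap (model too short or peak too flat); the NC cutoff will not separate them cleanly")
  nc <- (min(pos) + max(dec)) / 2
  hmm$cutoffs <- list(GA = c(nc, nc), TC = c(min(pos), min(pos)),
                      NC = c(nc, nc))
  # Gumbel calibration by moment matching on a larger decoy sample
  gum <- vapply(replicate(n_gumbel, shuffle_seq(consensus)),
                function(s) viterbi_bitscore(hmm, s)$bit_score,
                numeric(1), USE.NAMES = FALSE)
  lambda <- pi / (sd(gum) * sqrt(6))
  mu <- mean(gum) - 0.5772156649015329 / lambda
  hmm$stats <- list(msv = c(mu, lambda), viterbi = c(mu, lambda),
                    forward = c(mu, log(2)))
  attr(hmm, "calibration") <- list(positives = pos, decoys = dec,
                                   gumbel_decoys = gum)
  hmm
}

#' Build a peaked synthetic profile HMM around a consensus
#'
#' Match emissions put probability `peak` on the consensus letter at each
#' node with the remainder spread uniformly; inserts and background are
#' uniform. Bit-score cutoffs are constructed from seeded score
#' distributions so the threshold logic is sharp by design: positives are
#' sequences sampled from the match emissions, decoys their residue
#' shuffles, NC (and GA) the midpoint between the lowest positive and the
#' highest decoy score, TC the lowest positive score. Gumbel parameters are
#' moment-matched to a larger decoy sample. The score samples used are kept
#' in the `"calibration"` attribute.
#'
#' @param consensus consensus protein string.
#' @param peak match-emission probability of the consensus letter,
#'   in `(1/20, 1]`.
#' @param seed integer seed; `NULL` continues the caller's RNG stream.
#' @param name model name.
#' @param n_cal positives/decoys drawn for cutoff construction.
#' @param n_gumbel decoys drawn for Gumbel moment matching.
#' @param calibrate construct cutoffs and Gumbel parameters; `FALSE` returns
#'   the bare (uncalibrated) model.
#' @return a calibrated [profile_hmm].
#' @export
make_hmm <- function(consensus, peak = 0.9, seed = NULL, name = "synthetic",
                     n_cal = 50, n_gumbel = 200, calibrate = TRUE) {
  if (peak <= 1 / 20 || peak > 1) stop("peak must be in (1/20, 1]")
  hmm <- if (is.null(seed))
           make_hmm_core(consensus, peak, n_cal, n_gumbel, calibrate)
         else with_seed(seed,
           make_hmm_core(consensus, peak, n_cal, n_gumbel, calibrate))
  hmm$name <- name
  hmm
}

## Module genes each category pattern plants (names match default_module_set)
category_patterns <- function() {
  rnf <- c("rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG")
  ech <- c("echA", "echB", "echC", "echD", "echE", "echF")
  fpo <- c("fpoA", "fpoB", "fpoC", "fpoD", "fpoH", "fpoI", "fpoJ")
  list(
    "I"            = c("acs", fpo),
    "II-rnf"       = c("ack", "pta", rnf, fpo, "fpoF"),
    "II-ech"       = c("ack", "pta", ech),
    "III"          = c("acs", rnf, fpo, "fpoF"),
    "IV"           = c("ack", "pta", fpo),
    "unclassified" = character(0))
}

## expected category call for each planted pattern
pattern_truth <- c("I" = "I", "II-rnf" = "II", "II-ech" = "II",
                   "III" = "III", "IV" = "IV",
                   "unclassified" = "unclassified")

pattern_genus <- c("I" = "Methanothrix", "II-rnf" = "Methanosarcina",
                   "II-ech" = "Methanosarcina", "III" = "Methanomethylovorans",
                   "IV" = "Methanoquartus", "unclassified" = "Methanolobus")

#' Specify a synthetic genome community
#'
#' @param n_per_category genomes to plant per co-occurrence pattern; named
#'   over `I`, `II-rnf`, `II-ech`, `III`, `IV`, `unclassified`.
#' @param decoys_per_genome shuffled decoy proteins added to every genome.
#' @param divergence per-residue substitution probability applied to planted
#'   genes, in `[0, 0.5)`.
#' @param gene_length planted gene length in residues.
#' @param peak match-emission peak of the synthetic HMMs.
#' @param seed integer seed driving every random choice.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_per_category = c("I" = 2, "II-rnf" = 2,
                                              "II-ech" = 2, "III" = 2,
                                              "IV" = 2, "unclassified" = 2),
                           decoys_per_genome = 10, divergence = 0.05,
                           gene_length = 120, peak = 0.9, seed = 1701) {
  stopifnot(all(names(n_per_category) %in% names(category_patterns())),
            all(n_per_category >= 0), decoys_per_genome >= 0,
            divergence >= 0, divergence < 0.5, gene_length >= 1)
  if (sum(n_per_category) == 0) stop("community must contain at least one genome")
  structure(list(n_per_category = n_per_category,
                 decoys_per_genome = decoys_per_genome,
                 divergence = divergence, gene_length = gene_length,
                 peak = peak, seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate a synthetic genome community with known ground truth
#'
#' For every genome, plants divergence-mutated copies of the module genes
#' its category pattern requires (category I: Acs plus the seven Fpo'
#' subunits and no FpoF; II-rnf: Ack, Pta, the six Rnf subunits and a full
#' Fpo; II-ech: Ack, Pta and the six Ech subunits; III: Acs, Rnf and full
#' Fpo; IV: Ack, Pta and Fpo' only; unclassified: decoys only), plus
#' composition-preserving shuffled decoys. Genus labels group the category
#' patterns; the tree is a random seeded topology over the genomes. The
#' returned `truth` records every planted gene and the expected category of
#' each genome. Pure function of the spec (same seed, same community).
#'
#' @param spec a [community_spec()].
#' @return list with `proteomes` (data frame), `hmms` (named list of
#'   calibrated [profile_hmm]s), `taxonomy`, `tree`, `truth`, `spec`.
#' @export
make_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    patterns <- category_patterns()
    hmm_names <- unique(unlist(patterns))
    consensi <- setNames(vapply(hmm_names, function(nm)
      rand_consensus(spec$gene_length), character(1)), hmm_names)
    hmms <- lapply(hmm_names, function(nm)
      make_hmm(consensi[[nm]], peak = spec$peak, name = nm))
    names(hmms) <- hmm_names

    counts <- spec$n_per_category[spec$n_per_category > 0]
    cats <- rep(names(counts), counts)
    genome_ids <- sprintf("SYN_G%03d", seq_along(cats))
    proteome_rows <- list(); truth_genomes <- list()
    for (g in seq_along(cats)) {
      cat_g <- cats[g]
      planted <- patterns[[cat_g]]
      genes <- vapply(planted, function(nm)
        mutate_seq(consensi[[nm]], spec$divergence), character(1))
      pids <- if (length(planted)) paste0(genome_ids[g], "_", planted)
              else character(0)
      # decoys: residue shuffles of planted genes (or of random module
      # consensi for gene-free genomes) — composition-preserving nulls
      pool <- if (length(genes)) genes else consensi
      decoys <- if (spec$decoys_per_genome > 0)
        vapply(seq_len(spec$decoys_per_genome), function(d)
          shuffle_seq(pool[[sample.int(length(pool), 1)]]), character(1))
        else character(0)
      did <- if (length(decoys))
        sprintf("%s_decoy%03d", genome_ids[g], seq_along(decoys))
        else character(0)
      proteome_rows[[g]] <- data.frame(
        genome_id = genome_ids[g],
        protein_id = c(pids, did),
        seq = c(unname(genes), decoys), stringsAsFactors = FALSE)
      truth_genomes[[genome_ids[g]]] <- list(
        pattern = cat_g, category = unname(pattern_truth[cat_g]),
        planted_hmms = planted,
        planted_proteins = as.list(setNames(pids, planted)),
        genus = unname(pattern_genus[cat_g]))
    }
    proteomes <- do.call(rbind, proteome_rows)
    rownames(proteomes) <- NULL

    genus <- vapply(truth_genomes, `[[`, character(1), "genus")
    taxonomy <- data.frame(
      genome_id = genome_ids, domain = "Archaea", phylum = "Halobacteriota",
      class = "Methanosarcinia",
      order = ifelse(genus == "Methanothrix", "Methanotrichales",
                     "Methanosarcinales"),
      family = paste0(genus, "ceae"), genus = genus,
      species = paste0(genus, " sp", seq_along(genome_ids)),
      stringsAsFactors = FALSE)

    tree <- ape::rtree(length(genome_ids),
                       tip.label = sample(genome_ids))

    list(proteomes = proteomes, hmms = hmms, taxonomy = taxonomy,
         tree = tree,
         truth = list(seed = spec$seed, genomes = truth_genomes,
                      hmm_names = hmm_names),
         spec = spec)
  })
}

#' Write a synthetic community to disk
#'
#' Emits `proteomes/<genome>.faa`, `hmms/<model>.hmm`, `taxonomy.tsv`,
#' `tree.nwk` and `truth.json` under `dir`, plus `curves.csv` when a growth
#' table is supplied. Deterministic: the same community object always
#' produces byte-identical files.
#'
#' @param community result of [make_community()].
#' @param dir output directory.
#' @param curves optional tidy growth table (`strain`, `replicate`,
#'   `time_h`, `od600`) to write as `curves.csv`.
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir, curves = NULL) {
  dir.create(file.path(dir, "proteomes"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "hmms"), showWarnings = FALSE, recursive = TRUE)
  for (g in unique(community$proteomes$genome_id))
    write_fasta(community$proteomes[community$proteomes$genome_id == g, ],
                file.path(dir, "proteomes", paste0(g, ".faa")))
  for (nm in names(community$hmms))
    write_hmmer3(community$hmms[[nm]], file.path(dir, "hmms", paste0(nm, ".hmm")))
  tax <- community$taxonomy
  tax_str <- apply(tax[, names(GTDB_RANKS)], 1, function(r)
    paste0(GTDB_RANKS, r, collapse = ";"))
  writeLines(paste(tax$genome_id, tax_str, sep = "\t"),
             file.path(dir, "taxonomy.tsv"))
  write_newick(community$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(community$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(curves))
    write.table(curves, file.path(dir, "curves.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate an OD600 growth curve
#'
#' The mean curve holds at `od0` through the lag, doubles every `t_d` hours
#' afterwards, and saturates at `od_max`; multiplicative lognormal noise
#' with log-scale standard deviation `noise_sd` is applied pointwise.
#'
#' @param od0 initial OD600.
#' @param t_lag lag time in hours.
#' @param t_d doubling time in hours (positive).
#' @param od_max stationary-phase ceiling (must exceed `od0` for a growing
#'   curve; equal to `od0` yields a flat, non-growing culture).
#' @param noise_sd lognormal noise parameter (0 for a noise-free curve).
#' @param seed integer seed; `NULL` continues the caller's RNG stream.
#' @param times sampling grid in hours.
#' @return data frame with `time_h`, `od600`; the generating parameters are
#'   attached as the `"truth"` attribute.
#' @export
make_growth_curve <- function(od0 = 0.02, t_lag = 0, t_d = 10, od_max = 1,
                              noise_sd = 0, seed = NULL,
                              times = seq(0, 100, by = 5)) {
  stopifnot(od0 > 0, t_d > 0, od_max >= od0)
  gen <- function() {
    mean_od <- ifelse(times < t_lag, od0,
                      pmin(od0 * 2^((times - t_lag) / t_d), od_max))
    noise <- if (noise_sd > 0) exp(rnorm(length(times), 0, noise_sd)) else 1
    structure(data.frame(time_h = times, od600 = mean_od * noise),
              truth = list(od0 = od0, t_lag = t_lag, t_d = t_d,
                           od_max = od_max, noise_sd = noise_sd))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a replicated growth experiment
#'
#' Conditions mirror the package's motivating organisms: a fast
#' methylotrophic-substrate condition (doubling time near 14 h, short lag),
#' a slow acetate condition (doubling time near 80 h, lag of hundreds of
#' hours), and a non-growing culture observed past the six-month horizon.
#'
#' @param seed integer seed.
#' @param n_rep replicates per strain.
#' @param noise_sd lognormal noise parameter for every curve.
#' @return list with `curves` (tidy data frame: `strain`, `replicate`,
#'   `time_h`, `od600`) and `truth` (per-strain generating parameters).
#' @export
make_growth_dataset <- function(seed = 1701, n_rep = 3, noise_sd = 0.02) {
  strains <- list(
    tma_fast = list(od0 = 0.05, t_lag = 12, t_d = 14, od_max = 1.0,
                    times = seq(0, 120, by = 6)),
    acetate_slow = list(od0 = 0.03, t_lag = 500, t_d = 80, od_max = 0.6,
                        times = seq(0, 1500, by = 48)),
    no_growth = list(od0 = 0.03, t_lag = 0, t_d = 10, od_max = 0.03,
                     times = seq(0, 4500, by = 250)))
  with_seed(seed, {
    rows <- list()
    for (nm in names(strains)) {
      p <- strains[[nm]]
      for (r in seq_len(n_rep)) {
        cv <- make_growth_curve(p$od0, p$t_lag, p$t_d, p$od_max,
                                noise_sd = noise_sd, times = p$times)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(strain = nm, replicate = paste0("rep", r),
                     stringsAsFactors = FALSE), cv)
      }
    }
    list(curves = do.call(rbind, rows), truth = strains)
  })
}
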