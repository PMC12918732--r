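## One-call survey pipeline: search, filter, profile, classify, audit.

#' Run the acetoclastic module survey end to end
#'
#' Scores every proteome against every profile HMM, applies the E-value
#' ceiling and bit-score cutoff, deduplicates hits, calls per-genome module
#' presence with the subunit-completeness thresholds, assigns co-occurrence
#' categories, and audits the never-observed module combinations. When a
#' taxonomy table is supplied, per-genus prevalence of each module flag and
#' category is summarised as well.
#'
#' @param proteomes data frame of protein sequences (rows from
#'   [read_fasta()] across all genomes).
#' @param hmms list of [profile_hmm] objects.
#' @param taxonomy optional data frame from [parse_gtdb_taxonomy()].
#' @param config a [search_config()].
#' @param module_defs module definitions (default [default_module_set()]).
#' @param rank taxonomy rank for prevalence summaries.
#' @return list with `hits` (filtered, deduplicated), `profiles`,
#'   `categories`, `cooccurrence`, and (if taxonomy given) `prevalence`.
#' @export
run_survey <- function(proteomes, hmms, taxonomy = NULL,
                       config = search_config(),
                       module_defs = default_module_set(),
                       rank = "genus") {
  raw <- run_search(proteomes, hmms, config)
  hits <- best_hit_per_protein(filter_hits(raw, hmms, config))
  profiles <- profile_genomes(hits, module_defs,
                              genome_ids = sort(unique(proteomes$genome_id)))
  categories <- assign_categories(profiles)
  out <- list(hits = hits, profiles = profiles, categories = categories,
              cooccurrence = check_cooccurrence(profiles))
  if (!is.null(taxonomy)) {
    flags <- c("ack_pta", "acs", "rnf", "ech", "fpo_full", "fpo_prime_only")
    cats <- intersect(unique(categories$category),
                      c("I", "II", "III", "IV", "unclassified"))
    prev <- rbind(
      do.call(rbind, lapply(flags, function(t)
        prevalence(profiles, taxonomy, t, rank = rank))),
      do.call(rbind, lapply(cats, function(t)
        prevalence(profiles, taxonomy, t, rank = rank, calls = categories))))
    out$prevalence <- prev
  }
  out
}
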