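## Convert filtered hits into per-genome module presence/absence using
## subunit-completeness thresholds, including the Fpo / Fpo' / FpoF
## distinction (Fpo' = the complex without the F420-interacting FpoF head).

#' Define a metabolic module
#'
#' @param module_id short module name.
#' @param members character vector of member profile-HMM names.
#' @param min_subunits minimum number of distinct member HMMs that must have
#'   at least one passing hit for the module to be called present.
#' @param require_all convenience flag; forces
#'   `min_subunits = length(members)`.
#' @return a `module_definition` list.
#' @export
module_definition <- function(module_id, members,
                              min_subunits = length(members),
                              require_all = min_subunits == length(members)) {
  if (require_all) min_subunits <- length(members)
  if (min_subunits < 1 || min_subunits > length(members))
    stop("min_subunits must be between 1 and the number of member HMMs")
  structure(list(module_id = module_id, members = members,
                 min_subunits = as.integer(min_subunits),
                 require_all = isTRUE(require_all)),
            class = "module_definition")
}

#' The default acetoclastic module set
#'
#' Seven modules with the survey's completeness thresholds: single-gene
#' modules Ack, Pta, Acs and FpoF (each requiring its one HMM), and the
#' multi-subunit respiratory complexes with partial-completeness thresholds
#' of at least 4 of 6 Rnf subunits, at least 4 of 6 Ech subunits, and at
#' least 5 of 7 Fpo' subunits. Member HMM names are placeholders matching
#' the synthetic generator; supply your own accessions via
#' [read_module_set()] when searching real models.
#'
#' @return named list of [module_definition] objects.
#' @export
default_module_set <- function() {
  defs <- list(
    module_definition("ack", "ack"),
    module_definition("pta", "pta"),
    module_definition("acs", "acs"),
    module_definition("rnf", c("rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG"),
                      min_subunits = 4),
    module_definition("ech", c("echA", "echB", "echC", "echD", "echE", "echF"),
                      min_subunits = 4),
    module_definition("fpo_prime",
                      c("fpoA", "fpoB", "fpoC", "fpoD", "fpoH", "fpoI", "fpoJ"),
                      min_subunits = 5),
    module_definition("fpoF", "fpoF"))
  setNames(defs, vapply(defs, `[[`, character(1), "module_id"))
}

#' Read module definitions from a YAML file
#'
#' The file maps each module id to a list with `members` (HMM names) and an
#' optional `min_subunits` (default: all members required).
#'
#' @param path YAML file path.
#' @return named list of [module_definition] objects.
#' @export
read_module_set <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(names(raw), function(id) {
    entry <- raw[[id]]
    members <- as.character(entry$members)
    ms <- if (is.null(entry$min_subunits)) length(members)
          else as.integer(entry$min_subunits)
    module_definition(id, members, min_subunits = ms)
  })
  setNames(defs, names(raw))
}

#' Call one module's presence in one genome
#'
#' Counts the number of distinct member HMMs with at least one passing hit;
#' the module is present when that count reaches `min_subunits`.
#'
#' @param hits filtered hits for one genome.
#' @param definition a [module_definition].
#' @return list with `module_id`, `present`, `subunits_found`, `proteins`
#'   (supporting protein ids).
#' @export
call_module <- function(hits, definition) {
  mh <- hits[hits$hmm_name %in% definition$members, , drop = FALSE]
  found <- unique(mh$hmm_name)
  list(module_id = definition$module_id,
       present = length(found) >= definition$min_subunits,
       subunits_found = length(found),
       proteins = sort(unique(mh$protein_id)))
}

derive_flags <- function(present) {
  c(present,
    ack_pta = unname(present["ack"] && present["pta"]),
    fpo_full = unname(present["fpo_prime"] && present["fpoF"]),
    fpo_prime_only = unname(present["fpo_prime"] && !present["fpoF"]))
}

profile_one <- function(genome_id, hits, module_defs, warn = TRUE) {
  ids <- vapply(module_defs, `[[`, character(1), "module_id")
  if (anyDuplicated(ids)) stop("duplicate module_id in module definitions")
  calls <- lapply(module_defs, call_module, hits = hits)
  present <- setNames(vapply(calls, `[[`, logical(1), "present"), ids)
  if (warn) {
    if (xor(isTRUE(present["ack"]), isTRUE(present["pta"])))
      warning(sprintf("genome %s has a partial Ack+Pta activation module (only %s)",
                      genome_id, if (present["ack"]) "ack" else "pta"))
    for (d in module_defs) {
      if (length(d$members) < 2) next
      mh <- hits[hits$hmm_name %in% d$members, , drop = FALSE]
      multi <- unique(mh$protein_id[duplicated(mh$protein_id)])
      if (length(multi))
        warning(sprintf("genome %s: protein(s) %s hit multiple %s subunit models (counted toward each)",
                        genome_id, paste(multi, collapse = ", "), d$module_id))
    }
  }
  structure(list(genome_id = genome_id,
                 modules = data.frame(
                   module_id = ids,
                   present = unname(present),
                   subunits_found = vapply(calls, `[[`, integer(1), "subunits_found"),
                   proteins = vapply(calls, function(x)
                     paste(x$proteins, collapse = ","), character(1)),
                   stringsAsFactors = FALSE, row.names = NULL),
                 flags = derive_flags(present)),
            class = "genome_profile")
}

#' Profile one genome's module presence/absence
#'
#' Applies every module definition to one genome's filtered hits and derives
#' the combined flags: `ack_pta` (both Ack and Pta present), `fpo_full`
#' (Fpo' plus FpoF) and `fpo_prime_only` (Fpo' without FpoF). Warns on a
#' partial Ack+Pta module and on proteins hitting several subunit models of
#' the same complex.
#'
#' @param hits filtered hits for one genome (rows with other `genome_id`s
#'   are rejected).
#' @param module_defs list of [module_definition]s; must include the seven
#'   defaults' module ids for flag derivation.
#' @param genome_id the genome accession; inferred from `hits` when they are
#'   non-empty.
#' @return a `genome_profile`: per-module presence records plus named
#'   logical `flags`.
#' @export
profile_genome <- function(hits, module_defs = default_module_set(),
                           genome_id = NULL) {
  gids <- unique(hits$genome_id)
  if (length(gids) > 1)
    stop("profile_genome() expects hits for a single genome; see profile_genomes()")
  if (is.null(genome_id)) {
    if (!length(gids)) stop("genome_id must be given when hits are empty")
    genome_id <- gids
  }
  profile_one(genome_id, hits, module_defs)
}

#' Profile many genomes into a wide presence/absence table
#'
#' @param hits filtered hits for any number of genomes.
#' @param module_defs list of [module_definition]s.
#' @param genome_ids genomes to include; defaults to those observed in
#'   `hits`, but passing the full surveyed set ensures hit-free genomes are
#'   reported as all-absent rows.
#' @param warn emit the per-genome partial-module / cross-hit warnings.
#' @return data frame, one row per genome: presence flags for each module,
#'   `<module>_subunits` counts for the multi-subunit complexes, and the
#'   derived `ack_pta`, `fpo_full`, `fpo_prime_only` flags.
#' @export
profile_genomes <- function(hits, module_defs = default_module_set(),
                            genome_ids = NULL, warn = FALSE) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(hits$genome_id))
  if (!length(genome_ids)) stop("no genomes to profile")
  rows <- lapply(genome_ids, function(g) {
    p <- profile_one(g, hits[hits$genome_id == g, , drop = FALSE],
                     module_defs, warn = warn)
    counts <- setNames(p$modules$subunits_found,
                       paste0(p$modules$module_id, "_subunits"))
    multi <- vapply(module_defs, function(d) length(d$members) > 1, logical(1))
    c(as.list(p$flags), as.list(counts[multi]))
  })
  df <- cbind(data.frame(genome_id = genome_ids, stringsAsFactors = FALSE),
              do.call(rbind, lapply(rows, as.data.frame)))
  rownames(df) <- NULL
  df
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("genome %s:\n", x$genome_id))
  present <- x$modules$module_id[x$modules$present]
  cat("  modules present:",
      if (length(present)) paste(present, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  ack_pta=%s acs=%s rnf=%s ech=%s fpo_full=%s fpo_prime_only=%s\n",
              x$flags["ack_pta"], x$flags["acs"], x$flags["rnf"],
              x$flags["ech"], x$flags["fpo_full"], x$flags["fpo_prime_only"]))
  invisible(x)
}
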