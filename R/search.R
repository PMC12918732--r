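## Run every proteome against every profile HMM and apply the survey's hit
## filtering: an E-value ceiling combined with a per-model bit-score cutoff
## (noise cutoff by default).

#' Search configuration
#'
#' @param evalue_max E-value ceiling; hits at or above it are discarded
#'   (strict `<` comparison by default).
#' @param cutoff_key which per-model bit-score cutoff to enforce: the noise
#'   cutoff `"NC"` (default), `"GA"`, `"TC"`, or `"none"` for E-value-only
#'   filtering.
#' @param n_targets number of target sequences used to calibrate internal
#'   E-values; defaults to the size of the searched proteome set, fixed at
#'   search start.
#' @param engine `"internal"` (the package's Viterbi scorer) or
#'   `"hmmsearch"` (shell out to a HMMER 3 binary).
#' @param evalue_strict compare E-values with strict `<` (default) or `<=`.
#' @return a `search_config` list.
#' @export
search_config <- function(evalue_max = 1e-3, cutoff_key = c("NC", "TC", "GA", "none"),
                          n_targets = NULL, engine = c("internal", "hmmsearch"),
                          evalue_strict = TRUE) {
  if (evalue_max <= 0) stop("evalue_max must be positive")
  structure(list(evalue_max = evalue_max,
                 cutoff_key = match.arg(cutoff_key),
                 n_targets = n_targets,
                 engine = match.arg(engine),
                 evalue_strict = isTRUE(evalue_strict)),
            class = "search_config")
}

empty_hits <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             hmm_name = character(), bit_score = numeric(),
             e_value = numeric(), engine = character(),
             stringsAsFactors = FALSE)
}

#' Score all proteomes against all profile HMMs
#'
#' Produces one raw (unfiltered) hit per `(protein, HMM)` pair. With the
#' internal engine every pair is scored by [viterbi_bitscore()] and the
#' E-value comes from the model's `STATS LOCAL VITERBI` Gumbel parameters;
#' models lacking them get infinite E-values (with one warning per model) so
#' that only score cutoffs can apply downstream. With `engine = "hmmsearch"`
#' the HMMER binary is invoked and its tblout is parsed, so only hits HMMER
#' itself reports are returned.
#'
#' @param proteomes data frame with columns `genome_id`, `protein_id`,
#'   `seq` (rows from [read_fasta()] for one or more genomes).
#' @param hmms list of [profile_hmm] objects.
#' @param config a [search_config()].
#' @return hit data frame: `genome_id`, `protein_id`, `hmm_name`,
#'   `bit_score`, `e_value`, `engine`.
#' @export
run_search <- function(proteomes, hmms, config = search_config()) {
  stopifnot(is.data.frame(proteomes), nrow(proteomes) > 0, length(hmms) > 0)
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  n_targets <- if (is.null(config$n_targets)) nrow(proteomes) else config$n_targets
  if (config$engine == "hmmsearch")
    return(run_search_hmmsearch(proteomes, hmms, config))
  hits <- vector("list", length(hmms))
  for (h in seq_along(hmms)) {
    hmm <- hmms[[h]]
    gp <- hmm$stats$viterbi
    if (is.null(gp))
      warning(sprintf("model '%s' has no VITERBI Gumbel parameters; E-values set to Inf, score cutoffs only",
                      hmm$name))
    bits <- vapply(proteomes$seq,
                   function(s) viterbi_bitscore(hmm, s)$bit_score,
                   numeric(1), USE.NAMES = FALSE)
    ev <- if (is.null(gp)) rep(Inf, length(bits))
          else gumbel_evalue(bits, gp[1], gp[2], n_targets)
    hits[[h]] <- data.frame(genome_id = proteomes$genome_id,
                            protein_id = proteomes$protein_id,
                            hmm_name = hmm$name, bit_score = bits,
                            e_value = ev, engine = "internal",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

run_search_hmmsearch <- function(proteomes, hmms, config,
                                 binary = Sys.which("hmmsearch")) {
  if (!nzchar(binary))
    stop("hmmsearch binary not found on PATH; re-run with engine = \"internal\"")
  if (any(grepl("|", proteomes$protein_id, fixed = TRUE)) ||
      any(grepl("|", proteomes$genome_id, fixed = TRUE)))
    stop("'|' is reserved as the genome/protein separator for the hmmsearch engine")
  dir <- tempfile("hmmsearch"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  faa <- file.path(dir, "targets.faa")
  tagged <- proteomes
  tagged$protein_id <- paste(proteomes$genome_id, proteomes$protein_id, sep = "|")
  write_fasta(tagged, faa)
  hfile <- file.path(dir, "models.hmm")
  for (h in seq_along(hmms)) write_hmmer3(hmms[[h]], hfile, append = h > 1)
  tbl <- file.path(dir, "hits.tblout")
  status <- system2(binary, c("--tblout", shQuote(tbl), "--noali",
                              "-E", "1e6", "--domE", "1e6",
                              shQuote(hfile), shQuote(faa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop("hmmsearch exited with non-zero status; check the models, or re-run with engine = \"internal\"")
  raw <- parse_tblout(tbl)
  if (!nrow(raw)) return(empty_hits())
  parts <- strsplit(raw$protein_id, "|", fixed = TRUE)
  data.frame(genome_id = vapply(parts, `[`, character(1), 1),
             protein_id = vapply(parts, `[`, character(1), 2),
             hmm_name = raw$hmm_name, bit_score = raw$bit_score,
             e_value = raw$e_value, engine = "hmmsearch",
             stringsAsFactors = FALSE)
}

## Resolve the bit-score cutoff for one model, walking the documented
## fallback chain NC -> GA -> TC -> none when the requested key is absent.
resolve_cutoff <- function(hmm, cutoff_key) {
  if (cutoff_key == "none") return(list(key = "none", bits = -Inf))
  chain <- unique(c(cutoff_key, "NC", "GA", "TC"))
  for (key in chain)
    if (!is.null(hmm$cutoffs[[key]]))
      return(list(key = key, bits = hmm$cutoffs[[key]][1]))
  list(key = "none", bits = -Inf)
}

#' Filter hits by E-value ceiling and bit-score cutoff
#'
#' Retains hits whose E-value is below `evalue_max` (strict `<` by default)
#' and whose full-sequence bit score is at least the selected cutoff's
#' sequence-bits value on the matching model. When the requested cutoff key
#' is missing on a model, the fallback chain NC, GA, TC, then E-value-only
#' is walked, with a per-model warning. Idempotent; the output is a subset
#' of the input.
#'
#' @param hits hit data frame from [run_search()].
#' @param hmms list of [profile_hmm] objects covering every `hmm_name`.
#' @param config a [search_config()].
#' @return the retained hits, with a logical `passed` column set to `TRUE`.
#' @export
filter_hits <- function(hits, hmms, config = search_config()) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  names(hmms) <- vapply(hmms, `[[`, character(1), "name")
  unknown <- setdiff(unique(hits$hmm_name), names(hmms))
  if (length(unknown))
    stop(sprintf("hit(s) reference unknown model(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!nrow(hits)) { hits$passed <- logical(0); return(hits) }
  cut_bits <- vapply(names(hmms), function(nm) {
    res <- resolve_cutoff(hmms[[nm]], config$cutoff_key)
    if (config$cutoff_key != "none" && res$key != config$cutoff_key)
      warning(sprintf("model '%s' lacks the %s cutoff; falling back to %s",
                      nm, config$cutoff_key,
                      if (res$key == "none") "E-value-only filtering" else res$key))
    res$bits
  }, numeric(1))
  ev_ok <- if (config$evalue_strict) hits$e_value < config$evalue_max
           else hits$e_value <= config$evalue_max
  keep <- ev_ok & hits$bit_score >= cut_bits[hits$hmm_name]
  out <- hits[keep, , drop = FALSE]
  out$passed <- TRUE
  rownames(out) <- NULL
  out
}

#' Keep the single best hit per (genome, protein, model)
#'
#' Deduplicates re-run or duplicated hit rows, ordering by higher bit score,
#' then lower E-value, then lexicographic protein id.
#'
#' @param hits a (typically filtered) hit data frame.
#' @return hit data frame with at most one row per
#'   `(genome_id, protein_id, hmm_name)`.
#' @export
best_hit_per_protein <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$genome_id, hits$hmm_name, -hits$bit_score, hits$e_value,
             hits$protein_id)
  out <- hits[o, , drop = FALSE]
  key <- paste(out$genome_id, out$protein_id, out$hmm_name, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
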