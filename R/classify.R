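## Assign each genome an acetoclastic co-occurrence category (I-IV or
## unclassified), audit co-occurrence claims, and summarise prevalence by
## taxon. Categories pair an acetate-activation module with an
## energy-conservation module: I = Acs + Fpo' only; II = Ack+Pta with Rnf
## or Ech; III = Acs + Rnf; IV (hypothetical) = Ack+Pta + Fpo' only.

CATEGORY_RULES <- list(
  III = function(f) f[["acs"]] && f[["rnf"]],
  II  = function(f) f[["ack_pta"]] && (f[["rnf"]] || f[["ech"]]),
  I   = function(f) f[["acs"]] && f[["fpo_prime_only"]] &&
                    !f[["rnf"]] && !f[["ech"]],
  IV  = function(f) f[["ack_pta"]] && f[["fpo_prime_only"]] &&
                    !f[["rnf"]] && !f[["ech"]])

profile_flags <- function(profile) {
  if (inherits(profile, "genome_profile")) return(as.list(profile$flags))
  as.list(profile)
}

#' Assign the acetoclastic category of one genome
#'
#' Evaluates the category rule table in order (default precedence III, II,
#' I, IV; first matching rule wins) and reports the rationale axes: which
#' activation module(s) are present and which energy-conservation modules.
#' A genome matching no rule is `"unclassified"`. Rule precedence is
#' configurable; the default calls a genome with Acs, Rnf and Fpo'-only
#' category III, since III is defined by the Acs-Rnf co-occurrence.
#'
#' @param profile a `genome_profile` from [profile_genome()], or any named
#'   list/vector with logical `ack_pta`, `acs`, `rnf`, `ech`,
#'   `fpo_prime_only`, `fpo_full` entries.
#' @param rule_order character permutation of `c("III","II","I","IV")`.
#' @return list with `category`, `activation_axis` (`"ack_pta"`, `"acs"`,
#'   `"both"` or `"none"`) and `energy_axis` (character subset of
#'   `c("rnf","ech","fpo_prime_only","fpo_full")`, or `"none"`).
#' @export
assign_category <- function(profile, rule_order = c("III", "II", "I", "IV")) {
  stopifnot(setequal(rule_order, names(CATEGORY_RULES)))
  f <- profile_flags(profile)
  category <- "unclassified"
  for (r in rule_order)
    if (isTRUE(CATEGORY_RULES[[r]](f))) { category <- r; break }
  activation <- if (f$ack_pta && f$acs) "both"
                else if (f$ack_pta) "ack_pta"
                else if (f$acs) "acs" else "none"
  energy <- c("rnf", "ech", "fpo_prime_only", "fpo_full")
  energy <- energy[vapply(energy, function(e) isTRUE(f[[e]]), logical(1))]
  if (!length(energy)) energy <- "none"
  list(category = category, activation_axis = activation, energy_axis = energy)
}

#' Assign categories to a table of genome profiles
#'
#' @param profiles wide profile data frame from [profile_genomes()].
#' @inheritParams assign_category
#' @return data frame with `genome_id`, `category`, `activation_axis`,
#'   `energy_axis` (multiple energy modules joined with `+`).
#' @export
assign_categories <- function(profiles, rule_order = c("III", "II", "I", "IV")) {
  calls <- lapply(seq_len(nrow(profiles)), function(i)
    assign_category(profiles[i, , drop = FALSE], rule_order))
  data.frame(genome_id = profiles$genome_id,
             category = vapply(calls, `[[`, character(1), "category"),
             activation_axis = vapply(calls, `[[`, character(1), "activation_axis"),
             energy_axis = vapply(calls, function(x)
               paste(x$energy_axis, collapse = "+"), character(1)),
             stringsAsFactors = FALSE)
}

#' Audit module co-occurrence claims across a genome set
#'
#' Reports (a) genomes carrying both acetate-activation modules (Ack+Pta
#' and Acs together), and (b) genomes matching the hypothetical category IV
#' pattern (Ack+Pta with Fpo'-only and neither Rnf nor Ech). Both patterns
#' are absent from the surveyed Methanosarcinia, so non-empty lists flag
#' either a remarkable genome or an upstream problem.
#'
#' @param profiles wide profile data frame from [profile_genomes()].
#' @return a `cooccurrence_report` list with character vectors
#'   `ack_pta_and_acs` and `category_iv_pattern`.
#' @export
check_cooccurrence <- function(profiles) {
  both <- profiles$genome_id[profiles$ack_pta & profiles$acs]
  iv <- profiles$genome_id[profiles$ack_pta & profiles$fpo_prime_only &
                           !profiles$rnf & !profiles$ech]
  structure(list(ack_pta_and_acs = both, category_iv_pattern = iv),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  cat("co-occurrence audit:\n")
  cat(sprintf("  Ack+Pta together with Acs: %d genome(s)%s\n",
              length(x$ack_pta_and_acs),
              if (length(x$ack_pta_and_acs))
                paste0(" [", paste(x$ack_pta_and_acs, collapse = ", "), "]")
              else ""))
  cat(sprintf("  category IV pattern (Ack+Pta with Fpo' only): %d genome(s)%s\n",
              length(x$category_iv_pattern),
              if (length(x$category_iv_pattern))
                paste0(" [", paste(x$category_iv_pattern, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Per-taxon prevalence of a module or category
#'
#' Joins profiles (and category calls) to a taxonomy table on the stripped
#' genome accession and summarises, for every taxon observed at the chosen
#' rank, how many genomes carry the target. Genomes without a taxonomy
#' record, or with an empty label at the rank, are excluded with a warning.
#' Percentages are rounded to the nearest integer; the exact fraction is
#' retained.
#'
#' @param profiles wide profile data frame from [profile_genomes()].
#' @param taxonomy data frame from [parse_gtdb_taxonomy()].
#' @param target a module flag column of `profiles` (e.g. `"ack_pta"`,
#'   `"acs"`, `"rnf"`, `"fpo_prime_only"`) or a category label
#'   (`"I"`, `"II"`, `"III"`, `"IV"`, `"unclassified"`).
#' @param rank one of the seven GTDB ranks (default `"genus"`).
#' @param calls category call data frame from [assign_categories()];
#'   required when `target` is a category label.
#' @return data frame with `rank`, `taxon`, `target`, `k`, `n`, `fraction`,
#'   `percent`, one row per taxon.
#' @export
prevalence <- function(profiles, taxonomy, target, rank = "genus",
                       calls = NULL) {
  rank <- match.arg(rank, names(GTDB_RANKS))
  if (target %in% names(profiles) && is.logical(profiles[[target]])) {
    positive <- profiles[[target]]
    ids <- profiles$genome_id
  } else if (target %in% c("I", "II", "III", "IV", "unclassified")) {
    if (is.null(calls))
      stop("category targets need the `calls` table from assign_categories()")
    positive <- calls$category == target
    ids <- calls$genome_id
  } else stop(sprintf("unknown target '%s'", target))
  key <- strip_accession(ids)
  tax <- taxonomy[match(key, strip_accession(taxonomy$genome_id)), rank]
  drop <- is.na(tax) | !nzchar(tax)
  if (any(drop))
    warning(sprintf("%d genome(s) lack a taxonomy record or a %s label and are excluded",
                    sum(drop), rank))
  tax <- tax[!drop]; positive <- positive[!drop]
  taxa <- sort(unique(tax))
  k <- vapply(taxa, function(t) sum(positive[tax == t]), integer(1))
  n <- vapply(taxa, function(t) sum(tax == t), integer(1))
  data.frame(rank = rank, taxon = taxa, target = target,
             k = unname(k), n = unname(n), fraction = unname(k / n),
             percent = unname(round(100 * k / n)),
             stringsAsFactors = FALSE, row.names = NULL)
}
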