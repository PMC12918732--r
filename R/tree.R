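## Prune a reference tree to the surveyed genomes and emit presence/absence
## and category annotations for tree-overlay visualisation (iTOL-style
## plain-text binary datasets).

#' Prune a tree to a set of genomes
#'
#' Returns the smallest topology-preserving tree whose leaves are the
#' intersection of the tree's tips and `genome_ids` (matched on stripped
#' accessions). Internal unary nodes are collapsed and branch lengths
#' summed across collapsed paths. Genomes absent from the tree are reported
#' via a message, not an error.
#'
#' @param tree an \pkg{ape} `phylo` with accession tip labels.
#' @param genome_ids accessions to keep.
#' @return the pruned `phylo`.
#' @export
prune_to_genomes <- function(tree, genome_ids) {
  keep <- tree$tip.label[strip_accession(tree$tip.label) %in%
                         strip_accession(genome_ids)]
  if (!length(keep))
    stop("no overlap between tree tips and the requested genomes")
  missing <- genome_ids[!strip_accession(genome_ids) %in%
                        strip_accession(tree$tip.label)]
  if (length(missing))
    message(sprintf("%d genome(s) not present in the tree: %s",
                    length(missing), paste(missing, collapse = ", ")))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Write tree-overlay annotation files
#'
#' Emits, for a pruned tree: (a) one iTOL `DATASET_BINARY` text file per
#' module flag, (b) a TSV mapping each leaf to its category, and (c) a
#' sidecar listing leaves without a profile. Every tree leaf appears exactly
#' once across the annotation and the sidecar.
#'
#' @param profiles wide profile data frame from [profile_genomes()].
#' @param calls category calls from [assign_categories()].
#' @param tree pruned `phylo` whose tips are genome accessions.
#' @param dir output directory (created if needed).
#' @param modules which logical profile columns to emit as binary datasets.
#' @return invisibly, a list with `files` (paths written) and
#'   `unannotated` (leaves lacking a profile).
#' @export
emit_overlay <- function(profiles, calls, tree, dir,
                         modules = c("ack_pta", "acs", "rnf", "ech",
                                     "fpo_prime", "fpoF", "fpo_full",
                                     "fpo_prime_only")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  leaves <- tree$tip.label
  idx <- match(strip_accession(leaves), strip_accession(profiles$genome_id))
  annotated <- leaves[!is.na(idx)]
  unannotated <- leaves[is.na(idx)]
  files <- character(0)
  for (m in modules) {
    stopifnot(m %in% names(profiles))
    path <- file.path(dir, paste0("itol_", m, ".txt"))
    con <- file(path, "w")
    writeLines(c("DATASET_BINARY", "SEPARATOR TAB",
                 paste0("DATASET_LABEL\t", m), "COLOR\t#4477aa",
                 "FIELD_SHAPES\t1", paste0("FIELD_LABELS\t", m), "DATA"), con)
    vals <- as.integer(profiles[[m]][idx[!is.na(idx)]])
    writeLines(paste(annotated, vals, sep = "\t"), con)
    close(con)
    files <- c(files, path)
  }
  cat_path <- file.path(dir, "categories.tsv")
  ci <- match(strip_accession(annotated), strip_accession(calls$genome_id))
  cat_df <- data.frame(leaf_id = annotated, category = calls$category[ci])
  write.table(cat_df, cat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, cat_path)
  side_path <- file.path(dir, "unannotated_leaves.txt")
  writeLines(unannotated, side_path)
  files <- c(files, side_path)
  invisible(list(files = files, unannotated = unannotated))
}
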