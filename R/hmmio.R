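## Readers and writers for the on-disk formats the survey touches:
## HMMER3 text profiles, protein FASTA, HMMER --tblout tables, GTDB
## taxonomy tables, and Newick trees.

## ---- profile HMM container ------------------------------------------------

#' Construct a profile HMM object
#'
#' A plan7-style profile over the 20-letter amino-acid alphabet, stored in
#' probability space. Emission rows and each state's outgoing transition
#' group (`m->*`, `i->*`, `d->*`) must sum to 1 within `1e-4`.
#'
#' @param name model name.
#' @param M model length (number of match nodes).
#' @param match,insert `M x 20` emission probability matrices, columns in
#'   HMMER alphabet order (see [amino_alphabet()]).
#' @param trans `M x 7` transition probability matrix, columns
#'   `mm, mi, md, im, ii, dm, dd`; row `k` holds transitions leaving node `k`.
#' @param trans0 length-7 begin-node transition row (`B->M1`, `B->I0`,
#'   `B->D1`, and the node-0 insert/delete groups).
#' @param background length-20 background (null) distribution.
#' @param insert0 length-20 node-0 insert emission row (defaults to the
#'   background, HMMER's convention).
#' @param acc optional accession string.
#' @param cutoffs optional named list with any of `GA`, `TC`, `NC`, each a
#'   numeric pair `(sequence-bits, domain-bits)`.
#' @param stats optional named list with any of `msv`, `viterbi` (each
#'   `(mu, lambda)`) and `forward` (`(tau, lambda)`), the Gumbel/exponential
#'   calibration read from `STATS LOCAL` lines.
#' @return an object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, M, match, insert, trans, trans0, background,
                        insert0 = background, acc = NULL, cutoffs = NULL,
                        stats = NULL) {
  hmm <- structure(list(
    name = as.character(name), acc = acc, M = as.integer(M),
    alphabet = "amino",
    match = unname(as.matrix(match)), insert = unname(as.matrix(insert)),
    trans = unname(as.matrix(trans)), trans0 = unname(as.numeric(trans0)),
    background = unname(as.numeric(background)),
    insert0 = unname(as.numeric(insert0)),
    cutoffs = cutoffs, stats = stats), class = "profile_hmm")
  validate_hmm(hmm)
  hmm
}

#' The amino-acid alphabet in HMMER column order
#' @return character vector of the 20 standard residues.
#' @export
amino_alphabet <- function() AMINO

validate_hmm <- function(hmm, tol = 1e-4) {
  if (hmm$M < 1) stop("profile HMM must have M >= 1")
  for (mat in list(hmm$match, hmm$insert)) {
    if (!all(dim(mat) == c(hmm$M, 20)))
      stop("emission matrices must be M x 20")
    if (any(mat < -tol | mat > 1 + tol))
      stop("emission probabilities outside [0, 1]")
    if (any(abs(rowSums(mat) - 1) > tol))
      stop("emission row does not sum to 1 within 1e-4")
  }
  if (!all(dim(hmm$trans) == c(hmm$M, 7)))
    stop("transition matrix must be M x 7")
  rows <- rbind(hmm$trans0, hmm$trans)
  if (any(rows < -tol | rows > 1 + tol))
    stop("transition probabilities outside [0, 1]")
  groups <- list(1:3, 4:5, 6:7)
  for (g in groups)
    if (any(abs(rowSums(rows[, g, drop = FALSE]) - 1) > tol))
      stop("state transition group does not sum to 1 within 1e-4")
  if (abs(sum(hmm$background) - 1) > tol || abs(sum(hmm$insert0) - 1) > tol)
    stop("background distribution does not sum to 1 within 1e-4")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s'%s: M = %d, alphabet = amino\n", x$name,
              if (is.null(x$acc)) "" else paste0(" (", x$acc, ")"), x$M))
  if (!is.null(x$cutoffs) && length(x$cutoffs))
    cat("  cutoffs:", paste(sprintf("%s = %.2f", names(x$cutoffs),
        vapply(x$cutoffs, `[`, numeric(1), 1)), collapse = ", "), "\n")
  if (!is.null(x$stats) && length(x$stats))
    cat("  calibrated:", paste(names(x$stats), collapse = ", "), "\n")
  invisible(x)
}

## ---- HMMER3 text format ---------------------------------------------------

## File body stores negative natural-log probabilities; "*" is probability 0.
.nl2p <- function(tok, line) {
  out <- numeric(length(tok))
  star <- tok == "*"
  out[star] <- 0
  val <- suppressWarnings(as.numeric(tok[!star]))
  if (anyNA(val)) parse_error("non-numeric value in HMM body", line)
  out[!star] <- exp(-val)
  out
}

.p2nl <- function(p) ifelse(p <= 0, "*", sprintf("%.7f", -log(p)))

#' Parse a HMMER3 text profile file
#'
#' Reads one or more records from a HMMER3 ASCII profile file (format
#' versions `HMMER3/f` and `HMMER3/b`), converting the negative-log values
#' of the body back to probabilities (`*` becomes probability zero).
#' Bit-score cutoff lines (`GA`/`TC`/`NC`) and `STATS LOCAL` calibration
#' lines are captured when present. The `COMPO` average-composition line,
#' when present, is used as the model's background distribution; otherwise
#' the background is uniform.
#'
#' @param path path to a `.hmm` text file.
#' @return a list of [profile_hmm] objects (length one for single-record
#'   files).
#' @export
parse_hmmer3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) parse_error("empty HMM file", 1L)
  i <- 1L
  out <- list()
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    if (!grepl("^HMMER3/[fb]", lines[i]))
      parse_error(sprintf("unsupported HMM format line '%s' (only HMMER3/f and HMMER3/b text profiles are read)",
                          trimws(lines[i])), i)
    i <- i + 1L
    hdr <- list(name = NULL, acc = NULL, M = NULL, alph = NULL,
                cutoffs = list(), stats = list())
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      key <- toupper(tok[1])
      if (key == "NAME") hdr$name <- tok[2]
      else if (key == "ACC") hdr$acc <- tok[2]
      else if (key == "LENG") hdr$M <- as.integer(tok[2])
      else if (key == "ALPH") hdr$alph <- tolower(tok[2])
      else if (key %in% c("GA", "TC", "NC")) {
        val <- suppressWarnings(as.numeric(sub(";$", "", tok[2:3])))
        if (anyNA(val)) parse_error(sprintf("malformed %s cutoff line", key), i)
        hdr$cutoffs[[key]] <- val
      } else if (key == "STATS") {
        kind <- tolower(tok[3])
        val <- suppressWarnings(as.numeric(tok[4:5]))
        if (anyNA(val)) parse_error("malformed STATS line", i)
        hdr$stats[[kind]] <- val
      }
      i <- i + 1L
    }
    if (i > n) parse_error("missing HMM body header line", n)
    if (is.null(hdr$name) || is.null(hdr$M))
      parse_error("malformed header: NAME or LENG missing", i)
    if (is.null(hdr$alph) || hdr$alph != "amino")
      parse_error("only the amino alphabet is supported", i)
    M <- hdr$M
    i <- i + 1L  # skip "HMM A C D ..." column header
    if (i <= n && grepl("m->m", lines[i])) i <- i + 1L  # transition labels

    background <- rep(1 / 20, 20)
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (identical(toupper(tok[1]), "COMPO")) {
      if (length(tok) != 21) parse_error("COMPO row of wrong arity", i)
      background <- .nl2p(tok[-1], i)
      i <- i + 1L
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    }
    if (length(tok) != 20) parse_error("node-0 insert emission row of wrong arity", i)
    insert0 <- .nl2p(tok, i)
    i <- i + 1L
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 7) parse_error("node-0 transition row of wrong arity", i)
    trans0 <- .nl2p(tok, i)
    i <- i + 1L

    match <- matrix(0, M, 20); insert <- matrix(0, M, 20)
    trans <- matrix(0, M, 7)
    for (k in seq_len(M)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 21) parse_error("match emission row of wrong arity", i)
      if (suppressWarnings(as.integer(tok[1])) != k)
        parse_error(sprintf("expected node %d", k), i)
      match[k, ] <- .nl2p(tok[2:21], i)
      i <- i + 1L
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) != 20) parse_error("insert emission row of wrong arity", i)
      insert[k, ] <- .nl2p(tok, i)
      i <- i + 1L
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) != 7) parse_error("transition row of wrong arity", i)
      trans[k, ] <- .nl2p(tok, i)
      i <- i + 1L
    }
    if (i > n || trimws(lines[i]) != "//")
      parse_error("record not terminated by //", min(i, n))
    i <- i + 1L
    hmm <- tryCatch(
      profile_hmm(name = hdr$name, M = M, match = match, insert = insert,
                  trans = trans, trans0 = trans0, background = background,
                  insert0 = insert0, acc = hdr$acc,
                  cutoffs = if (length(hdr$cutoffs)) hdr$cutoffs else NULL,
                  stats = if (length(hdr$stats)) hdr$stats else NULL),
      error = function(e) parse_error(conditionMessage(e), i - 1L))
    out[[length(out) + 1L]] <- hmm
  }
  if (!length(out)) parse_error("no HMM records found", 1L)
  out
}

#' Write a profile HMM in HMMER3 text format
#'
#' Emits a `HMMER3/f` ASCII record readable by [parse_hmmer3()] and by
#' HMMER 3 itself. Probabilities are written as negative natural logs with
#' seven decimals; zero probabilities are written as `*`. Cutoff and
#' `STATS LOCAL` lines are emitted only for the fields present on the model.
#'
#' @param hmm a [profile_hmm].
#' @param path output file path.
#' @param append append to an existing file (to build multi-record files).
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(hmm, path, append = FALSE) {
  stopifnot(inherits(hmm, "profile_hmm"))
  validate_hmm(hmm)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("HMMER3/f [acetoscan | profile HMM text]")
  w("NAME  %s", hmm$name)
  if (!is.null(hmm$acc)) w("ACC   %s", hmm$acc)
  w("LENG  %d", hmm$M)
  w("ALPH  amino")
  w("RF    no"); w("MM    no"); w("CONS  yes"); w("CS    no"); w("MAP   yes")
  for (key in c("GA", "TC", "NC"))
    if (!is.null(hmm$cutoffs[[key]]))
      w("%s    %.2f %.2f;", key, hmm$cutoffs[[key]][1], hmm$cutoffs[[key]][2])
  if (!is.null(hmm$stats)) {
    if (!is.null(hmm$stats$msv))
      w("STATS LOCAL MSV      %.5f  %.5f", hmm$stats$msv[1], hmm$stats$msv[2])
    if (!is.null(hmm$stats$viterbi))
      w("STATS LOCAL VITERBI  %.5f  %.5f", hmm$stats$viterbi[1], hmm$stats$viterbi[2])
    if (!is.null(hmm$stats$forward))
      w("STATS LOCAL FORWARD  %.5f  %.5f", hmm$stats$forward[1], hmm$stats$forward[2])
  }
  w("HMM     %s", paste(sprintf("%8s", AMINO), collapse = " "))
  w("        %s", paste(sprintf("%8s",
      c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")), collapse = " "))
  row <- function(p) paste(sprintf("%9s", .p2nl(p)), collapse = " ")
  w("  COMPO %s", row(hmm$background))
  w("        %s", row(hmm$insert0))
  w("        %s", row(hmm$trans0))
  cons <- AMINO[max.col(hmm$match, ties.method = "first")]
  for (k in seq_len(hmm$M)) {
    w("%7d %s %6d %s - - -", k, row(hmm$match[k, ]), k, cons[k])
    w("        %s", row(hmm$insert[k, ]))
    w("        %s", row(hmm$trans[k, ]))
  }
  w("//")
  invisible(path)
}

## ---- protein FASTA --------------------------------------------------------

#' Read a protein FASTA proteome
#'
#' Loads one genome's proteome. Sequences are uppercased; the protein id is
#' the first whitespace-delimited token of each header. Residues outside the
#' 20-letter alphabet are rejected, except `X`, which is kept and treated as
#' ambiguous by the scoring engine.
#'
#' @param path FASTA file path.
#' @param genome_id genome accession to attach to every sequence.
#' @return data frame with columns `genome_id`, `protein_id`, `seq`.
#' @export
read_fasta <- function(path, genome_id) {
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) parse_error(conditionMessage(e)))
  if (!length(aa)) parse_error("empty FASTA file")
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    parse_error(sprintf("duplicate protein id(s) in %s: %s", path,
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(aa))
  bad <- grepl(sprintf("[^%sX]", paste(AMINO, collapse = "")), seqs)
  if (any(bad))
    parse_error(sprintf("illegal residue letter(s) in sequence(s): %s",
                        paste(ids[bad], collapse = ", ")))
  if (any(!nzchar(seqs))) parse_error("empty sequence record")
  data.frame(genome_id = genome_id, protein_id = unname(ids),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write proteins to FASTA
#' @param proteins data frame with `protein_id` and `seq` columns.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  x <- Biostrings::AAStringSet(setNames(proteins$seq, proteins$protein_id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

## ---- HMMER --tblout -------------------------------------------------------

#' Parse a HMMER per-sequence tabular output file
#'
#' Reads HMMER's `--tblout` dialect: whitespace-delimited columns, `#`
#' comment lines. The columns consumed are target name (1), query name (3),
#' full-sequence E-value (5) and full-sequence bit score (6).
#'
#' @param path tblout file path.
#' @return data frame with columns `protein_id`, `hmm_name`, `e_value`,
#'   `bit_score`; zero rows for a file of comments only.
#' @export
parse_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- data.frame(protein_id = character(), hmm_name = character(),
                    e_value = numeric(), bit_score = numeric(),
                    stringsAsFactors = FALSE)
  for (j in keep) {
    tok <- strsplit(trimws(lines[j]), "\\s+")[[1]]
    if (length(tok) < 6) parse_error("tblout row with too few columns", j)
    ev <- suppressWarnings(as.numeric(tok[5]))
    bs <- suppressWarnings(as.numeric(tok[6]))
    if (is.na(ev) || is.na(bs))
      parse_error("non-numeric score field in tblout row", j)
    out[nrow(out) + 1L, ] <- list(tok[1], tok[3], ev, bs)
  }
  out
}

## ---- GTDB taxonomy --------------------------------------------------------

#' Parse a GTDB taxonomy table
#'
#' Two-column tab-separated table: genome accession and a semicolon-joined
#' seven-rank taxonomy string (`d__...;p__...;c__...;o__...;f__...;g__...;
#' s__...`). Rank labels may be empty after the prefix. Accession prefixes
#' `RS_`/`GB_` are stripped for joining.
#'
#' @param path file path.
#' @return data frame with columns `genome_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`.
#' @export
parse_gtdb_taxonomy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) parse_error("empty taxonomy table")
  recs <- lapply(seq_along(lines), function(j) {
    tok <- strsplit(lines[j], "\t", fixed = TRUE)[[1]]
    if (length(tok) != 2) parse_error("taxonomy row must have two tab-separated columns", j)
    ranks <- strsplit(tok[2], ";", fixed = TRUE)[[1]]
    if (length(ranks) != 7)
      parse_error(sprintf("expected 7 ranks, found %d", length(ranks)), j)
    ranks <- trimws(ranks)
    ok <- startsWith(ranks, unname(GTDB_RANKS))
    if (!all(ok))
      parse_error(sprintf("misplaced rank prefix '%s'", ranks[which(!ok)[1]]), j)
    c(strip_accession(tok[1]), substring(ranks, 4))
  })
  df <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
  names(df) <- c("genome_id", names(GTDB_RANKS))
  if (anyDuplicated(df$genome_id))
    parse_error("duplicate genome accession in taxonomy table")
  df
}

## ---- Newick trees ---------------------------------------------------------

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} with an up-front balance check so that a
#' malformed file raises a named parse error instead of an opaque failure.
#' Leaf labels are genome accessions; round trips preserve topology and
#' labels.
#'
#' @param path Newick file path.
#' @return `read_newick`: an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  no_q <- gsub("'[^']*'", "", txt)
  if (sum(strsplit(no_q, "")[[1]] == "(") != sum(strsplit(no_q, "")[[1]] == ")"))
    parse_error("unbalanced parentheses in Newick file")
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) parse_error(conditionMessage(e)))
  if (is.null(tree)) parse_error("could not parse Newick file")
  tree
}

#' @rdname read_newick
#' @param tree an \pkg{ape} `phylo` object.
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
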