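## Minimal profile-HMM scoring engine: single-hit local Viterbi bit scores
## against an i.i.d. background null, plus Gumbel E-values. Serves as the
## hermetic search backend for synthetic data and as an oracle-verifiable
## stand-in for an external hmmsearch binary.

seq_to_idx <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AMINO)
  idx[chars == "X"] <- 0L  # ambiguous: scores as background (log-odds 0)
  if (anyNA(idx))
    stop(sprintf("sequence contains letters outside the amino alphabet: %s",
                 paste(unique(chars[is.na(idx)]), collapse = ", ")))
  idx
}

## L x M natural-log odds of emitting residue i at node k, versus background.
logodds_matrix <- function(emis, background, idx) {
  lo <- log(emis) - rep(log(background), each = nrow(emis))  # M x 20
  out <- matrix(0, length(idx), nrow(emis))
  known <- idx > 0L
  out[known, ] <- t(lo)[idx[known], , drop = FALSE]
  out
}

#' Score a protein against a profile HMM (single-hit local Viterbi)
#'
#' Computes the maximum, over all single contiguous local alignments, of the
#' log2-odds score of the sequence under the profile versus an i.i.d.
#' background null. Alignment may begin at any match node (uniform entry
#' probability `1/M`) and exit from any match node at no cost; flanking
#' residues are emitted by the null and contribute nothing. Ambiguous `X`
#' residues score as background. Deterministic.
#'
#' @param hmm a [profile_hmm].
#' @param seq a protein sequence string, or a one-row data frame as returned
#'   by [read_fasta()].
#' @return an object of class `scored_alignment`: list with `bit_score`,
#'   `start_node`, `end_node`, `start_res`, `end_res` (1-based, inclusive).
#' @seealso [viterbi_enumerate()] for the brute-force reference scorer used
#'   to validate this implementation on tiny instances.
#' @export
viterbi_bitscore <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (is.data.frame(seq)) seq <- seq$seq[1]
  if (!nzchar(seq)) stop("sequence must have length >= 1")
  idx <- seq_to_idx(seq)
  lom <- logodds_matrix(hmm$match, hmm$background, idx)
  loi <- logodds_matrix(hmm$insert, hmm$background, idx)
  res <- viterbi_local_c(lom, loi, log(hmm$trans), -log(hmm$M))
  structure(list(bit_score = res$score / log(2),
                 start_node = res$start_node, end_node = res$end_node,
                 start_res = res$start_res, end_res = res$end_res),
            class = "scored_alignment")
}

#' Brute-force reference scorer by exhaustive path enumeration
#'
#' Enumerates every legal single-hit local state path (begin at any match
#' node with uniform probability `1/M`, walk match/insert/delete states, end
#' at any match node) and returns the best log2-odds score. Exponential in
#' the problem size; intended only for tiny models (`M <= 3`) and sequences
#' (`L <= 4`) as an independent check of [viterbi_bitscore()].
#'
#' @inheritParams viterbi_bitscore
#' @return best bit score over all enumerated paths.
#' @export
viterbi_enumerate <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (is.data.frame(seq)) seq <- seq$seq[1]
  idx <- seq_to_idx(seq)
  L <- length(idx); M <- hmm$M
  lom <- logodds_matrix(hmm$match, hmm$background, idx)
  loi <- logodds_matrix(hmm$insert, hmm$background, idx)
  ltr <- log(hmm$trans)
  best <- -Inf
  # walk(state at node k having just consumed residue i, accumulated score)
  walk <- function(state, k, i, sc) {
    if (!is.finite(sc)) return()
    if (state == "M") best <<- max(best, sc)  # may end at any match state
    if (state == "M") {
      if (k < M && i < L) walk("M", k + 1L, i + 1L, sc + ltr[k, 1] + lom[i + 1L, k + 1L])
      if (i < L)          walk("I", k,      i + 1L, sc + ltr[k, 2] + loi[i + 1L, k])
      if (k < M)          walk("D", k + 1L, i,      sc + ltr[k, 3])
    } else if (state == "I") {
      if (k < M && i < L) walk("M", k + 1L, i + 1L, sc + ltr[k, 4] + lom[i + 1L, k + 1L])
      if (i < L)          walk("I", k,      i + 1L, sc + ltr[k, 5] + loi[i + 1L, k])
    } else {  # D
      if (k < M && i < L) walk("M", k + 1L, i + 1L, sc + ltr[k, 6] + lom[i + 1L, k + 1L])
      if (k < M)          walk("D", k + 1L, i,      sc + ltr[k, 7])
    }
  }
  for (i0 in seq_len(L))
    for (k0 in seq_len(M))
      walk("M", k0, i0, -log(M) + lom[i0, k0])
  best / log(2)
}

#' Gumbel E-value for a bit score
#'
#' Converts a Viterbi bit score to an expected number of false positives
#' under the Gumbel law with location `mu` and scale `1/lambda`:
#' `E = n_targets * (1 - exp(-exp(-lambda * (bits - mu))))`. Monotone
#' non-increasing in `bits` and linear in `n_targets`.
#'
#' @param bits bit score.
#' @param mu Gumbel location (bits).
#' @param lambda Gumbel slope (per bit), must be positive.
#' @param n_targets number of target sequences searched.
#' @return E-value (vectorised over `bits`).
#' @export
gumbel_evalue <- function(bits, mu, lambda, n_targets = 1) {
  if (lambda <= 0) stop("lambda must be positive")
  if (n_targets < 1) stop("n_targets must be >= 1")
  n_targets * (-expm1(-exp(-lambda * (bits - mu))))
}

#' Consensus sequence of a profile HMM
#'
#' The length-`M` string of per-node argmax match emissions; ties break to
#' the first letter in alphabet order.
#'
#' @param hmm a [profile_hmm].
#' @return a single consensus string of length `M`.
#' @export
hmm_consensus <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  paste(AMINO[max.col(hmm$match, ties.method = "first")], collapse = "")
}

#' @export
print.scored_alignment <- function(x, ...) {
  cat(sprintf("alignment: %.2f bits, nodes %d-%d, residues %d-%d\n",
              x$bit_score, x$start_node, x$end_node, x$start_res, x$end_res))
  invisible(x)
}
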