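as_dna <- function(seq) chartr("Uu", "Tt", toupper(seq))

aln_from_pa <- function(pa, q, s) {
  qa <- as.character(Biostrings::alignedPattern(pa))
  sa <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(qa, "")[[1]]; sc <- strsplit(sa, "")[[1]]
  gap <- qc == "-" | sc == "-"
  ident <- sum(!gap & qc == sc)
  structure(list(
    query_aln = qa, subject_aln = sa,
    score = Biostrings::score(pa),
    identities = ident,
    mismatches = sum(!gap & qc != sc),
    gaps = sum(gap),
    columns = length(qc),
    query_range = c(Biostrings::start(Biostrings::pattern(pa)),
                    Biostrings::end(Biostrings::pattern(pa))),
    subject_range = c(Biostrings::start(Biostrings::subject(pa)),
                      Biostrings::end(Biostrings::subject(pa)))
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$query_aln, "\n", x$subject_aln, "\n", sep = "")
  cat(sprintf("score %.1f  id %d  mm %d  gaps %d\n",
              x$score, x$identities, x$mismatches, x$gaps))
  invisible(x)
}

#' Global pairwise nucleotide alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + L * gap_extend` (both negative).
#' RNA input is aligned in DNA space (U treated as T).
#'
#' @param q,s Query and subject sequences (non-empty).
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Gap opening / per-base extension penalties
#'   (negative values).
#' @return An `alignment_result` with the aligned strings, score, and
#'   identity/mismatch/gap tallies.
#' @export
align_global <- function(q, s, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1) {
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    as_dna(q), as_dna(s), type = "global", substitutionMatrix = sm,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  aln_from_pa(pa, q, s)
}

#' Local pairwise nucleotide alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams align_global
#' @return An `alignment_result`; `query_range`/`subject_range` give the
#'   1-based aligned spans on the input sequences.
#' @export
align_local <- function(q, s, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    as_dna(q), as_dna(s), type = "local", substitutionMatrix = sm,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  aln_from_pa(pa, q, s)
}

#' Alignment identity, optionally excluding end gaps
#'
#' Identity is matched columns over alignment columns; with
#' `exclude_end_gaps = TRUE` (the default) leading/trailing columns that
#' are gapped in either sequence are dropped from both numerator and
#' denominator, so truncated sequences are not penalized for missing ends.
#'
#' @param aln An `alignment_result`.
#' @param exclude_end_gaps Drop terminal gap columns.
#' @return Identity in [0, 1]; NA for an all-gap core.
#' @export
alignment_identity <- function(aln, exclude_end_gaps = TRUE) {
  qc <- strsplit(aln$query_aln, "")[[1]]
  sc <- strsplit(aln$subject_aln, "")[[1]]
  keep <- rep(TRUE, length(qc))
  if (exclude_end_gaps) {
    gap <- qc == "-" | sc == "-"
    core <- which(!gap)
    if (length(core) == 0) return(NA_real_)
    keep <- seq_along(qc) >= min(core) & seq_along(qc) <= max(core)
  }
  sum(qc[keep] == sc[keep] & qc[keep] != "-") / sum(keep)
}

#' Global protein alignment (BLOSUM62, affine gaps)
#'
#' @param q,s Protein sequences.
#' @param gap_open,gap_extend Negative gap penalties.
#' @return An `alignment_result`.
#' @export
align_protein <- function(q, s, gap_open = -10, gap_extend = -1) {
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = -gap_open, gapExtension = -gap_extend)
  aln_from_pa(pa, q, s)
}

#' Local protein alignment (BLOSUM62, affine gaps)
#'
#' @inheritParams align_protein
#' @return An `alignment_result`.
#' @export
align_protein_local <- function(q, s, gap_open = -10, gap_extend = -1) {
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = -gap_open, gapExtension = -gap_extend)
  aln_from_pa(pa, q, s)
}
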