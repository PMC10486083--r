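#' @useDynLib retromir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

normalize_rna <- function(seq, max_ambiguous = 0) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  bad <- nchar(gsub("[ACGU]", "", s))
  if (bad > max_ambiguous * nchar(s)) {
    stop("sequence contains ", bad, " non-ACGU(T) characters")
  }
  s
}

#' Maximum base-pairing fold of an RNA sequence
#'
#' Nussinov-style dynamic program maximizing the number of nested
#' Watson-Crick (and, by default, G:U wobble) pairs subject to a minimum
#' hairpin-loop length, with a deterministic traceback. This is a
#' structure-counting stand-in for a thermodynamic minimum-free-energy
#' fold: it has no energy model, but discriminates genuine stem-loops from
#' unstructured sequence at the scales used here.
#'
#' @param seq RNA (or DNA; T is read as U) sequence.
#' @param min_loop Minimum hairpin loop length (nt) between a pair.
#' @param allow_gu Allow G:U wobble pairs (default TRUE).
#' @return An object of class `fold_result` with elements `sequence`,
#'   `dotbracket`, `pairs` (two-column matrix of 1-based pair indices),
#'   `n_pairs`, `longest_helix`, `loop_len` (terminal loop of the longest
#'   helix; NA when no helix), `paired_fraction`.
#' @export
fold_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  partner <- .nussinov_pairs(s, as.integer(min_loop), isTRUE(allow_gu))
  db <- rep(".", n)
  idx <- which(partner >= 0)
  db[idx[partner[idx] > idx - 1L]] <- "("
  db[idx[partner[idx] < idx - 1L]] <- ")"
  open <- which(partner > seq_len(n) - 1L)  # 0-based partner > 0-based self
  pairs <- cbind(i = open, j = partner[open] + 1L)
  helix <- helix_chains(pairs)
  structure(list(
    sequence = s,
    dotbracket = paste(db, collapse = ""),
    pairs = pairs,
    n_pairs = nrow(pairs),
    longest_helix = helix$longest,
    loop_len = helix$loop_len,
    paired_fraction = if (n > 0) 2 * nrow(pairs) / n else 0
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("pairs: %d  longest helix: %d  terminal loop: %s  paired: %.2f\n",
              x$n_pairs, x$longest_helix,
              ifelse(is.na(x$loop_len), "NA", x$loop_len),
              x$paired_fraction))
  invisible(x)
}

# Chain stacked pairs into extended helices: consecutive pairs (i1,j1),
# (i2,j2) with i2 > i1, j2 < j1 extend one helix when the total interior
# unpaired gap (i2-i1-1)+(j1-j2-1) is at most max_gap. Returns the pair
# count of the longest chain and its terminal loop length.
helix_chains <- function(pairs, max_gap = 6) {
  if (nrow(pairs) == 0) return(list(longest = 0L, loop_len = NA_integer_))
  p <- pairs[order(pairs[, 1]), , drop = FALSE]
  n <- nrow(p)
  best_len <- 0L; best_inner <- NULL
  chain_len <- 1L; chain_start <- 1L
  for (k in seq_len(n)) {
    extend <- FALSE
    if (k > 1) {
      gap <- (p[k, 1] - p[k - 1, 1] - 1L) + (p[k - 1, 2] - p[k, 2] - 1L)
      extend <- p[k, 2] < p[k - 1, 2] && gap >= 0 && gap <= max_gap
    }
    if (extend) chain_len <- chain_len + 1L else { chain_len <- 1L; chain_start <- k }
    if (chain_len > best_len) { best_len <- chain_len; best_inner <- p[k, ] }
  }
  loop <- if (is.null(best_inner)) NA_integer_ else {
    as.integer(best_inner[2] - best_inner[1] - 1L)
  }
  list(longest = best_len, loop_len = loop)
}

#' Decide whether a sequence folds into a miRNA-like stem-loop
#'
#' A sequence passes when its maximum-pairing fold contains an extended
#' helix of at least `min_stem` base pairs (allowing interior loops of up
#' to 6 unpaired nt between helix segments), the terminal loop closed by
#' that helix is at most `max_loop` nt, and at least `min_paired_frac` of
#' all bases are paired.
#'
#' @param seq RNA/DNA sequence (recommended length 40-200 nt; a warning is
#'   emitted outside that range).
#' @param min_stem Minimum extended-helix length in base pairs.
#' @param max_loop Maximum terminal loop length (nt).
#' @param min_paired_frac Minimum fraction of paired bases.
#' @param min_loop,allow_gu Passed to [fold_max_pairs()].
#' @return List with `is_hairpin` (logical) and `fold` (the `fold_result`).
#' @export
assess_hairpin <- function(seq, min_stem = 18, max_loop = 40,
                           min_paired_frac = 0.4, min_loop = 3,
                           allow_gu = TRUE) {
  n <- nchar(seq)
  if (n < 40 || n > 200) {
    warning("sequence length ", n, " outside the recommended 40-200 nt range")
  }
  fr <- fold_max_pairs(seq, min_loop = min_loop, allow_gu = allow_gu)
  ok <- fr$longest_helix >= min_stem &&
    !is.na(fr$loop_len) && fr$loop_len <= max_loop &&
    fr$paired_fraction >= min_paired_frac
  list(is_hairpin = isTRUE(ok), fold = fr)
}
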