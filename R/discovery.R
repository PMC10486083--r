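#' Find candidate retro-miRs: miRNA precursors overlapping retrocopies
#'
#' One candidate is produced per (precursor, retrocopy) pair whose loci
#' overlap by at least `min_overlap` bp. The overlap is strand-aware by
#' default (retrocopy and miRNA co-orientation is the biological
#' expectation); set `ignore_strand = TRUE` for an orientation-blind scan.
#'
#' @param mirnas Named list of [mirna_record()] objects.
#' @param retrocopies Named list of [retrocopy_record()] objects.
#' @param min_overlap Minimum precursor/retrocopy overlap (bp).
#' @param ignore_strand Disable strand matching.
#' @return Data frame of candidates ordered by (chrom, start, ids), with
#'   `overlap_bp` and placeholder evidence flags.
#' @export
find_candidates <- function(mirnas, retrocopies, min_overlap = 5,
                            ignore_strand = FALSE) {
  rows <- list()
  for (m in mirnas) {
    for (r in retrocopies) {
      ov <- overlap_bp(interval_of(m), interval_of(r),
                       ignore_strand = ignore_strand)
      if (ov >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m$id, retrocopy_id = r$id, chrom = m$chrom,
          start = m$start, end = m$end, strand = m$strand,
          overlap_bp = ov, repeat_overlap = FALSE, hairpin_ok = NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(0), retrocopy_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      overlap_bp = integer(0), repeat_overlap = logical(0),
                      hairpin_ok = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$mirna_id, out$retrocopy_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag candidates whose precursor lies inside an annotated repeat
#'
#' Mirrors the manual mobile-element screen as a reproducible rule: a
#' candidate is flagged when at least `min_frac` of its precursor length
#' is covered by repeat annotation. Flagged candidates are partitioned
#' into a review set, never silently deleted.
#'
#' @param candidates Data frame from [find_candidates()].
#' @param repeats BED-style data frame (`chrom`, `start`, `end`, ...).
#' @param min_frac Coverage fraction at or above which to flag.
#' @return List with `kept` and `review` data frames (both carry the
#'   updated `repeat_overlap` flag).
#' @export
exclude_repeats <- function(candidates, repeats, min_frac = 0.5) {
  if (nrow(candidates) == 0 || is.null(repeats) || nrow(repeats) == 0) {
    return(list(kept = candidates, review = candidates[0, , drop = FALSE]))
  }
  flag <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    cov <- 0L
    for (j in seq_len(nrow(repeats))) {
      rp <- repeats[j, ]
      if (rp$chrom != cand$chrom) next
      cov <- cov + max(0L, min(cand$end, rp$end) - max(cand$start, rp$start))
    }
    cov / (cand$end - cand$start) >= min_frac
  }, logical(1))
  candidates$repeat_overlap <- flag
  list(kept = candidates[!flag, , drop = FALSE],
       review = candidates[flag, , drop = FALSE])
}

#' Confirm that a candidate's precursor folds into a stem-loop
#'
#' Extracts the precursor sequence from the genome (strand-aware) and
#' applies [assess_hairpin()]; candidates whose structure passes are
#' retro-miRs.
#'
#' @param candidates Data frame from [find_candidates()].
#' @param genome Named character vector of contig sequences.
#' @param ... Passed to [assess_hairpin()].
#' @return The candidates with `hairpin_ok` filled in.
#' @export
confirm_hairpin <- function(candidates, genome, ...) {
  candidates$hairpin_ok <- vapply(seq_len(nrow(candidates)), function(i) {
    iv <- gi(candidates$chrom[i], candidates$start[i], candidates$end[i],
             candidates$strand[i])
    s <- extract_sequence(genome, iv)
    bad <- nchar(gsub("[ACGTUacgtu]", "", s))
    if (bad > 0.1 * nchar(s)) {
      stop("candidate ", candidates$mirna_id[i],
           ": more than 10% non-nucleotide characters")
    }
    suppressWarnings(assess_hairpin(s, ...)$is_hairpin)
  }, logical(1))
  candidates
}

#' Run the discovery stage end to end
#'
#' @param mirnas,retrocopies,genome,repeats Stage inputs.
#' @param min_overlap,repeat_frac,ignore_strand Stage parameters.
#' @return List with `retro_mirs` (confirmed), `rejected_fold` (overlap
#'   candidates that failed folding), and `review` (repeat-flagged).
#' @export
discover_retromirs <- function(mirnas, retrocopies, genome,
                               repeats = NULL, min_overlap = 5,
                               repeat_frac = 0.5, ignore_strand = FALSE) {
  cand <- find_candidates(mirnas, retrocopies, min_overlap = min_overlap,
                          ignore_strand = ignore_strand)
  part <- exclude_repeats(cand, repeats, min_frac = repeat_frac)
  conf <- confirm_hairpin(part$kept, genome)
  list(retro_mirs = conf[conf$hairpin_ok, , drop = FALSE],
       rejected_fold = conf[!conf$hairpin_ok, , drop = FALSE],
       review = part$review)
}

translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Screen transcripts for DNA-mediated duplications
#'
#' Translated search in the spirit of a tblastn screen: each transcript's
#' protein (longest forward-frame ORF) is aligned (BLOSUM62, affine,
#' local) against all six reading frames of sliding genome windows; a
#' duplication is called when a non-self hit scores at least `ratio_min`
#' of the protein's self-alignment score. Exhaustive over windows -
#' intended for toy genomes, not chromosome scale.
#'
#' @param txs Named list of [transcript_model()] objects.
#' @param genome Named character vector.
#' @param ratio_min Minimum score ratio for a call.
#' @param window,step Genome window size and stride (bp).
#' @return Data frame of calls: `gene_id`, `tx_id`, `chrom`, `start`,
#'   `end`, `frame`, `score_ratio`.
#' @export
find_dna_duplications <- function(txs, genome, ratio_min = 0.7,
                                  window = 2000, step = 1000) {
  calls <- list()
  for (tx in txs) {
    mrna <- splice(genome, tx)
    orf <- find_longest_orf(mrna)
    if (is.na(orf$frame) || nchar(orf$protein) < 30) {
      warning("transcript ", tx$id, ": protein < 30 aa, skipped")
      next
    }
    prot <- orf$protein
    self_score <- align_protein_local(prot, prot)$score
    own <- interval_of(tx)
    for (chrom in names(genome)) {
      L <- nchar(genome[[chrom]])
      starts <- unique(c(seq(0L, max(0L, L - window), by = step),
                         max(0L, L - window)))
      for (ws in starts) {
        we <- min(L, ws + window)
        wseq <- substring(genome[[chrom]], ws + 1L, we)
        frames <- c(lapply(1:3, function(f) substring(wseq, f)),
                    lapply(1:3, function(f) substring(revcomp(wseq), f)))
        for (fi in seq_along(frames)) {
          p <- translate_dna(frames[[fi]])
          if (nchar(p) < 10) next
          aln <- align_protein_local(prot, p)
          ratio <- aln$score / self_score
          if (ratio < ratio_min) next
          # genomic span of the aligned subject (frame-aware)
          off <- (fi - 1L) %% 3L
          nt_lo <- off + 3L * (aln$subject_range[1] - 1L)
          nt_hi <- off + 3L * aln$subject_range[2]
          hit <- if (fi <= 3) gi(chrom, ws + nt_lo, ws + nt_hi, "+")
          else gi(chrom, we - nt_hi, we - nt_lo, "-")
          if (overlap_bp(hit, own, ignore_strand = TRUE) > 0) next
          calls[[length(calls) + 1L]] <- data.frame(
            gene_id = tx$gene_id, tx_id = tx$id, chrom = chrom,
            start = hit$start, end = hit$end, frame = fi,
            score_ratio = min(1, ratio), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(gene_id = character(0), tx_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      score_ratio = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  # merge overlapping windows: keep the best-scoring window per locus
  out <- out[order(out$gene_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
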