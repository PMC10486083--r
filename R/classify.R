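#' Place a retro-miR precursor on its spliced parental mRNA
#'
#' Aligns the precursor sequence (taken from the retrocopy locus,
#' transcript-oriented) locally against the spliced parental mRNA and
#' projects the best placement back to parental genomic blocks. A
#' placement below 60% identity is reported as unplaceable.
#'
#' @param precursor_seq Precursor sequence (transcript orientation).
#' @param parental_tx Parental [transcript_model()].
#' @param genome Named character vector.
#' @param min_identity Identity below which the placement is rejected.
#' @return List with `placed` (logical), `mrna_span` (0-based half-open),
#'   `blocks` (genomic interval data frame), `identity`, `alignment`.
#' @export
locate_in_parent <- function(precursor_seq, parental_tx, genome,
                             min_identity = 0.6) {
  mrna <- splice(genome, parental_tx)
  aln <- align_local(precursor_seq, mrna)
  ident <- alignment_identity(aln, exclude_end_gaps = FALSE)
  cols <- aln$columns
  # guard against trivial local hits: require most of the precursor aligned
  frac_aligned <- (aln$query_range[2] - aln$query_range[1] + 1) /
    nchar(precursor_seq)
  if (is.na(ident) || cols == 0 || ident < min_identity ||
      frac_aligned < 0.5) {
    return(list(placed = FALSE, mrna_span = c(NA_integer_, NA_integer_),
                blocks = NULL, identity = ident, alignment = aln))
  }
  span <- c(aln$subject_range[1] - 1L, aln$subject_range[2])
  blocks <- project_to_genome(parental_tx, span[1], span[2])
  list(placed = TRUE, mrna_span = span, blocks = blocks, identity = ident,
       alignment = aln)
}

count_mature_mismatches <- function(mature_seq, parental_tx, genome,
                                    mrna_span = NULL) {
  mrna <- splice(genome, parental_tx)
  aln <- align_local(as_dna(mature_seq), mrna)
  aligned <- aln$query_range[2] - aln$query_range[1] + 1
  # unaligned mature bases count as differences
  aln$mismatches + aln$gaps + (nchar(mature_seq) - aligned)
}

#' Classify one confirmed retro-miR as R, EJ, or N
#'
#' Decision order (structural evidence first):
#' 1. EJ when the precursor placement on the parental gene splits into
#'    two or more genomic blocks separated by at least `min_intron` bp -
#'    the precursor is contiguous only in the retrocopy.
#' 2. R when an annotated parental exonic miRNA overlaps the placed locus
#'    and the mature copy differs from the parent by at most 1 nt.
#' 3. N when the mature differs by at least 2 nt and the equivalent
#'    parental region does not fold into a stem-loop.
#' Anything else is reported as `unclassified`.
#'
#' @param candidate One row of the confirmed-candidate data frame.
#' @param mirna The candidate's [mirna_record()].
#' @param retrocopy The host [retrocopy_record()].
#' @param parental_tx Parental [transcript_model()].
#' @param parental_mirnas Named list of annotated parental
#'   [mirna_record()]s (possibly empty).
#' @param genome Named character vector.
#' @param min_intron Minimum genomic gap (bp) between placement blocks to
#'   count as an intron.
#' @return A one-row data frame with the class call and evidence.
#' @export
classify_retromir <- function(candidate, mirna, retrocopy, parental_tx,
                              parental_mirnas, genome, min_intron = 30) {
  pre_seq <- extract_sequence(genome, interval_of(mirna))
  loc <- locate_in_parent(pre_seq, parental_tx, genome)
  evidence <- function(cls, mm, loc, parental_hairpin = NA,
                       parental_mirna = NA_character_) {
    data.frame(
      mirna_id = mirna$id, retrocopy_id = retrocopy$id, class = cls,
      placed = loc$placed, placement_identity = loc$identity,
      n_blocks = if (is.null(loc$blocks)) 0L else nrow(loc$blocks),
      mature_mismatches = mm, parental_hairpin = parental_hairpin,
      parental_mirna = parental_mirna,
      blocks = if (is.null(loc$blocks)) NA_character_ else
        paste(sprintf("%s:%d-%d", loc$blocks$chrom, loc$blocks$start,
                      loc$blocks$end), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!loc$placed) {
    return(evidence("unclassified", NA_integer_, loc))
  }
  mm <- min(vapply(seq_len(nrow(mirna$matures)), function(i) {
    count_mature_mismatches(mirna$matures$sequence[i], parental_tx, genome)
  }, numeric(1)))

  # (1) exon-junction evidence
  if (nrow(loc$blocks) >= 2) {
    b <- loc$blocks[order(loc$blocks$start), ]
    gaps <- b$start[-1] - b$end[-nrow(b)]
    if (any(gaps >= min_intron)) {
      return(evidence("EJ", mm, loc))
    }
  }
  # (2) retroposed: annotated parental miRNA at the placed locus
  overlaps_parental <- NA_character_
  for (pm in parental_mirnas) {
    for (bi in seq_len(nrow(loc$blocks))) {
      b <- loc$blocks[bi, , drop = FALSE]
      if (overlap_bp(interval_of(pm), b, ignore_strand = TRUE) > 0) {
        overlaps_parental <- pm$id
      }
    }
  }
  if (!is.na(overlaps_parental) && mm <= 1) {
    return(evidence("R", mm, loc, parental_mirna = overlaps_parental))
  }
  # (3) de novo: mutated mature and no parental stem-loop
  mrna <- splice(genome, parental_tx)
  span <- loc$mrna_span
  pad <- max(0, (nchar(pre_seq) - (span[2] - span[1])) %/% 2)
  ps <- max(0L, span[1] - pad); pe <- min(nchar(mrna), span[2] + pad)
  parent_region <- substring(mrna, ps + 1L, pe)
  parental_hp <- suppressWarnings(assess_hairpin(parent_region)$is_hairpin)
  if (mm >= 2 && !parental_hp) {
    return(evidence("N", mm, loc, parental_hairpin = parental_hp))
  }
  evidence("unclassified", mm, loc, parental_hairpin = parental_hp,
           parental_mirna = overlaps_parental)
}

#' Classify every confirmed retro-miR
#'
#' @param confirmed Confirmed-candidate data frame from
#'   [discover_retromirs()].
#' @param mirnas,retrocopies,transcripts,parental_mirnas,genome Pipeline
#'   objects.
#' @param min_intron Passed to [classify_retromir()].
#' @return Data frame of class `retromir_calls` (one row per candidate).
#' @export
classify_all <- function(confirmed, mirnas, retrocopies, transcripts,
                         parental_mirnas, genome, min_intron = 30) {
  rows <- lapply(seq_len(nrow(confirmed)), function(i) {
    cand <- confirmed[i, ]
    mr <- mirnas[[cand$mirna_id]]
    rc <- retrocopies[[cand$retrocopy_id]]
    tx <- transcripts[[rc$parental_transcript_id]]
    classify_retromir(cand, mr, rc, tx, parental_mirnas, genome,
                      min_intron = min_intron)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), retrocopy_id = character(0),
               class = character(0), stringsAsFactors = FALSE)
  class(out) <- c("retromir_calls", class(out))
  out
}

#' @export
print.retromir_calls <- function(x, ...) {
  cat(sprintf("retro-miR calls: %d candidates\n", nrow(x)))
  print(table(x$class))
  NextMethod()
}
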