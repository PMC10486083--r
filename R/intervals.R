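#' Genomic interval constructor
#'
#' Intervals are held as data frames with columns `chrom`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates throughout the package.
#' GTF/GFF input (1-based inclusive) is converted at the I/O boundary.
#'
#' @param chrom Chromosome/contig identifier (character).
#' @param start 0-based inclusive start (integer, >= 0).
#' @param end 0-based exclusive end (integer, > start).
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A data frame with one row per interval.
#' @export
gi <- function(chrom, start, end, strand = ".") {
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (any(x$start < 0)) stop("negative interval start")
  if (any(x$start >= x$end)) stop("empty or inverted interval (start >= end)")
  if (!all(x$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  invisible(x)
}

#' Overlap between two genomic intervals in base pairs
#'
#' Returns 0 for intervals on different chromosomes. By default the overlap
#' is strand-aware: intervals on opposite explicit strands do not overlap;
#' a `"."` strand on either side matches any strand.
#'
#' @param a,b Single-row interval data frames (see [gi()]).
#' @param ignore_strand If `TRUE`, strands are not compared.
#' @return Integer overlap in bp (>= 0).
#' @export
overlap_bp <- function(a, b, ignore_strand = FALSE) {
  if (a$chrom != b$chrom) return(0L)
  if (!ignore_strand && a$strand != "." && b$strand != "." &&
      a$strand != b$strand) {
    return(0L)
  }
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

#' Transcript model constructor
#'
#' @param id Transcript identifier.
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"` (explicit strand required).
#' @param exons Data frame with `start`, `end` (0-based half-open), given in
#'   transcription order (genomically descending starts on the minus strand).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) stop("transcript strand must be + or -")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$start < 0) || any(exons$start >= exons$end)) {
    stop("invalid exon coordinates in transcript ", id)
  }
  g <- exons[order(exons$start), , drop = FALSE]
  if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
    stop("overlapping exons in transcript ", id)
  }
  # enforce transcription order internally
  exons <- if (strand == "+") g else g[rev(seq_len(nrow(g))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons$start), end = max(exons$end),
                 exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d(%s), %d exon(s), spliced %d nt>\n",
              x$id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), spliced_length(x)))
  invisible(x)
}

spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcription order; on the minus strand
#' the result is the reverse complement of the genomic exon sequence.
#'
#' @param genome Named character vector of contig sequences.
#' @param tx A [transcript_model()].
#' @return The mRNA sequence (character scalar, DNA alphabet).
#' @export
splice <- function(genome, tx) {
  if (!tx$chrom %in% names(genome)) stop("chromosome ", tx$chrom, " not in genome")
  chrom_seq <- genome[[tx$chrom]]
  if (tx$end > nchar(chrom_seq)) stop("exon beyond chromosome end in ", tx$id)
  parts <- substring(chrom_seq, tx$exons$start + 1L, tx$exons$end)
  if (tx$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste0(parts, collapse = "")
}

#' Project a spliced-mRNA span back onto the genome
#'
#' Maps a 0-based half-open span on the spliced transcript to the genomic
#' exon blocks it covers. More than one block is returned exactly when the
#' span crosses at least one exon-exon junction.
#'
#' @param tx A [transcript_model()].
#' @param mrna_start,mrna_end 0-based half-open span on the spliced mRNA.
#' @return Interval data frame (blocks in genomic order).
#' @export
project_to_genome <- function(tx, mrna_start, mrna_end) {
  L <- spliced_length(tx)
  if (mrna_start < 0 || mrna_end > L || mrna_start >= mrna_end) {
    stop("span [", mrna_start, ",", mrna_end, ") outside transcript of spliced length ", L)
  }
  lens <- tx$exons$end - tx$exons$start
  offs <- cumsum(c(0L, lens))[seq_along(lens)]  # spliced offset of each exon
  blocks <- list()
  for (i in seq_along(lens)) {
    s <- max(mrna_start, offs[i]); e <- min(mrna_end, offs[i] + lens[i])
    if (s >= e) next
    within_s <- s - offs[i]; within_e <- e - offs[i]
    if (tx$strand == "+") {
      gs <- tx$exons$start[i] + within_s; ge <- tx$exons$start[i] + within_e
    } else {
      gs <- tx$exons$end[i] - within_e; ge <- tx$exons$end[i] - within_s
    }
    blocks[[length(blocks) + 1L]] <- gi(tx$chrom, gs, ge, tx$strand)
  }
  out <- do.call(rbind, blocks)
  out[order(out$start), , drop = FALSE]
}

#' Reverse complement of a nucleotide string
#'
#' Accepts DNA or RNA; output alphabet is DNA unless the input contains U,
#' in which case U-pairing is preserved as A and complements are reported in
#' the input's case.
#'
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTUacgtuNn", "TGCAAtgcaaNn", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' miRNA record constructor
#'
#' @param id Precursor identifier.
#' @param chrom,start,end,strand Precursor locus (explicit strand required).
#' @param matures Data frame with `id`, `start`, `end`, `sequence` (RNA
#'   alphabet, 18-26 nt, each mature within the precursor).
#' @param host_context One of `"exonic"`, `"intronic"`, `"intergenic"`.
#' @return An object of class `mirna_record`.
#' @export
mirna_record <- function(id, chrom, start, end, strand,
                         matures, host_context = "intergenic") {
  if (!strand %in% c("+", "-")) stop("miRNA strand must be + or -")
  stopifnot(host_context %in% c("exonic", "intronic", "intergenic"))
  validate_intervals(gi(chrom, start, end, strand))
  matures <- as.data.frame(matures, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(matures))) {
    m <- matures[i, ]
    if (m$start < start || m$end > end) stop("mature ", m$id, " outside precursor ", id)
    len <- m$end - m$start
    if (len < 18 || len > 26) stop("mature ", m$id, " length ", len, " outside [18,26]")
    if (!is.na(m$sequence)) {
      if (nchar(m$sequence) != len) stop("mature ", m$id, " sequence length mismatch")
      if (grepl("[^ACGU]", m$sequence)) stop("mature ", m$id, " sequence must be RNA (ACGU)")
    }
  }
  structure(list(id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 matures = matures, host_context = host_context),
            class = "mirna_record")
}

#' Retrocopy record constructor
#'
#' @param id Retrocopy identifier.
#' @param chrom,start,end,strand Insertion locus.
#' @param parental_gene_id,parental_transcript_id Link to the source gene.
#' @param sequence Genomic sequence of the locus (length must equal end-start).
#' @return An object of class `retrocopy_record`.
#' @export
retrocopy_record <- function(id, chrom, start, end, strand,
                             parental_gene_id, parental_transcript_id,
                             sequence) {
  validate_intervals(gi(chrom, start, end, strand))
  if (nchar(sequence) != end - start) {
    stop("retrocopy ", id, " sequence length != end - start")
  }
  structure(list(id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 parental_gene_id = parental_gene_id,
                 parental_transcript_id = parental_transcript_id,
                 sequence = sequence),
            class = "retrocopy_record")
}

interval_of <- function(x) {
  gi(x$chrom, x$start, x$end, x$strand)
}
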