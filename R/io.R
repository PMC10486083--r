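#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

# Light line-level validation so malformed files are rejected with the
# offending 1-based line number before the real parser sees them.
check_coordinate_file <- function(path, coord_cols, min_fields,
                                  comment = "#", sep = "\t",
                                  require_start_lt_end = TRUE,
                                  one_based = FALSE) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, comment)) next
    f <- strsplit(ln, sep, fixed = TRUE)[[1]]
    if (length(f) < min_fields) {
      stop(sprintf("%s line %d: expected >= %d fields, got %d",
                   path, i, min_fields, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[coord_cols[1]]))
    e <- suppressWarnings(as.numeric(f[coord_cols[2]]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    }
    if (s < 0 || e < 0) stop(sprintf("%s line %d: negative coordinate", path, i))
    lo <- if (one_based) s - 1 else s
    if (require_start_lt_end && lo >= e) {
      stop(sprintf("%s line %d: empty interval (start %s, end %s)",
                   path, i, f[coord_cols[1]], f[coord_cols[2]]))
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector.
#' @param path File path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  x <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' GTF 1-based inclusive coordinates are converted to the package-internal
#' 0-based half-open convention.
#'
#' @param path File path.
#' @return Named list of [transcript_model()] objects.
#' @export
read_gtf <- function(path) {
  check_coordinate_file(path, coord_cols = c(4, 5), min_fields = 9,
                        one_based = TRUE, require_start_lt_end = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  txs <- split(seq_along(ex), as.character(ex$transcript_id))
  out <- lapply(names(txs), function(tid) {
    idx <- txs[[tid]]
    e <- ex[idx]
    transcript_model(
      id = tid, gene_id = as.character(e$gene_id[1]),
      chrom = as.character(GenomicRanges::seqnames(e))[1],
      strand = as.character(GenomicRanges::strand(e))[1],
      exons = data.frame(start = GenomicRanges::start(e) - 1L,
                         end = GenomicRanges::end(e)))
  })
  names(out) <- names(txs)
  out[order(names(out))]
}

#' Write transcript models to a GTF file
#'
#' @param txs List of [transcript_model()] objects.
#' @param path File path.
#' @export
write_gtf <- function(txs, path) {
  rows <- lapply(txs, function(tx) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    n <- nrow(ex)
    GenomicRanges::GRanges(
      seqnames = tx$chrom,
      ranges = IRanges::IRanges(start = c(tx$start, ex$start) + 1L,
                                end = c(tx$end, ex$end)),
      strand = tx$strand,
      type = c("transcript", rep("exon", n)),
      source = "retromir",
      gene_id = tx$gene_id,
      transcript_id = tx$id)
  })
  # records may sit on different contigs; merging seqlevels is expected
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read miRNA precursor and mature annotation from GFF3
#'
#' Expects the miRBase dialect: `miRNA_primary_transcript` features with an
#' `ID` attribute and `miRNA` features carrying `Derives_from`. Mature
#' sequences are extracted from `genome` when provided (strand-aware,
#' reported in the RNA alphabet).
#'
#' @param path File path.
#' @param genome Optional named character vector of contig sequences.
#' @return Named list of [mirna_record()] objects.
#' @export
read_mirna_gff3 <- function(path, genome = NULL) {
  check_coordinate_file(path, coord_cols = c(4, 5), min_fields = 9,
                        one_based = TRUE, require_start_lt_end = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  pre <- gr[gr$type == "miRNA_primary_transcript"]
  mat <- gr[gr$type == "miRNA"]
  out <- lapply(seq_along(pre), function(i) {
    p <- pre[i]
    pid <- as.character(p$ID)
    m <- mat[as.character(mat$Derives_from) == pid]
    strand <- as.character(GenomicRanges::strand(p))
    chrom <- as.character(GenomicRanges::seqnames(p))
    mdf <- data.frame(
      id = as.character(m$ID),
      start = GenomicRanges::start(m) - 1L,
      end = GenomicRanges::end(m),
      sequence = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(genome)) {
      mdf$sequence <- vapply(seq_len(nrow(mdf)), function(j) {
        s <- substring(genome[[chrom]], mdf$start[j] + 1L, mdf$end[j])
        if (strand == "-") s <- revcomp(s)
        chartr("T", "U", s)
      }, character(1))
    }
    hc <- if (!is.null(p$host_context) && !is.na(p$host_context)) {
      as.character(p$host_context)
    } else "intergenic"
    mirna_record(pid, chrom, GenomicRanges::start(p) - 1L,
                 GenomicRanges::end(p), strand, mdf, hc)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out[order(names(out))]
}

#' Write miRNA records to GFF3 (miRBase dialect)
#'
#' @param mirnas List of [mirna_record()] objects.
#' @param path File path.
#' @export
write_mirna_gff3 <- function(mirnas, path) {
  rows <- lapply(mirnas, function(mr) {
    n <- nrow(mr$matures)
    GenomicRanges::GRanges(
      seqnames = mr$chrom,
      ranges = IRanges::IRanges(
        start = c(mr$start, mr$matures$start) + 1L,
        end = c(mr$end, mr$matures$end)),
      strand = mr$strand,
      type = c("miRNA_primary_transcript", rep("miRNA", n)),
      source = "retromir",
      ID = c(mr$id, mr$matures$id),
      Derives_from = c(NA_character_, rep(mr$id, n)),
      host_context = c(mr$host_context, rep(NA_character_, n)))
  })
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BED6 file
#'
#' BED coordinates are already 0-based half-open and are kept as such.
#' Zero-length records (start == end) are rejected.
#'
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  check_coordinate_file(path, coord_cols = c(2, 3), min_fields = 3,
                        one_based = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score) && !all(is.na(gr$score))) {
      as.numeric(gr$score)
    } else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write a BED6 file
#'
#' @param df Data frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @param path File path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(within(df, strand <- if ("strand" %in% names(df)) strand else "."))
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  strand[strand == "."] <- "."
  out <- data.frame(df$chrom, df$start, df$end, name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write plain TSV tables with a header row
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param df Data frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path File path.
#' @return Named list of character vectors (set id -> genes); set
#'   descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("%s line %d: GMT needs >= 3 fields", path, i))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
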