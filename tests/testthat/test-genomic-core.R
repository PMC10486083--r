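test_that("interval overlap follows half-open, strand-aware semantics", {
  expect_equal(overlap_bp(gi("chr1", 0, 100, "+"), gi("chr1", 100, 200, "+")), 0L)
  expect_equal(overlap_bp(gi("chr1", 50, 150, "+"), gi("chr1", 100, 200, "+")), 50L)
  expect_equal(overlap_bp(gi("chr1", 1000, 1080, "+"), gi("chr2", 1000, 1080, "+")), 0L)
  # strand rules: opposite explicit strands never overlap; '.' matches any
  expect_equal(overlap_bp(gi("chr1", 0, 50, "+"), gi("chr1", 0, 50, "-")), 0L)
  expect_equal(overlap_bp(gi("chr1", 0, 50, "+"), gi("chr1", 0, 50, "-"),
                          ignore_strand = TRUE), 50L)
  expect_equal(overlap_bp(gi("chr1", 0, 50, "."), gi("chr1", 20, 50, "-")), 30L)
})

test_that("overlap is symmetric and bounded by the shorter interval", {
  set.seed(1)
  for (i in 1:200) {
    a <- sort(sample(0:500, 2)); b <- sort(sample(0:500, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    ia <- gi("chr1", a[1], a[2], "+"); ib <- gi("chr1", b[1], b[2], "+")
    ov <- overlap_bp(ia, ib)
    expect_identical(ov, overlap_bp(ib, ia))
    expect_lte(ov, min(a[2] - a[1], b[2] - b[1]))
    expect_gte(ov, 0)
  }
})

test_that("splice concatenates exons in transcription order", {
  genome <- c(chrA = "AAACCCGGG")
  tx_plus <- transcript_model("t1", "g1", "chrA", "+",
                              data.frame(start = c(0, 6), end = c(3, 9)))
  expect_equal(splice(genome, tx_plus), "AAAGGG")
  tx_minus <- transcript_model("t2", "g1", "chrA", "-",
                               data.frame(start = c(0, 6), end = c(3, 9)))
  expect_equal(splice(genome, tx_minus), "CCCTTT")
  tx_one <- transcript_model("t3", "g1", "chrA", "+",
                             data.frame(start = 0, end = 9))
  expect_equal(splice(genome, tx_one), "AAACCCGGG")
})

test_that("project_to_genome splits spans at exon junctions", {
  tx <- transcript_model("t1", "g1", "chrA", "+",
                         data.frame(start = c(0, 6), end = c(3, 9)))
  one <- project_to_genome(tx, 0, 3)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 3))
  two <- project_to_genome(tx, 2, 5)
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(2, 6))
  expect_equal(two$end, c(3, 8))
  expect_error(project_to_genome(tx, 3, 3), "span")
})

test_that("projecting the full spliced span recovers the exact exons", {
  set.seed(42)
  for (rep in 1:20) {
    n_ex <- sample(2:5, 1)
    starts <- cumsum(sample(5:30, n_ex * 2))
    exons <- data.frame(start = starts[seq(1, 2 * n_ex, 2)],
                        end = starts[seq(2, 2 * n_ex, 2)])
    strand <- sample(c("+", "-"), 1)
    tx <- transcript_model(paste0("t", rep), "g", "chrA", strand, exons)
    L <- sum(exons$end - exons$start)
    blocks <- project_to_genome(tx, 0, L)
    genomic <- tx$exons[order(tx$exons$start), ]
    expect_equal(blocks$start, genomic$start)
    expect_equal(blocks$end, genomic$end)
  }
})

test_that("FASTA, GTF, miRNA GFF3, BED, TSV and GMT round-trip losslessly", {
  tmp <- withr::local_tempdir()
  seqs <- c(chr1 = rand_dna_str(150), chr2 = rand_dna_str(61))
  fa <- file.path(tmp, "x.fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)

  txs <- list(
    TXA = transcript_model("TXA", "GA", "chr1", "+",
                           data.frame(start = c(0, 50), end = c(20, 90))),
    TXB = transcript_model("TXB", "GB", "chr1", "-",
                           data.frame(start = c(10, 60), end = c(30, 100))),
    TXC = transcript_model("TXC", "GC", "chr2", "+",
                           data.frame(start = 5, end = 55)))
  gtf <- file.path(tmp, "x.gtf")
  write_gtf(txs, gtf)
  back <- read_gtf(gtf)
  expect_identical(names(back), names(txs))
  for (id in names(txs)) {
    expect_equal(back[[id]]$exons, txs[[id]]$exons)
    expect_identical(back[[id]]$strand, txs[[id]]$strand)
    expect_identical(back[[id]]$gene_id, txs[[id]]$gene_id)
  }

  mr <- mirna_record("mir-x", "chr1", 100, 156, "-",
                     data.frame(id = "mir-x-5p", start = 101, end = 123,
                                sequence = substr(strrep("ACGU", 6), 1, 22),
                                stringsAsFactors = FALSE), "exonic")
  gff <- file.path(tmp, "x.gff3")
  write_mirna_gff3(list(mr), gff)
  back <- read_mirna_gff3(gff)
  expect_equal(back[["mir-x"]]$start, 100L)
  expect_equal(back[["mir-x"]]$end, 156L)
  expect_identical(back[["mir-x"]]$strand, "-")
  expect_equal(back[["mir-x"]]$matures$start, 101L)
  expect_identical(back[["mir-x"]]$host_context, "exonic")

  bed <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(5L, 30L),
                    name = c("a", "b"), score = c(0, 1),
                    strand = c("+", "."), stringsAsFactors = FALSE)
  bp <- file.path(tmp, "x.bed")
  write_bed(bed, bp)
  back <- read_bed(bp)
  expect_equal(back$start, bed$start)
  expect_equal(back$end, bed$end)
  expect_equal(back$name, bed$name)

  df <- data.frame(a = 1:3, b = c("x", "y", "z"), stringsAsFactors = FALSE)
  tp <- file.path(tmp, "x.tsv")
  write_tsv(df, tp)
  expect_equal(read_tsv(tp), df)

  sets <- list(S1 = c("g1", "g2"), S2 = c("g2", "g3", "g4"))
  attr(sets, "description") <- c(S1 = "one", S2 = "two")
  gp <- file.path(tmp, "x.gmt")
  write_gmt(sets, gp)
  back <- read_gmt(gp)
  expect_identical(back$S1, sets$S1)
  expect_identical(back$S2, sets$S2)
})

test_that("malformed coordinate files are rejected with a 1-based line number", {
  tmp <- withr::local_tempdir()
  bad_bed <- file.path(tmp, "bad.bed")
  writeLines(c("chr1\t0\t10\tok\t0\t+", "chr1\t5\t5\tempty\t0\t+"), bad_bed)
  expect_error(read_bed(bad_bed), "line 2")
  neg <- file.path(tmp, "neg.bed")
  writeLines("chr1\t-5\t10\tx\t0\t+", neg)
  expect_error(read_bed(neg), "negative")
  short <- file.path(tmp, "short.gtf")
  writeLines("chr1\tsrc\texon\t1", short)
  expect_error(read_gtf(short), "line 1")
})

test_that("GFF/GTF 1-based input becomes internal 0-based half-open", {
  tmp <- withr::local_tempdir()
  gtf <- file.path(tmp, "one.gtf")
  writeLines(paste0("chr1\tsim\texon\t1\t10\t.\t+\t.\t",
                    'gene_id "G"; transcript_id "T";'), gtf)
  tx <- read_gtf(gtf)[["T"]]
  expect_equal(tx$exons$start, 0L)
  expect_equal(tx$exons$end, 10L)
})

test_that("interval and record constructors enforce their invariants", {
  expect_error(gi("chr1", -1, 10), "negative")
  expect_error(gi("chr1", 10, 10), "empty")
  expect_error(gi("chr1", 0, 10, "x"), "strand")
  expect_error(transcript_model("t", "g", "c", ".",
                                data.frame(start = 0, end = 10)), "strand")
  expect_error(transcript_model("t", "g", "c", "+",
                                data.frame(start = c(0, 5), end = c(10, 15))),
               "overlap")
  expect_error(mirna_record("m", "c", 0, 56, "+",
                            data.frame(id = "m5", start = 0, end = 10,
                                       sequence = "ACGUACGUAC")),
               "length")
  expect_error(retrocopy_record("r", "c", 0, 10, "+", "g", "t", "ACGT"),
               "length")
})

test_that("reverse complement handles DNA and RNA alphabets", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAACCC"), "GGGTTT")
  expect_equal(revcomp("ACGU"), "ACGT")
})
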