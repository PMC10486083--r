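mk_mirna <- function(id, chrom, start, end, strand = "+") {
  mirna_record(id, chrom, start, end, strand,
               data.frame(id = paste0(id, "-5p"), start = start + 1,
                          end = start + 23,
                          sequence = substr(strrep("ACGU", 6), 1, 22),
                          stringsAsFactors = FALSE))
}

mk_rc <- function(id, chrom, start, end, strand = "+") {
  retrocopy_record(id, chrom, start, end, strand, "G", "T",
                   strrep("A", end - start))
}

test_that("the 5-bp overlap threshold is an inclusive boundary", {
  m5 <- mk_mirna("m", "chr1", 1000, 1080)
  kept <- find_candidates(list(m5), list(mk_rc("r", "chr1", 1075, 2000)))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$overlap_bp, 5L)
  dropped <- find_candidates(list(m5), list(mk_rc("r", "chr1", 1076, 2000)))
  expect_equal(nrow(dropped), 0)
  inside <- find_candidates(list(m5), list(mk_rc("r", "chr1", 900, 2000)))
  expect_equal(inside$overlap_bp, 80L)
  expect_equal(nrow(find_candidates(list(), list())), 0)
})

test_that("candidate finding equals a brute-force all-pairs scan", {
  set.seed(13)
  chroms <- c("chr1", "chr2")
  mirnas <- lapply(1:40, function(i) {
    st <- sample(0:5000, 1)
    mk_mirna(sprintf("m%02d", i), sample(chroms, 1), st, st + 80,
             sample(c("+", "-"), 1))
  })
  rcs <- lapply(1:25, function(i) {
    st <- sample(0:5000, 1)
    mk_rc(sprintf("r%02d", i), sample(chroms, 1), st, st + sample(200:800, 1),
          sample(c("+", "-"), 1))
  })
  got <- find_candidates(mirnas, rcs, min_overlap = 5)
  brute <- 0L
  for (m in mirnas) for (r in rcs) {
    if (m$chrom != r$chrom || m$strand != r$strand) next
    ov <- max(0, min(m$end, r$end) - max(m$start, r$start))
    if (ov >= 5) brute <- brute + 1L
  }
  expect_equal(nrow(got), brute)
  # deterministic ordering
  again <- find_candidates(mirnas, rcs, min_overlap = 5)
  expect_identical(got, again)
})

test_that("repeat flagging uses the >= 50% precursor-coverage rule", {
  cand <- find_candidates(list(mk_mirna("m", "chr1", 100, 180)),
                          list(mk_rc("r", "chr1", 0, 1000)))
  reps <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    name = "rep", score = 0, strand = ".",
                                    stringsAsFactors = FALSE)
  flagged <- exclude_repeats(cand, reps(100, 160))   # 60/80 = 0.75
  expect_equal(nrow(flagged$review), 1)
  clean <- exclude_repeats(cand, reps(500, 600))     # no overlap
  expect_equal(nrow(clean$review), 0)
  boundary <- exclude_repeats(cand, reps(100, 140))  # exactly 40/80
  expect_equal(nrow(boundary$review), 1)
  # flagged candidates are partitioned, not deleted
  expect_equal(nrow(flagged$kept) + nrow(flagged$review), nrow(cand))
})

test_that("hairpin confirmation separates planted hairpins from poly-A", {
  set.seed(4)
  arm <- rand_dna_str(24)
  hp <- paste0(arm, rand_dna_str(8), revcomp(arm))
  genome <- c(chr1 = paste0(strrep("A", 100), hp, strrep("A", 100)))
  cand <- rbind(
    find_candidates(list(mk_mirna("planted", "chr1", 100, 156)),
                    list(mk_rc("r", "chr1", 0, 256))),
    find_candidates(list(mk_mirna("polya", "chr1", 10, 90)),
                    list(mk_rc("r", "chr1", 0, 256))))
  conf <- suppressWarnings(confirm_hairpin(cand, genome))
  expect_true(conf$hairpin_ok[conf$mirna_id == "planted"])
  expect_false(conf$hairpin_ok[conf$mirna_id == "polya"])
})

test_that("discovery recovers all planted retro-miRs and flags the decoy", {
  sim <- small_sim()
  mirnas <- c(sim$parental_mirnas, sim$retro_mirnas)
  disc <- discover_retromirs(mirnas, sim$retrocopies, sim$genome,
                             repeats = sim$repeats)
  planted <- sim$ledger$retromir_id[sim$ledger$class %in% c("R", "EJ", "N")]
  expect_setequal(disc$retro_mirs$mirna_id, planted)
  expect_identical(disc$review$mirna_id, "mir-DECOY")
})

test_that("no planted events means no candidates", {
  cfg <- sim_config(seed = 10, n_genes = 3, plant = c(R = 0, EJ = 0, N = 0),
                    plant_repeat_decoy = FALSE)
  g <- simulate_genome(cfg)
  res <- simulate_retrotransposition(g$genome, g$transcripts[[1]], cfg,
                                     retro_id = "RC1")
  cand <- find_candidates(list(), list(res$retrocopy))
  expect_equal(nrow(cand), 0)
})

test_that("translated duplication screen calls exact copies but not self", {
  set.seed(19)
  cfg <- sim_config(seed = 19, n_genes = 1, plant = c(R = 0, EJ = 0, N = 0),
                    plant_repeat_decoy = FALSE)
  g <- simulate_genome(cfg)
  tx <- g$transcripts[[1]]
  # plant an exact copy of the coding unit (the spliced mRNA) elsewhere
  gene_seq <- splice(g$genome, tx)
  genome <- c(chr1 = paste0(g$genome[["chr1"]], rand_dna_str(300), gene_seq))
  calls <- find_dna_duplications(list(tx), genome, ratio_min = 0.7,
                                 window = 1500, step = 700)
  expect_gt(nrow(calls), 0)
  expect_true(any(calls$score_ratio >= 0.99))
  # every call lies outside the gene's own locus
  own <- interval_of(tx)
  for (i in seq_len(nrow(calls))) {
    hit <- gi(calls$chrom[i], calls$start[i], calls$end[i], ".")
    expect_equal(overlap_bp(hit, own, ignore_strand = TRUE), 0)
  }
  # a genome without the copy yields no calls
  none <- find_dna_duplications(list(tx), g$genome, ratio_min = 0.7,
                                window = 1500, step = 700)
  expect_equal(nrow(none), 0)
})

test_that("protein self-alignment ratio is exactly one", {
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  self <- align_protein_local(prot, prot)
  expect_equal(self$score / self$score, 1.0)
  expect_equal(self$identities, nchar(prot))
})
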