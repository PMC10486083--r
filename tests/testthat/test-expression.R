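test_that("TPM and RPM normalization match hand arithmetic", {
  counts <- matrix(c(10, 90), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  lens <- c(a = 100, b = 100)
  tpm <- normalize_expression(counts, lens, "TPM")
  expect_equal(unname(tpm[, 1]), c(1e5, 9e5))
  counts2 <- matrix(c(50, 50), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  tpm2 <- normalize_expression(counts2, c(a = 100, b = 200), "TPM")
  expect_equal(unname(tpm2[, 1]), c(666666.67, 333333.33), tolerance = 1e-6)
  rpm <- normalize_expression(counts, mode = "RPM")
  expect_equal(unname(rpm[, 1]), c(1e5, 9e5))
})

test_that("TPM columns always sum to one million", {
  set.seed(51)
  counts <- matrix(rpois(60, 100), nrow = 10,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  lens <- stats::setNames(sample(50:500, 10), paste0("f", 1:10))
  tpm <- normalize_expression(counts, lens, "TPM")
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)
})

test_that("zero-depth samples come back all-zero with a warning", {
  counts <- matrix(c(5, 5, 0, 0), nrow = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(out <- normalize_expression(counts, mode = "RPM"),
                 "zero-depth")
  expect_equal(unname(out[, "s2"]), c(0, 0))
})

test_that("breadth counts tissues with positive median", {
  mat <- rbind(
    one = c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0),
    zero = rep(0, 10),
    medzero = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 4))
  tissue <- rep(paste0("t", 1:5), each = 2)
  s <- summarize_expression(mat, tissue)
  expect_equal(unname(s$breadth["one"]), 1)
  expect_equal(unname(s$breadth["zero"]), 0)
  # median of {0, 4} = 2 > 0 counts; median of {0, 0} does not -
  # check the boundary case median {0,0,4} = 0 explicitly
  m3 <- matrix(c(0, 0, 4), nrow = 1, dimnames = list("f", NULL))
  s3 <- summarize_expression(m3, rep("t1", 3))
  expect_equal(unname(s3$breadth), 0)
})

test_that("significance stars follow the figure-legend bands", {
  expect_identical(p_stars(c(0.03, 0.005, 1e-5, 0.2, 0.05, 0.01, 1e-4)),
                   c("*", "**", "***", "", "*", "*", "**"))
})

test_that("the rank-sum U statistic equals brute-force pair counting", {
  set.seed(53)
  for (i in 1:30) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(1:50, n1); y <- sample(1:50, n2)
    vals <- c(x, y)
    cond <- c(rep("tumor", n1), rep("normal", n2))
    got <- tumor_vs_normal(vals, cond)
    expect_equal(unname(got$U), brute_U(x, y))
  }
})

test_that("identical groups are not significant", {
  vals <- c(1, 2, 3, 4, 1, 2, 3, 4)
  cond <- rep(c("tumor", "normal"), each = 4)
  got <- tumor_vs_normal(vals, cond)
  expect_equal(got$p, 1)
  expect_identical(got$stars, "")
})

test_that("planted tumor overexpression is detected in the right direction", {
  sim <- small_sim()
  e <- sim$expression
  tpm <- normalize_expression(e$counts, e$lengths, "TPM")
  cohort <- e$meta$tissue == "cohort"
  tt <- tumor_vs_normal_all(tpm[, cohort, drop = FALSE],
                            e$meta$condition[cohort])
  truth <- e$ledger$true_fold[match(tt$feature, e$ledger$feature)]
  expect_true(all(tt$p[truth > 1] < 0.05))
  # planted features shift upward in tumors: U above its null midpoint
  n1 <- sum(e$meta$condition[cohort] == "tumor")
  n2 <- sum(e$meta$condition[cohort] == "normal")
  expect_true(all(tt$U[truth > 1] > n1 * n2 / 2))
})

test_that("with no planted fold the tumor test rejects at the nominal rate", {
  # fold = 1 everywhere: TPM has no compositional shift and p-values
  # are calibrated
  cfg <- sim_config(seed = 2, expr = list(
    n_tissues = 2, n_per_tissue = 2, n_tumor = 15, n_normal = 15,
    baseline_mu = 200, fold = 1, dispersion = 0.3, n_background = 0))
  set.seed(91)
  rej <- 0L; n_rep <- 200L
  for (r in seq_len(n_rep)) {
    e <- simulate_expression(sprintf("f%d", 1:2), character(0), cfg)
    tpm <- normalize_expression(e$counts, e$lengths, "TPM")
    cohort <- e$meta$tissue == "cohort"
    p <- tumor_vs_normal(tpm["f1", cohort], e$meta$condition[cohort])$p
    if (p <= 0.05) rej <- rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), 3 * se + 0.01)
})

test_that("TSS association is strand-aware, windowed, and shift-invariant", {
  tssdf <- function(pos, strand = "+") {
    data.frame(chrom = "chr1", start = pos, end = pos + 1, name = "tss",
               score = 0, strand = strand, stringsAsFactors = FALSE)
  }
  plus <- gi("chr1", 5000, 5056, "+")
  hit <- associate_tss(plus, tssdf(1500), window = 4000)
  expect_true(hit$tss_found)
  expect_equal(hit$distance, 3500)
  miss <- associate_tss(plus, tssdf(500), window = 4000)
  expect_false(miss$tss_found)
  minus <- gi("chr1", 4944, 5000, "-")
  hit2 <- associate_tss(minus, tssdf(8000, "-"), window = 4000)
  expect_true(hit2$tss_found)
  expect_equal(hit2$distance, 3000)
  # wrong strand is ignored
  expect_false(associate_tss(plus, tssdf(1500, "-"), window = 4000)$tss_found)
  # translation invariance
  shift <- 12345
  hit3 <- associate_tss(gi("chr1", 5000 + shift, 5056 + shift, "+"),
                        tssdf(1500 + shift), window = 4000)
  expect_equal(hit3$distance, 3500)
})

test_that("cCRE association uses a 20-kb window with overlap as zero", {
  ccre <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    name = "ccre", score = 0, strand = ".",
                                    stringsAsFactors = FALSE)
  locus <- gi("chr1", 50000, 51000, "+")
  near <- associate_ccre(locus, ccre(60000, 60100))
  expect_true(near$ccre_nearby)
  expect_equal(near$distance, 9000)
  far <- associate_ccre(locus, ccre(77000, 77100))
  expect_false(far$ccre_nearby)
  ov <- associate_ccre(locus, ccre(50500, 50600))
  expect_true(ov$ccre_nearby)
  expect_equal(ov$distance, 0)
})

test_that("identical mature sequences collapse into one flagged feature", {
  counts <- matrix(1:8, nrow = 4,
                   dimnames = list(c("m1", "m2", "m3", "m4"), c("s1", "s2")))
  seqs <- c(m1 = "AAGG", m2 = "AAGG", m3 = "CCUU", m4 = "GGAA")
  out <- collapse_identical_matures(counts, seqs)
  expect_equal(nrow(out$counts), 3)
  amb <- out$groups$feature[out$groups$ambiguous]
  expect_identical(amb, "m1|m2")
  expect_equal(unname(out$counts["m1|m2", ]), c(1 + 2, 5 + 6),
               ignore_attr = TRUE)
})
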