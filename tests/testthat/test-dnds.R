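test_that("synonymous and nonsynonymous sites partition every sense codon", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  expect_length(sense, 61)
  for (cod in sense) {
    sn <- codon_sites(cod)
    expect_equal(unname(sn["S"] + sn["N"]), 3, info = cod)
  }
})

test_that("TTT has exactly one third of a synonymous site", {
  expect_equal(unname(codon_sites("TTT")["S"]), 1 / 3)
})

test_that("identical sequences give zero rates and undefined omega", {
  cds <- simulate_codon_pair(30, 1, n_sub = 0, seed = 1)$cds1
  pairs <- codon_align(cds, cds)
  res <- dnds_ng86(pairs)
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_true(is.na(res$omega))
  res <- test_neutrality(res, pairs, n_boot = 50, seed = 1)
  expect_true(is.na(res$regime))
})

test_that("a single synonymous change yields dS > 0 and dN = 0", {
  base <- strrep("GGG", 29)
  cds1 <- paste0("GGG", base)
  cds2 <- paste0("GGA", base)  # GGG->GGA, both glycine
  pairs <- codon_align(cds1, cds2)
  res <- dnds_ng86(pairs)
  expect_equal(res$dN, 0)
  expect_gt(res$dS, 0)
  expect_equal(res$Sd, 1)
})

test_that("NG86 agrees with an independent pathway-enumerating oracle", {
  set.seed(41)
  for (rep in 1:60) {
    pair <- simulate_codon_pair(50, sample(c(0.2, 1, 3), 1),
                                n_sub = sample(10:60, 1))
    c1 <- substring(pair$cds1, seq(1, 148, 3), seq(3, 150, 3))
    c2 <- substring(pair$cds2, seq(1, 148, 3), seq(3, 150, 3))
    got <- dnds_ng86(data.frame(codon1 = c1, codon2 = c2))
    want <- brute_ng86(c1, c2)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$dS, want$dS, tolerance = 1e-12)
    expect_equal(got$dN, want$dN, tolerance = 1e-12)
  }
})

test_that("the estimator recovers the simulated selection regime", {
  set.seed(43)
  n_rep <- 15
  pur_ok <- 0; neu_ok <- 0
  for (r in 1:n_rep) {
    p <- simulate_codon_pair(200, 0.1, n_sub = 150)
    res <- dnds_ng86(codon_align(p$cds1, p$cds2))
    res <- test_neutrality(res, codon_align(p$cds1, p$cds2),
                           n_boot = 200, seed = r)
    if (!is.na(res$omega) && res$omega < 1 && res$regime == "purifying") {
      pur_ok <- pur_ok + 1
    }
    p <- simulate_codon_pair(200, 1, n_sub = 150)
    res <- dnds_ng86(codon_align(p$cds1, p$cds2))
    res <- test_neutrality(res, codon_align(p$cds1, p$cds2),
                           n_boot = 200, seed = 1000 + r)
    if (res$regime == "neutral/NS") neu_ok <- neu_ok + 1
  }
  expect_gte(pur_ok / n_rep, 0.9)
  expect_gte(neu_ok / n_rep, 0.9)
})

test_that("ORF finding obeys start, stop, frame, and tie rules", {
  orf <- find_longest_orf("ATGAAATAA", min_codons = 2)
  expect_identical(orf$protein, "MK")
  expect_equal(orf$start, 0)
  # two equal-length ORFs: the 5'-most wins
  two <- paste0("ATGAAATAA", "ATGCCCTAA")
  orf <- find_longest_orf(two, min_codons = 2)
  expect_equal(orf$start, 0)
  # no ATG, or all stops: NA result
  expect_true(is.na(find_longest_orf("TTTTTTTTTTTT", min_codons = 2)$frame))
  # frame-2 ORF found
  orf <- find_longest_orf(paste0("G", "ATGGGGAAATAA"), min_codons = 2)
  expect_equal(orf$frame, 2)
  expect_identical(orf$protein, "MGK")
  # min_codons filter
  expect_true(is.na(find_longest_orf("ATGAAATAA", min_codons = 20)$frame))
})

test_that("codon alignment maps amino-acid columns to source codons", {
  p <- simulate_codon_pair(25, 1, n_sub = 5, seed = 9)
  pairs <- codon_align(p$cds1, p$cds2)
  expect_equal(nrow(pairs), 25)
  expect_identical(paste(pairs$codon1, collapse = ""), p$cds1)
  # a frameshifted CDS is rejected
  expect_error(codon_align(substr(p$cds1, 1, 74), p$cds2), "multiple of 3")
  # internal stop is rejected
  bad <- paste0("ATG", "TAA", strrep("GGG", 23))
  expect_error(codon_align(bad, bad), "stop")
})

test_that("saturated inputs return NA rather than a number", {
  set.seed(45)
  # two unrelated random codon strings: typically saturated or near it
  c1 <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                       c("TAA", "TAG", "TGA")), 30, replace = TRUE)
  shift <- function(cod) chartr("ACGT", "GTAC", cod)
  c2 <- shift(c1)
  keep <- Biostrings::GENETIC_CODE[c2] != "*"
  df <- data.frame(codon1 = c1[keep], codon2 = c2[keep])
  if (nrow(df) >= 20) {
    res <- dnds_ng86(df)
    expect_true(res$saturated || res$pS > 0.5 || res$pN > 0.5)
  }
})
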