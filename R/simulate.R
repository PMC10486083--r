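DNA <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

rand_cds <- function(n_codons) {
  sc <- setdiff(sense_codons(), "ATG")
  paste0("ATG", paste(sample(sc, n_codons - 1, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# bases that can pair with `b` under WC + GU (DNA alphabet, T ~ U)
pairs_with <- function(b) {
  switch(b, A = c("T"), T = c("A", "G"), G = c("C", "T"), C = c("G"))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults define the
#' reference study conditions used by the package's own validation: 12
#' planted retro-miRs (4 per class), no background point mutations for the
#' retrocopies carrying R/EJ plants, targeted substitutions creating the N
#' plants, a five-species primate-like ortholog panel, negative-binomial
#' expression with a planted 4-fold tumor overexpression, exponential
#' survival with a log(2) hazard effect, and site-free 3'UTR backgrounds
#' with exact planted seed-site counts.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_genes Number of parental genes.
#' @param n_codons_range CDS length range (codons).
#' @param utr5_range,utr3_range UTR length ranges (nt).
#' @param exons_per_gene Range of exon counts per gene.
#' @param intron_len Range of intron lengths (nt).
#' @param intergenic_len Range of intergenic spacer lengths (nt).
#' @param point_mutation_rate Per-bp substitution probability applied to
#'   each retrocopy (0 keeps R/EJ plants exact copies).
#' @param truncation_prob Probability of a 5' truncation of a retrocopy.
#' @param plant Named integer vector: planted retro-miR counts per class
#'   (`R`, `EJ`, `N`).
#' @param plant_repeat_decoy Add one mobile-element decoy candidate that
#'   discovery must flag (logical).
#' @param stem_len,loop_len,mature_len Planted hairpin geometry (bp/nt).
#' @param n_break Substitutions used to break the parental hairpin for N
#'   plants (all placed in the mature-bearing arm).
#' @param species,divergence Ortholog panel species (ordered from closest)
#'   and per-site substitution probabilities.
#' @param expr Expression spec: `n_tissues`, `n_per_tissue`, `n_tumor`,
#'   `n_normal`, `baseline_mu`, `fold`, `dispersion`, `n_background`.
#' @param surv Survival spec: `n_patients`, `baseline_hazard`, `beta`,
#'   `censoring_rate`.
#' @param utr UTR spec: `n_utrs`, `utr_len`, `n_8mer`, `n_7mer`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 12,
                       n_codons_range = c(90, 130),
                       utr5_range = c(80, 120),
                       utr3_range = c(260, 340),
                       exons_per_gene = c(3, 5),
                       intron_len = c(80, 200),
                       intergenic_len = c(200, 400),
                       point_mutation_rate = 0,
                       truncation_prob = 0,
                       plant = c(R = 4, EJ = 4, N = 4),
                       plant_repeat_decoy = TRUE,
                       stem_len = 24, loop_len = 8, mature_len = 22,
                       n_break = 7,
                       species = c("chimpanzee", "gorilla", "orangutan",
                                   "rhesus", "marmoset"),
                       divergence = c(0.02, 0.04, 0.06, 0.08, 0.10),
                       expr = list(n_tissues = 5, n_per_tissue = 6,
                                   n_tumor = 30, n_normal = 30,
                                   baseline_mu = 200, fold = 4,
                                   dispersion = 0.3, n_background = 20),
                       surv = list(n_patients = 200, baseline_hazard = 0.001,
                                   beta = log(2), censoring_rate = 0.3),
                       utr = list(n_utrs = 50, utr_len = 500,
                                  n_8mer = 2, n_7mer = 2)) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_codons_range = n_codons_range, utr5_range = utr5_range,
              utr3_range = utr3_range, exons_per_gene = exons_per_gene,
              intron_len = intron_len, intergenic_len = intergenic_len,
              point_mutation_rate = point_mutation_rate,
              truncation_prob = truncation_prob, plant = plant,
              plant_repeat_decoy = plant_repeat_decoy,
              stem_len = stem_len, loop_len = loop_len,
              mature_len = mature_len, n_break = n_break,
              species = species, divergence = divergence,
              expr = expr, surv = surv, utr = utr)
  stopifnot(cfg$point_mutation_rate >= 0, cfg$point_mutation_rate <= 1,
            cfg$truncation_prob >= 0, cfg$truncation_prob <= 1,
            all(cfg$plant >= 0), cfg$mature_len <= cfg$stem_len,
            length(cfg$species) == length(cfg$divergence),
            all(cfg$divergence >= 0), all(cfg$divergence <= 1))
  if (sum(cfg$plant) > cfg$n_genes) {
    stop("more planted retro-miRs than genes (one plant per gene)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# A planted hairpin: 5' arm + loop + reverse-complement arm. The mature
# sits at offset 1 of the 5' arm.
make_hairpin <- function(stem_len, loop_len, mature_len) {
  arm1 <- rand_dna(stem_len)
  loop <- rand_dna(loop_len)
  seq <- paste0(arm1, loop, revcomp(arm1))
  mature_off <- 1L  # 0-based offset of the mature within the precursor
  list(seq = seq, arm1 = arm1, mature_off = mature_off,
       mature_len = mature_len, len = nchar(seq))
}

# Break the 5' arm of a hairpin at `idx` (1-based positions within the
# arm): each broken base is replaced by one that cannot pair (WC or GU)
# with its stem partner.
break_hairpin <- function(hp, idx) {
  chars <- strsplit(hp$seq, "")[[1]]
  for (i in idx) {
    partner <- revcomp(substring(hp$arm1, i, i))
    bad <- pairs_with(partner)
    choices <- setdiff(DNA, c(chars[i], bad))
    chars[i] <- sample(choices, 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a toy genome with planted parental-gene features
#'
#' Each gene is built as an mRNA (5'UTR + intact CDS + 3'UTR) that is then
#' split into exons by inserting introns. Genes destined to parent a
#' retro-miR carry, in their 3'UTR: an intact exonic hairpin (class R,
#' annotated as a parental miRNA), a hairpin straddling an exon junction
#' (class EJ, split by an intron in the genome and therefore not
#' annotated), or a pairing-broken hairpin (class N). All genes are placed
#' on the plus strand of a single contig separated by random spacers.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character), `transcripts`,
#'   `parental_mirnas`, and `plants` (per-gene planting ledger).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  classes <- c(rep("R", cfg$plant["R"]), rep("EJ", cfg$plant["EJ"]),
               rep("N", cfg$plant["N"]),
               rep("none", cfg$n_genes - sum(cfg$plant)))
  hp_len <- 2 * cfg$stem_len + cfg$loop_len
  chrom <- "chr1"
  genome_parts <- character(0)
  offset <- 0L
  transcripts <- list(); parental_mirnas <- list(); plants <- list()

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("GENE%02d", g)
    tx_id <- sprintf("TX%02d", g)
    cls <- classes[g]
    n_codons <- sample(seq(cfg$n_codons_range[1], cfg$n_codons_range[2]), 1)
    utr5 <- rand_dna(sample(seq(cfg$utr5_range[1], cfg$utr5_range[2]), 1))
    cds <- rand_cds(n_codons)
    utr3 <- rand_dna(sample(seq(cfg$utr3_range[1], cfg$utr3_range[2]), 1))
    mrna <- paste0(utr5, cds, utr3)
    utr3_start <- nchar(utr5) + nchar(cds)  # 0-based on the mRNA

    plant <- NULL
    if (cls != "none") {
      hp <- make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len)
      # plant the hairpin mid-3'UTR
      hp_mrna_start <- utr3_start + 30L
      planted_seq <- hp$seq
      break_idx <- integer(0)
      if (cls == "N") {
        # spread breaks across the mature-bearing arm; retried if the
        # broken arm still folds (it should not)
        for (try in 1:50) {
          break_idx <- seq(2L, by = 3L, length.out = cfg$n_break)
          broken <- break_hairpin(hp, break_idx)
          if (!assess_hairpin(broken)$is_hairpin) { planted_seq <- broken; break }
          hp <- make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len)
        }
        if (identical(planted_seq, hp$seq)) stop("could not break hairpin")
      }
      substr(mrna, hp_mrna_start + 1L, hp_mrna_start + hp_len) <- planted_seq
      plant <- list(class = cls, hairpin = hp, hp_mrna_start = hp_mrna_start,
                    break_idx = break_idx)
    }

    # exon boundaries on the mRNA (0-based junction positions)
    n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    L <- nchar(mrna)
    if (!is.null(plant) && plant$class == "EJ") {
      # one junction inside the mature region of the planted hairpin
      j_star <- plant$hp_mrna_start + plant$hairpin$mature_off + 11L
      pool <- setdiff(seq(40L, L - 40L), seq(plant$hp_mrna_start - 40L,
                                             plant$hp_mrna_start + hp_len + 40L))
      other <- sort(sample(pool, n_ex - 2))
      junctions <- sort(c(other, j_star))
      plant$junction_mrna <- j_star
    } else {
      pool <- seq(40L, L - 40L)
      if (!is.null(plant)) {
        pool <- setdiff(pool, seq(plant$hp_mrna_start - 5L,
                                  plant$hp_mrna_start + hp_len + 5L))
      }
      junctions <- sort(sample(pool, n_ex - 1))
    }
    bounds <- c(0L, junctions, L)
    exon_lens <- diff(bounds)
    intron_seqs <- vapply(seq_len(n_ex - 1), function(i) {
      rand_dna(sample(seq(cfg$intron_len[1], cfg$intron_len[2]), 1))
    }, character(1))

    gene_seq <- ""; exon_coords <- list(); pos <- 0L
    for (i in seq_len(n_ex)) {
      ex_seq <- substring(mrna, bounds[i] + 1L, bounds[i + 1])
      exon_coords[[i]] <- c(start = pos, end = pos + exon_lens[i])
      gene_seq <- paste0(gene_seq, ex_seq)
      pos <- pos + exon_lens[i]
      if (i < n_ex) {
        gene_seq <- paste0(gene_seq, intron_seqs[i])
        pos <- pos + nchar(intron_seqs[i])
      }
    }

    spacer <- rand_dna(sample(seq(cfg$intergenic_len[1],
                                  cfg$intergenic_len[2]), 1))
    gene_start <- offset + nchar(spacer)
    genome_parts <- c(genome_parts, spacer, gene_seq)
    offset <- gene_start + nchar(gene_seq)

    exons <- do.call(rbind, lapply(exon_coords, function(e) {
      data.frame(start = gene_start + e["start"], end = gene_start + e["end"])
    }))
    tx <- transcript_model(tx_id, gene_id, chrom, "+", exons)
    transcripts[[tx_id]] <- tx

    if (!is.null(plant)) {
      plant$gene_id <- gene_id; plant$tx_id <- tx_id
      plant$mrna <- mrna
      if (plant$class == "R") {
        # annotate the parental exonic miRNA at its genomic locus
        blocks <- project_to_genome(tx, plant$hp_mrna_start,
                                    plant$hp_mrna_start + hp_len)
        stopifnot(nrow(blocks) == 1)
        m0 <- plant$hp_mrna_start + plant$hairpin$mature_off
        mat_seq <- chartr("T", "U",
                          substring(mrna, m0 + 1L, m0 + cfg$mature_len))
        pid <- sprintf("mir-P%02d", g)
        parental_mirnas[[pid]] <- mirna_record(
          pid, chrom, blocks$start[1], blocks$end[1], "+",
          data.frame(id = paste0(pid, "-5p"),
                     start = blocks$start[1] + plant$hairpin$mature_off,
                     end = blocks$start[1] + plant$hairpin$mature_off +
                       cfg$mature_len,
                     sequence = mat_seq, stringsAsFactors = FALSE),
          host_context = "exonic")
        plant$parental_mirna_id <- pid
      }
      plants[[gene_id]] <- plant
    }
  }

  tail_spacer <- rand_dna(sample(seq(cfg$intergenic_len[1],
                                     cfg$intergenic_len[2]), 1))
  genome <- stats::setNames(paste(c(genome_parts, tail_spacer),
                                  collapse = ""), chrom)
  list(genome = genome, transcripts = transcripts,
       parental_mirnas = parental_mirnas, plants = plants)
}

#' Simulate one retrotransposition event
#'
#' Splices the parental transcript, applies Bernoulli point substitutions
#' (and, for class-N plants, the targeted substitutions that restore the
#' broken hairpin), optionally truncates the 5' end, and appends the copy
#' to the contig on a random strand. The planted retro-miR is annotated at
#' its genomic locus inside the copy.
#'
#' @param genome Named character vector (extended in place and returned).
#' @param tx Parental [transcript_model()].
#' @param cfg A [sim_config()].
#' @param plant Planting instructions from [simulate_genome()], or NULL
#'   for a plain retrocopy.
#' @param retro_id Identifier for the new copy.
#' @return List with the extended `genome`, the `retrocopy` record, the
#'   retro-miR `mirna` record (or NULL), and a `ledger` row.
#' @export
simulate_retrotransposition <- function(genome, tx, cfg, plant = NULL,
                                        retro_id = "RC01") {
  chrom <- tx$chrom
  mrna <- splice(genome, tx)
  L0 <- nchar(mrna)
  chars <- strsplit(mrna, "")[[1]]

  mut_pos <- integer(0)
  if (cfg$point_mutation_rate > 0) {
    hit <- which(stats::runif(L0) < cfg$point_mutation_rate)
    for (i in hit) chars[i] <- sample(setdiff(DNA, chars[i]), 1)
    mut_pos <- hit
  }
  targeted <- integer(0)
  if (!is.null(plant) && plant$class == "N") {
    # revert the parental breaks: the copy regains the intact hairpin
    orig <- strsplit(plant$hairpin$seq, "")[[1]]
    for (i in plant$break_idx) {
      p <- plant$hp_mrna_start + i  # 1-based mRNA position of arm1 base i
      chars[p] <- orig[i]
      targeted <- c(targeted, p)
    }
  }

  trunc_bp <- 0L
  if (stats::runif(1) < cfg$truncation_prob) {
    guard <- if (!is.null(plant)) plant$hp_mrna_start - 10L else L0 - 60L
    if (guard > 20L) trunc_bp <- sample.int(guard - 10L, 1)
  }
  seq_t <- paste(chars[(trunc_bp + 1L):L0], collapse = "")
  L <- nchar(seq_t)

  strand <- sample(c("+", "-"), 1)
  spacer <- rand_dna(sample(seq(cfg$intergenic_len[1],
                                cfg$intergenic_len[2]), 1))
  ins_pos <- nchar(genome[[chrom]]) + nchar(spacer)
  genomic_seq <- if (strand == "+") seq_t else revcomp(seq_t)
  genome[[chrom]] <- paste0(genome[[chrom]], spacer, genomic_seq)

  rc <- retrocopy_record(retro_id, chrom, ins_pos, ins_pos + L, strand,
                         tx$gene_id, tx$id, seq_t)

  mirna <- NULL
  mm_mature <- NA_integer_
  if (!is.null(plant)) {
    hp_len <- plant$hairpin$len
    p0 <- plant$hp_mrna_start - trunc_bp   # precursor offset on the copy
    q0 <- p0 + plant$hairpin$mature_off
    q1 <- q0 + plant$hairpin$mature_len
    to_genomic <- function(a, b) {
      if (strand == "+") c(ins_pos + a, ins_pos + b)
      else c(ins_pos + L - b, ins_pos + L - a)
    }
    pre_g <- to_genomic(p0, p0 + hp_len)
    mat_g <- to_genomic(q0, q1)
    mat_seq <- chartr("T", "U", substring(seq_t, q0 + 1L, q1))
    mid <- sub("^GENE", "mir-RM", plant$gene_id)
    mirna <- mirna_record(mid, chrom, pre_g[1], pre_g[2], strand,
                          data.frame(id = paste0(mid, "-5p"),
                                     start = mat_g[1], end = mat_g[2],
                                     sequence = mat_seq,
                                     stringsAsFactors = FALSE),
                          host_context = "exonic")
    # break_idx are 1-based positions in the 5' arm == precursor positions;
    # the mature covers precursor 1-based positions mature_off+1 .. mature_off+len
    mm_mature <- if (plant$class == "N") {
      sum(plant$break_idx >= plant$hairpin$mature_off + 1L &
            plant$break_idx <= plant$hairpin$mature_off + plant$hairpin$mature_len)
    } else {
      sum(mut_pos > plant$hp_mrna_start + plant$hairpin$mature_off &
            mut_pos <= plant$hp_mrna_start + plant$hairpin$mature_off +
              plant$hairpin$mature_len)
    }
  }

  ledger <- data.frame(
    retromir_id = if (is.null(mirna)) NA_character_ else mirna$id,
    class = if (is.null(plant)) "none" else plant$class,
    retrocopy_id = retro_id,
    parental_gene_id = tx$gene_id,
    parental_tx_id = tx$id,
    strand = strand,
    n_mutations = length(mut_pos),
    n_targeted = length(targeted),
    mature_mismatches = mm_mature,
    junction_mrna = if (!is.null(plant) && plant$class == "EJ")
      plant$junction_mrna else NA_integer_,
    truncation_bp = trunc_bp,
    stringsAsFactors = FALSE)

  list(genome = genome, retrocopy = rc, mirna = mirna, ledger = ledger)
}

#' Simulate an ortholog sequence at a given divergence
#'
#' Independent per-site substitution with probability `d`, uniform over
#' the three alternative bases; no indels.
#'
#' @param seq Source sequence (DNA).
#' @param d Per-site substitution probability in [0, 1].
#' @param seed Optional RNG seed.
#' @return The diverged sequence.
#' @export
simulate_ortholog <- function(seq, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < d)
  for (i in hit) chars[i] <- sample(setdiff(DNA, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Simulate a codon-sequence pair under a chosen dN/dS regime
#'
#' Evolves a copy of a random sense-codon sequence by repeated single-
#' nucleotide substitution: proposals creating stop codons are rejected;
#' synonymous proposals are accepted with probability min(1, 1/omega) and
#' nonsynonymous ones with probability min(1, omega), so the realized
#' nonsynonymous/synonymous rate ratio is `omega_true`.
#'
#' @param n_codons Number of codons.
#' @param omega_true Target dN/dS (>= 0).
#' @param n_sub Number of accepted substitutions (divergence control).
#' @param seed Optional RNG seed.
#' @return List with `cds1`, `cds2` (DNA strings).
#' @export
simulate_codon_pair <- function(n_codons, omega_true, n_sub = round(n_codons / 2),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  cod <- sample(sense_codons(), n_codons, replace = TRUE)
  cds1 <- paste(cod, collapse = "")
  chars <- strsplit(cds1, "")[[1]]
  acc_syn <- min(1, if (omega_true > 0) 1 / omega_true else 1)
  acc_non <- min(1, omega_true)
  done <- 0L; guard <- 0L
  while (done < n_sub) {
    guard <- guard + 1L
    if (guard > 200000L) stop("substitution sampler failed to mix")
    p <- sample.int(length(chars), 1)
    alt <- sample(setdiff(DNA, chars[p]), 1)
    ci <- (p - 1L) %/% 3L
    old_cod <- paste(chars[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    new_chars <- chars; new_chars[p] <- alt
    new_cod <- paste(new_chars[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (gc[[new_cod]] == "*") next
    syn <- gc[[new_cod]] == gc[[old_cod]]
    if (stats::runif(1) < (if (syn) acc_syn else acc_non)) {
      chars <- new_chars; done <- done + 1L
    }
  }
  list(cds1 = cds1, cds2 = paste(chars, collapse = ""))
}

#' Simulate a count matrix with planted tumor overexpression
#'
#' Negative-binomial counts over normal-tissue samples plus a
#' tumor/normal cohort; designated features get a lognormal-jittered fold
#' increase in tumor samples.
#'
#' @param feature_ids Features to simulate (retro-miR matures first).
#' @param overexpressed Character vector of features carrying the fold.
#' @param cfg A [sim_config()] (uses `cfg$expr`).
#' @param seed Optional RNG seed.
#' @return List: `counts` (features x samples), `meta` (sample, tissue,
#'   condition), `lengths` (named, nt), `ledger` (feature, true_fold).
#' @export
simulate_expression <- function(feature_ids, overexpressed, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- cfg$expr
  tissues <- sprintf("tissue%02d", seq_len(e$n_tissues))
  normal_samples <- unlist(lapply(tissues, function(t) {
    sprintf("%s_s%02d", t, seq_len(e$n_per_tissue))
  }))
  tumor_samples <- sprintf("tumor_s%02d", seq_len(e$n_tumor))
  ctrl_samples <- sprintf("healthy_s%02d", seq_len(e$n_normal))
  samples <- c(normal_samples, tumor_samples, ctrl_samples)
  meta <- data.frame(
    sample = samples,
    tissue = c(rep(tissues, each = e$n_per_tissue),
               rep("cohort", e$n_tumor + e$n_normal)),
    condition = c(rep("normal", length(normal_samples)),
                  rep("tumor", e$n_tumor), rep("normal", e$n_normal)),
    stringsAsFactors = FALSE)
  nf <- length(feature_ids)
  base_mu <- stats::rlnorm(nf, meanlog = log(e$baseline_mu), sdlog = 0.6)
  counts <- matrix(0, nrow = nf, ncol = length(samples),
                   dimnames = list(feature_ids, samples))
  size <- 1 / e$dispersion
  for (j in seq_along(samples)) {
    mu <- base_mu
    if (meta$condition[j] == "tumor") {
      idx <- feature_ids %in% overexpressed
      mu[idx] <- mu[idx] * e$fold * stats::rlnorm(sum(idx), 0, 0.1)
    }
    counts[, j] <- stats::rnbinom(nf, mu = mu, size = size)
  }
  lengths <- stats::setNames(rep(22L, nf), feature_ids)
  ledger <- data.frame(feature = feature_ids,
                       true_fold = ifelse(feature_ids %in% overexpressed,
                                          e$fold, 1),
                       stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, lengths = lengths, ledger = ledger)
}

#' Simulate a survival table tied to a miRNA score
#'
#' Event times are exponential with hazard `h0 * exp(beta * z)` where `z`
#' is the standardized log1p expression of the prognostic features;
#' censoring is independent exponential tuned to the requested rate.
#'
#' @param feature_ids All features in the table.
#' @param prognostic Features whose expression drives hazard.
#' @param cfg A [sim_config()] (uses `cfg$surv`).
#' @param seed Optional RNG seed.
#' @return List: `records` data frame (patient_id, time, event,
#'   one column per feature) and `ledger` (feature, true_beta).
#' @export
simulate_survival <- function(feature_ids, prognostic, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$surv
  n <- s$n_patients
  expr <- matrix(stats::rlnorm(n * length(feature_ids),
                               meanlog = log(50), sdlog = 0.8),
                 nrow = n, dimnames = list(NULL, feature_ids))
  z <- scale(log1p(expr))
  lin <- if (length(prognostic)) {
    rowSums(z[, prognostic, drop = FALSE]) * s$beta
  } else rep(0, n)
  haz <- s$baseline_hazard * exp(lin)
  t_event <- stats::rexp(n, rate = haz)
  cens_rate <- s$baseline_hazard * s$censoring_rate /
    max(1 - s$censoring_rate, 1e-9)
  t_cens <- stats::rexp(n, rate = cens_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  records <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        time = time, event = event, expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  ledger <- data.frame(feature = feature_ids,
                       true_beta = ifelse(feature_ids %in% prognostic,
                                          s$beta, 0),
                       stringsAsFactors = FALSE)
  list(records = records, ledger = ledger)
}

#' Simulate 3'UTRs with planted seed sites on a site-free background
#'
#' Backgrounds are rejection-sampled so that no UTR contains an accidental
#' seed match for any of the given miRNAs; planted 8mer-1a and 7mer-m8
#' sites are then written at recorded positions, so scanned counts equal
#' the ledger exactly.
#'
#' @param matures Named character vector of mature miRNA sequences (RNA).
#' @param cfg A [sim_config()] (uses `cfg$utr`).
#' @param seed Optional RNG seed.
#' @param max_attempts Rejection-sampling cap per UTR.
#' @return List: `utrs` (named character, DNA) and `ledger` data frame
#'   (utr_id, mirna_id, site_type, position).
#' @export
simulate_utrs <- function(matures, cfg, seed = NULL, max_attempts = 1000) {
  if (!is.null(seed)) set.seed(seed)
  u <- cfg$utr
  cores <- vapply(matures, function(m) {
    as_dna(revcomp(substring(m, 2, 8)))
  }, character(1))
  clean <- function(s) !any(vapply(cores, function(cc) grepl(cc, s, fixed = TRUE),
                                   logical(1)))
  utr_ids <- sprintf("UTRGENE%03d", seq_len(u$n_utrs))
  slots_per_utr <- max(1L, (u$utr_len - 20L) %/% 60L)
  utrs <- stats::setNames(character(u$n_utrs), utr_ids)
  for (i in seq_len(u$n_utrs)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- rand_dna(u$utr_len)
      if (clean(s)) { utrs[i] <- s; ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a site-free UTR in ", max_attempts, " attempts")
  }
  ledger <- list()
  target_utrs <- utrs
  ptr <- 0L
  for (mid in names(matures)) {
    core <- cores[[mid]]
    types <- c(rep("8mer-1a", u$n_8mer), rep("7mer-m8", u$n_7mer))
    for (ty in types) {
      ptr <- ptr + 1L
      # round-robin over UTRs; a UTR only gets a second site after every
      # UTR has one, in the next 60-nt slot (no overlap by construction)
      uid <- utr_ids[((ptr - 1L) %% length(utr_ids)) + 1L]
      slot <- ((ptr - 1L) %/% length(utr_ids)) %% slots_per_utr
      pos0 <- 10L + slot * 60L  # 0-based site start
      site <- if (ty == "8mer-1a") paste0(core, "A") else core
      # a 7mer-m8 must NOT be followed by A (that would make it an 8mer)
      repl <- if (ty == "7mer-m8") {
        paste0(site, sample(c("C", "G", "T"), 1))
      } else site
      s <- target_utrs[[uid]]
      substr(s, pos0 + 1L, pos0 + nchar(repl)) <- repl
      target_utrs[[uid]] <- s
      ledger[[length(ledger) + 1L]] <- data.frame(
        utr_id = uid, mirna_id = mid, site_type = ty, position = pos0,
        stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, ledger)
  # verify: every planted site scans back exactly once, no extras
  for (mid in names(matures)) {
    hits <- scan_sites(matures[[mid]], target_utrs, mirna_id = mid)
    want <- ledger[ledger$mirna_id == mid, ]
    if (nrow(hits) != nrow(want)) {
      stop("planted site verification failed for ", mid)
    }
  }
  list(utrs = target_utrs, ledger = ledger)
}

#' Simulate the full synthetic study
#'
#' Composes the genome, retrotransposition events (one per planted class
#' member plus an optional mobile-element decoy), ortholog panels, and the
#' expression / survival / UTR / gene-set inputs, with one truth ledger
#' covering every planted entity.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_dataset` with all simulated objects and
#'   the `ledger`.
#' @export
simulate_dataset <- function(cfg) {
  gsim <- simulate_genome(cfg)
  genome <- gsim$genome
  retrocopies <- list(); retro_mirnas <- list(); ledger <- list()
  planted_genes <- names(gsim$plants)
  rid <- 0L
  for (g in planted_genes) {
    rid <- rid + 1L
    plant <- gsim$plants[[g]]
    res <- simulate_retrotransposition(genome, gsim$transcripts[[plant$tx_id]],
                                       cfg, plant,
                                       retro_id = sprintf("RC%02d", rid))
    genome <- res$genome
    retrocopies[[res$retrocopy$id]] <- res$retrocopy
    retro_mirnas[[res$mirna$id]] <- res$mirna
    ledger[[length(ledger) + 1L]] <- res$ledger
  }

  repeats <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = numeric(0), strand = character(0))
  if (isTRUE(cfg$plant_repeat_decoy)) {
    # a mobile-element-borne hairpin inside an extra copy: discovery must
    # flag it, not call it
    hp <- make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len)
    elem <- paste0(rand_dna(80), hp$seq, rand_dna(80))
    body <- paste0(rand_dna(150), elem, rand_dna(150))
    spacer <- rand_dna(300)
    pos <- nchar(genome[["chr1"]]) + nchar(spacer)
    genome[["chr1"]] <- paste0(genome[["chr1"]], spacer, body)
    decoy_tx <- gsim$transcripts[[1]]
    rc <- retrocopy_record("RCDECOY", "chr1", pos, pos + nchar(body), "+",
                           decoy_tx$gene_id, decoy_tx$id, body)
    retrocopies[["RCDECOY"]] <- rc
    pre_start <- pos + 150L + 80L
    mat0 <- pre_start + hp$mature_off
    dec <- mirna_record("mir-DECOY", "chr1", pre_start, pre_start + hp$len,
                        "+",
                        data.frame(id = "mir-DECOY-5p", start = mat0,
                                   end = mat0 + cfg$mature_len,
                                   sequence = chartr("T", "U",
                                     substring(hp$seq, hp$mature_off + 1L,
                                               hp$mature_off + cfg$mature_len)),
                                   stringsAsFactors = FALSE),
                        host_context = "intergenic")
    retro_mirnas[["mir-DECOY"]] <- dec
    repeats <- data.frame(chrom = "chr1", start = pos + 150L,
                          end = pos + 150L + nchar(elem),
                          name = "SIM_MOBILE_ELEMENT", score = 0,
                          strand = ".", stringsAsFactors = FALSE)
    ledger[[length(ledger) + 1L]] <- data.frame(
      retromir_id = "mir-DECOY", class = "repeat", retrocopy_id = "RCDECOY",
      parental_gene_id = decoy_tx$gene_id, parental_tx_id = decoy_tx$id,
      strand = "+", n_mutations = 0L, n_targeted = 0L,
      mature_mismatches = NA_integer_, junction_mrna = NA_integer_,
      truncation_bp = 0L, stringsAsFactors = FALSE)
  }
  ledger <- do.call(rbind, ledger)

  # ortholog panels: precursor sequences diverged per species, with an
  # assigned age cutting off the more distal species
  # assigned conservation depth: 0 = human-specific, k = present (and
  # conserved) out to the k-th panel species
  ages <- rep(c(seq_along(cfg$species), 0L),
              length.out = sum(ledger$class %in% c("R", "EJ", "N")))
  panels <- list(); cons_rows <- list(); k <- 0L
  for (i in seq_len(nrow(ledger))) {
    if (!ledger$class[i] %in% c("R", "EJ", "N")) next
    k <- k + 1L
    mid <- ledger$retromir_id[i]
    mr <- retro_mirnas[[mid]]
    pre <- extract_sequence(genome, interval_of(mr))
    age_idx <- ages[k]  # how many panel species carry the sequence
    panel <- list()
    for (sp in seq_along(cfg$species)) {
      if (sp <= age_idx) {
        panel[[cfg$species[sp]]] <- simulate_ortholog(pre, cfg$divergence[sp])
      }
    }
    panels[[mid]] <- panel
    cons_rows[[mid]] <- data.frame(
      retromir_id = mid,
      true_age = if (age_idx == 0) "human-specific" else cfg$species[age_idx],
      stringsAsFactors = FALSE)
  }
  conservation_truth <- do.call(rbind, cons_rows)

  mat_ids <- unlist(lapply(retro_mirnas, function(m) m$matures$id))
  mat_seqs <- stats::setNames(
    unlist(lapply(retro_mirnas, function(m) m$matures$sequence)), mat_ids)
  real <- mat_ids[!grepl("DECOY", mat_ids)]
  n_over <- max(1L, floor(length(real) / 2))
  overexpressed <- real[seq_len(n_over)]
  prognostic <- real[seq_len(min(2L, length(real)))]

  bg_ids <- sprintf("mir-BG%02d", seq_len(cfg$expr$n_background))
  expression <- simulate_expression(c(real, bg_ids), overexpressed, cfg)
  surv <- simulate_survival(c(real, bg_ids), prognostic, cfg)
  plant_mats <- mat_seqs[real[seq_len(min(4L, length(real)))]]
  utrs <- simulate_utrs(plant_mats, cfg)

  utr_genes <- names(utrs$utrs)
  target_genes <- unique(utrs$ledger$utr_id)
  validated <- data.frame(mirna_id = utrs$ledger$mirna_id[1],
                          gene_id = utr_genes[c(1, 5, 9)],
                          stringsAsFactors = FALSE)
  set1 <- unique(c(target_genes,
                   utr_genes[seq_len(min(5, length(utr_genes)))]))
  set2 <- utr_genes[seq(1, length(utr_genes), by = 3)]
  gene_sets <- list(TARGET_RICH_PROCESS = set1, UNRELATED_PROCESS = set2)
  attr(gene_sets, "description") <- c(TARGET_RICH_PROCESS = "planted",
                                      UNRELATED_PROCESS = "background")

  structure(list(
    cfg = cfg, genome = genome, transcripts = gsim$transcripts,
    parental_mirnas = gsim$parental_mirnas, retro_mirnas = retro_mirnas,
    retrocopies = retrocopies, repeats = repeats, ledger = ledger,
    ortholog_panels = panels, conservation_truth = conservation_truth,
    expression = expression, survival = surv, utrs = utrs,
    validated_targets = validated, gene_sets = gene_sets,
    overexpressed = overexpressed, prognostic = prognostic
  ), class = "sim_dataset")
}

#' Extract the strand-oriented sequence of an interval
#'
#' @param genome Named character vector.
#' @param iv Single-row interval data frame.
#' @return Character scalar (reverse-complemented on the minus strand).
#' @export
extract_sequence <- function(genome, iv) {
  s <- substring(genome[[iv$chrom]], iv$start + 1L, iv$end)
  if (iv$strand == "-") s <- revcomp(s)
  s
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$transcripts, file.path(dir, "annotation.gtf"))
  write_mirna_gff3(c(sim$parental_mirnas, sim$retro_mirnas),
                   file.path(dir, "mirna.gff3"))
  rc <- do.call(rbind, lapply(sim$retrocopies, function(r) {
    data.frame(id = r$id, chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, parental_gene_id = r$parental_gene_id,
               parental_transcript_id = r$parental_transcript_id,
               stringsAsFactors = FALSE)
  }))
  write_tsv(rc, file.path(dir, "retrocopies.tsv"))
  if (nrow(sim$repeats) > 0) {
    write_bed(sim$repeats, file.path(dir, "repeats.bed"))
  } else {
    file.create(file.path(dir, "repeats.bed"))
  }
  write_tsv(sim$ledger, file.path(dir, "truth_ledger.tsv"))
  for (mid in names(sim$ortholog_panels)) {
    p <- sim$ortholog_panels[[mid]]
    if (length(p)) {
      write_fasta(unlist(p), file.path(dir, paste0("orthologs_", mid, ".fa")))
    }
  }
  counts <- data.frame(feature = rownames(sim$expression$counts),
                       sim$expression$counts, check.names = FALSE)
  write_tsv(counts, file.path(dir, "expression_counts.tsv"))
  write_tsv(sim$expression$meta, file.path(dir, "expression_meta.tsv"))
  write_tsv(data.frame(feature = names(sim$expression$lengths),
                       length = unname(sim$expression$lengths)),
            file.path(dir, "feature_lengths.tsv"))
  write_tsv(sim$survival$records, file.path(dir, "survival.tsv"))
  write_fasta(sim$utrs$utrs, file.path(dir, "utr.fa"))
  write_tsv(sim$validated_targets, file.path(dir, "validated_targets.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
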