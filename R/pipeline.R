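#' Pipeline configuration
#'
#' Validates paths and stage parameters before any stage runs; unknown
#' parameter names are rejected.
#'
#' @param input_dir Directory with the pipeline inputs (the layout
#'   written by [write_dataset()]).
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param params Named list overriding stage defaults: `min_overlap`,
#'   `repeat_frac`, `ignore_strand`, `min_intron`, `conservation_threshold`,
#'   `species`, `dnds_boot`, `tss_window`, `ccre_window`, `fe_min`,
#'   `fdr_max`, `surv_boot`, `keep_frac`, `lambda`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1, params = list()) {
  defaults <- list(min_overlap = 5, repeat_frac = 0.5, ignore_strand = FALSE,
                   min_intron = 30, conservation_threshold = 0.80,
                   species = c("chimpanzee", "gorilla", "orangutan",
                               "rhesus", "marmoset"),
                   dnds_boot = 200, tss_window = 4000, ccre_window = 20000,
                   fe_min = 1.5, fdr_max = 0.05,
                   surv_boot = 100, keep_frac = 0.8, lambda = 0.1)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(params)] <- params
  required <- c("genome.fa", "annotation.gtf", "mirna.gff3",
                "retrocopies.tsv")
  for (f in required) {
    if (!file.exists(file.path(input_dir, f))) {
      stop("missing required input: ", file.path(input_dir, f))
    }
  }
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              seed = as.integer(seed), params = defaults)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  # out_dir excluded: the hash identifies the analysis, not its location
  key <- list(seed = config$seed, params = config$params)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(key, tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Class tallies with half-up percentages
#'
#' @param classes Character vector of class labels (`R`, `EJ`, `N`, ...).
#' @return Data frame: `class`, `count`, `percent` (one decimal,
#'   half-up rounding).
#' @export
tally_classes <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0) stop("no classified candidates")
  tab <- table(classes)
  pct <- floor(1000 * as.numeric(tab) / length(classes) + 0.5) / 10
  data.frame(class = names(tab), count = as.integer(tab), percent = pct,
             stringsAsFactors = FALSE)
}

read_pipeline_inputs <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  transcripts <- read_gtf(file.path(dir, "annotation.gtf"))
  mirnas <- read_mirna_gff3(file.path(dir, "mirna.gff3"), genome = genome)
  rc_tab <- read_tsv(file.path(dir, "retrocopies.tsv"))
  retrocopies <- lapply(seq_len(nrow(rc_tab)), function(i) {
    r <- rc_tab[i, ]
    iv <- gi(r$chrom, r$start, r$end, r$strand)
    retrocopy_record(r$id, r$chrom, r$start, r$end, r$strand,
                     r$parental_gene_id, r$parental_transcript_id,
                     extract_sequence(genome, iv))
  })
  names(retrocopies) <- rc_tab$id
  rep_path <- file.path(dir, "repeats.bed")
  repeats <- if (file.exists(rep_path) && file.size(rep_path) > 0) {
    read_bed(rep_path)
  } else NULL
  opt <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  list(genome = genome, transcripts = transcripts, mirnas = mirnas,
       retrocopies = retrocopies, repeats = repeats,
       expression_counts = opt("expression_counts.tsv", read_tsv),
       expression_meta = opt("expression_meta.tsv", read_tsv),
       feature_lengths = opt("feature_lengths.tsv", read_tsv),
       survival = opt("survival.tsv", read_tsv),
       utrs = opt("utr.fa", read_fasta),
       validated = opt("validated_targets.tsv", read_tsv),
       gene_sets = opt("gene_sets.gmt", read_gmt),
       tss = opt("tss.bed", read_bed),
       ccre = opt("ccre.bed", read_bed))
}

#' Run the retro-miR pipeline end to end
#'
#' Discover, fold-confirm, classify, then characterize conservation,
#' selection, expression, targets/enrichment, and survival, writing every
#' stage table plus a deterministic human-readable report to
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A `retromir_report` list of stage tables and tallies.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  inp <- read_pipeline_inputs(config$input_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1-2: discovery (overlap, repeat screen, folding)
  disc <- discover_retromirs(inp$mirnas, inp$retrocopies, inp$genome,
                             repeats = inp$repeats,
                             min_overlap = p$min_overlap,
                             repeat_frac = p$repeat_frac,
                             ignore_strand = p$ignore_strand)
  write_tsv(disc$retro_mirs, file.path(config$out_dir, "retro_mirs.tsv"))
  write_tsv(disc$review, file.path(config$out_dir, "repeat_review.tsv"))

  # stage 3: classification
  calls <- classify_all(disc$retro_mirs, inp$mirnas, inp$retrocopies,
                        inp$transcripts, inp$mirnas, inp$genome,
                        min_intron = p$min_intron)
  write_tsv(as.data.frame(calls), file.path(config$out_dir, "classes.tsv"))
  tally <- tally_classes(calls$class[calls$class %in% c("R", "EJ", "N")])

  # stage 4: conservation / age
  cons <- lapply(calls$mirna_id, function(mid) {
    panel_path <- file.path(config$input_dir, paste0("orthologs_", mid, ".fa"))
    panel <- if (file.exists(panel_path)) as.list(read_fasta(panel_path)) else list()
    pre <- extract_sequence(inp$genome, interval_of(inp$mirnas[[mid]]))
    cc <- call_conservation(pre, panel, species_order = p$species,
                            threshold = p$conservation_threshold)
    data.frame(mirna_id = mid, species = cc$species, identity = cc$identity,
               conserved = cc$conserved, present = cc$present,
               age = assign_age(cc, p$species), stringsAsFactors = FALSE)
  })
  cons <- if (length(cons)) do.call(rbind, cons) else NULL
  if (!is.null(cons)) {
    write_tsv(cons, file.path(config$out_dir, "conservation.tsv"))
  }

  # stage 5: selection (retrocopy ORF vs parental ORF)
  sel <- lapply(seq_len(nrow(calls)), function(i) {
    rc <- inp$retrocopies[[calls$retrocopy_id[i]]]
    tx <- inp$transcripts[[rc$parental_transcript_id]]
    res <- selection_on_pair(rc$sequence, splice(inp$genome, tx),
                             n_boot = p$dnds_boot,
                             seed = config$seed + i)
    if (is.null(res)) {
      return(data.frame(mirna_id = calls$mirna_id[i], retrocopy_id = rc$id,
                        dN = NA_real_, dS = NA_real_, omega = NA_real_,
                        p_neutral = NA_real_, regime = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(mirna_id = calls$mirna_id[i], retrocopy_id = rc$id,
               dN = res$dN, dS = res$dS, omega = res$omega,
               p_neutral = res$p_neutral, regime = res$regime,
               stringsAsFactors = FALSE)
  })
  sel <- if (length(sel)) do.call(rbind, sel) else NULL
  if (!is.null(sel)) write_tsv(sel, file.path(config$out_dir, "selection.tsv"))

  # stage 6: expression
  expr_summary <- NULL; tumor_tests <- NULL
  if (!is.null(inp$expression_counts)) {
    counts <- as.matrix(inp$expression_counts[, -1, drop = FALSE])
    rownames(counts) <- inp$expression_counts[[1]]
    lengths <- stats::setNames(inp$feature_lengths$length,
                               inp$feature_lengths$feature)
    tpm <- normalize_expression(counts, lengths, mode = "TPM")
    meta <- inp$expression_meta
    normal <- meta$tissue != "cohort"
    summ <- summarize_expression(tpm[, meta$sample[normal], drop = FALSE],
                                 meta$tissue[normal])
    expr_summary <- data.frame(feature = rownames(tpm),
                               breadth = summ$breadth[rownames(tpm)],
                               stringsAsFactors = FALSE)
    cohort <- meta$tissue == "cohort"
    tt <- tumor_vs_normal_all(tpm[, meta$sample[cohort], drop = FALSE],
                              meta$condition[cohort])
    tumor_tests <- tt
    write_tsv(expr_summary, file.path(config$out_dir, "expression_breadth.tsv"))
    write_tsv(tt, file.path(config$out_dir, "tumor_vs_normal.tsv"))
  }

  # stage 7: targets + enrichment
  sites <- NULL; targets <- NULL; enrichment <- NULL
  if (!is.null(inp$utrs)) {
    mats <- do.call(c, unname(lapply(inp$mirnas[unique(calls$mirna_id)],
                                     function(m) {
      stats::setNames(m$matures$sequence, m$matures$id)
    })))
    mats <- mats[!duplicated(mats)]
    sites <- do.call(rbind, lapply(names(mats), function(mid) {
      scan_sites(mats[[mid]], inp$utrs, mirna_id = mid)
    }))
    if (!is.null(sites) && nrow(sites) > 0) {
      val <- if (!is.null(inp$validated)) inp$validated else
        data.frame(mirna_id = character(0), gene_id = character(0))
      targets <- merge_validated(sites, val)
      write_tsv(sites, file.path(config$out_dir, "target_sites.tsv"))
      write_tsv(targets, file.path(config$out_dir, "targets.tsv"))
      if (!is.null(inp$gene_sets)) {
        universe <- names(inp$utrs)
        query <- intersect(unique(targets$gene_id), universe)
        enrichment <- enrich_sets(query, inp$gene_sets, universe,
                                  fe_min = p$fe_min, fdr_max = p$fdr_max)
        write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
      }
    }
  }

  # stage 8: survival signature
  signature <- NULL; surv_eval <- NULL
  if (!is.null(inp$survival)) {
    feat_cols <- setdiff(names(inp$survival), c("patient_id", "time", "event"))
    mature_ids <- unlist(lapply(inp$mirnas[unique(calls$mirna_id)],
                                function(m) m$matures$id))
    feats <- intersect(feat_cols, mature_ids)
    # only expressed features (TPM > 0 anywhere) enter the model
    feats <- feats[vapply(feats, function(f) any(inp$survival[[f]] > 0),
                          logical(1))]
    if (length(feats) >= 1 && sum(inp$survival$event) >= 2) {
      signature <- bootstrap_signature(inp$survival, feats,
                                       n_boot = p$surv_boot,
                                       keep_frac = p$keep_frac,
                                       lambda = p$lambda,
                                       seed = config$seed)
      surv_eval <- evaluate_signature(signature, inp$survival)
      sig_df <- data.frame(feature = signature$features,
                           coefficient = unname(signature$coefficients),
                           stringsAsFactors = FALSE)
      write_tsv(sig_df, file.path(config$out_dir, "signature.tsv"))
      scores_df <- data.frame(patient_id = inp$survival$patient_id,
                              score = surv_eval$scores,
                              group = surv_eval$group,
                              stringsAsFactors = FALSE)
      write_tsv(scores_df, file.path(config$out_dir, "patient_scores.tsv"))
      if (!is.null(surv_eval$km)) {
        km_df <- rbind(cbind(group = "low", surv_eval$km$low),
                       cbind(group = "high", surv_eval$km$high))
        write_tsv(km_df, file.path(config$out_dir, "km_curves.tsv"))
      }
    }
  }

  report <- structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    params = p,
    n_mirnas = length(inp$mirnas),
    n_retrocopies = length(inp$retrocopies),
    n_candidates = nrow(disc$retro_mirs) + nrow(disc$rejected_fold) +
      nrow(disc$review),
    n_repeat_flagged = nrow(disc$review),
    n_confirmed = nrow(disc$retro_mirs),
    calls = as.data.frame(calls), tally = tally,
    conservation = cons, selection = sel,
    expression_breadth = expr_summary, tumor_tests = tumor_tests,
    sites = sites, targets = targets, enrichment = enrichment,
    signature = signature, survival = surv_eval
  ), class = "retromir_report")
  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  report
}

format_report <- function(r) {
  out <- c(
    "retro-miR pipeline report",
    sprintf("config hash: %s", r$config_hash),
    sprintf("seed: %d", r$seed),
    "",
    sprintf("miRNA annotations:       %d", r$n_mirnas),
    sprintf("retrocopies:             %d", r$n_retrocopies),
    sprintf("overlap candidates:      %d", r$n_candidates),
    sprintf("repeat-flagged (review): %d", r$n_repeat_flagged),
    sprintf("fold-confirmed:          %d", r$n_confirmed),
    "",
    "class tally:")
  for (i in seq_len(nrow(r$tally))) {
    out <- c(out, sprintf("  %-3s %3d  (%.1f%%)", r$tally$class[i],
                          r$tally$count[i], r$tally$percent[i]))
  }
  if (!is.null(r$conservation)) {
    ages <- unique(r$conservation[, c("mirna_id", "age")])
    out <- c(out, "", "ages:")
    for (i in seq_len(nrow(ages))) {
      out <- c(out, sprintf("  %-14s %s", ages$mirna_id[i], ages$age[i]))
    }
  }
  if (!is.null(r$selection)) {
    out <- c(out, "", "selection regimes:")
    tt <- table(r$selection$regime, useNA = "ifany")
    for (i in seq_along(tt)) {
      nm <- names(tt)[i]; if (is.na(nm)) nm <- "NA"
      out <- c(out, sprintf("  %-12s %d", nm, tt[[i]]))
    }
  }
  if (!is.null(r$enrichment)) {
    out <- c(out, "", sprintf("enriched gene sets (FE > %.1f, FDR < %.2f): %d",
                              r$params$fe_min, r$params$fdr_max,
                              sum(r$enrichment$pass)))
  }
  if (!is.null(r$signature)) {
    out <- c(out, "", sprintf("survival signature: %d feature(s); log-rank p = %s",
                              length(r$signature$features),
                              if (is.null(r$survival) || is.na(r$survival$p))
                                "NA" else sprintf("%.3g", r$survival$p)))
  }
  out
}

#' @export
print.retromir_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
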