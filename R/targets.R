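#' Scan 3'UTRs for canonical miRNA seed-match sites
#'
#' The seed is mature positions 2-8 (5' to 3'); its reverse complement
#' (the core, read 5' to 3' on the UTR) is searched in every UTR. A core
#' match followed immediately by an `A` on the UTR (opposite miRNA
#' position 1) is an 8mer-1a site; a core match without that `A` is a
#' 7mer-m8. Each core position is reported once with the strongest type.
#'
#' @param mature_seq Mature miRNA sequence (RNA or DNA, >= 8 nt).
#' @param utrs Named character vector of UTR sequences.
#' @param mirna_id Identifier recorded in the output.
#' @return Data frame: `utr_id`, `mirna_id`, `site_type`, `position`
#'   (0-based 5' end of the site on the UTR), `site_seq`.
#' @export
scan_sites <- function(mature_seq, utrs, mirna_id = "mirna") {
  if (nchar(mature_seq) < 8) stop("mature sequence must be >= 8 nt")
  seed <- substring(chartr("T", "U", toupper(mature_seq)), 2, 8)
  core <- as_dna(revcomp(seed))  # 5'->3' on the UTR
  rows <- list()
  for (uid in names(utrs)) {
    s <- as_dna(toupper(utrs[[uid]]))
    hits <- gregexpr(core, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in as.integer(hits)) {
      after <- substring(s, h + 7, h + 7)
      ty <- if (identical(after, "A")) "8mer-1a" else "7mer-m8"
      len <- if (ty == "8mer-1a") 8L else 7L
      rows[[length(rows) + 1L]] <- data.frame(
        utr_id = uid, mirna_id = mirna_id, site_type = ty,
        position = h - 1L, site_seq = substring(s, h, h + len - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(utr_id = character(0), mirna_id = character(0),
                      site_type = character(0), position = integer(0),
                      site_seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Merge predicted seed sites with validated interactions
#'
#' Gene-level union: a gene is a target when it carries a predicted site
#' or appears in the validated table (or both).
#'
#' @param predicted Site-level data frame from [scan_sites()].
#' @param validated Data frame with `mirna_id`, `gene_id`.
#' @return Data frame: `mirna_id`, `gene_id`, `evidence` in
#'   {predicted, validated, both}, `n_sites`.
#' @export
merge_validated <- function(predicted, validated) {
  pred <- unique(predicted[, c("mirna_id", "utr_id")])
  names(pred)[2] <- "gene_id"
  nsite <- stats::aggregate(list(n_sites = predicted$site_type),
                            by = list(mirna_id = predicted$mirna_id,
                                      gene_id = predicted$utr_id),
                            FUN = length)
  val <- unique(validated[, c("mirna_id", "gene_id")])
  key <- function(df) paste(df$mirna_id, df$gene_id)
  all_pairs <- unique(rbind(pred, val))
  ev <- ifelse(key(all_pairs) %in% key(pred) &
                 key(all_pairs) %in% key(val), "both",
               ifelse(key(all_pairs) %in% key(pred), "predicted",
                      "validated"))
  out <- data.frame(all_pairs, evidence = ev, stringsAsFactors = FALSE)
  m <- match(key(out), paste(nsite$mirna_id, nsite$gene_id))
  out$n_sites <- ifelse(is.na(m), 0L, nsite$n_sites[m])
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric p per set (P(X >= k)), fold enrichment
#' (k/n)/(K/N), Benjamini-Hochberg FDR across sets; a set passes when
#' fold enrichment > `fe_min` and FDR < `fdr_max`.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param gene_sets Named list of character vectors (e.g., [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @param fe_min,fdr_max Significance filter.
#' @return Data frame sorted by FDR then fold enrichment: `set_id`, `k`,
#'   `K`, `n`, `N`, `fold_enrichment`, `p`, `fdr`, `pass`.
#' @export
enrich_sets <- function(query, gene_sets, universe, fe_min = 1.5,
                        fdr_max = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad) > 0) {
    stop("query genes outside universe: ", paste(bad, collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(set_id = sid, k = k, K = K, n = n, N = N,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$pass <- out$fold_enrichment > fe_min & out$fdr < fdr_max
  out <- out[order(out$fdr, -out$fold_enrichment, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
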