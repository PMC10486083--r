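# Nei-Gojobori (1986) machinery. Site counts partition each codon's three
# positions into synonymous and nonsynonymous fractions (changes to stop
# codons count as nonsynonymous); pathway counts average the synonymous /
# nonsynonymous steps over all minimal substitution orders that avoid
# stop-codon intermediates.

codon_table_env <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

aa_of <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[chartr("U", "T", codon)])
}

#' Synonymous/nonsynonymous site counts of a codon
#'
#' @param codon A sense codon (DNA).
#' @return Named numeric: `S` (synonymous sites) and `N`; S + N = 3.
#' @export
codon_sites <- function(codon) {
  aa <- aa_of(codon)
  if (aa == "*") stop("stop codon has no site counts")
  b <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (alt in setdiff(b, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (aa_of(mut) == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# pathway-averaged (syn, nonsyn) differences between two codons
codon_path_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(diff_pos) else {
    if (nd == 2) {
      list(diff_pos, rev(diff_pos))
    } else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) diff_pos[o])
    }
  }
  walk <- function(order) {
    cur <- c1; syn <- 0; non <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa_of(nxt) == "*") return(NULL)
      if (aa_of(nxt) == aa_of(cur)) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(res) == 0) {  # all pathways pass through a stop: use them all
    res <- lapply(perms, function(order) {
      cur <- c1; syn <- 0; non <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa_of(nxt) == aa_of(cur)) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    })
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[[1]], nd = m[[2]])
}

codon_tables <- function() {
  if (!is.null(codon_table_env$tab)) return(codon_table_env$tab)
  codons <- all_codons()
  sense <- codons[aa_of(codons) != "*"]
  sites <- t(vapply(sense, codon_sites, numeric(2)))
  path <- array(NA_real_, dim = c(length(sense), length(sense), 2),
                dimnames = list(sense, sense, c("sd", "nd")))
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      pc <- codon_path_counts(sense[i], sense[j])
      path[i, j, 1] <- pc[["sd"]]; path[i, j, 2] <- pc[["nd"]]
    }
  }
  codon_table_env$tab <- list(sense = sense, sites = sites, path = path)
  codon_table_env$tab
}

split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Find the longest ORF of a nucleotide sequence
#'
#' Scans the requested forward frames for the longest ATG-to-stop open
#' reading frame; ties go to the 5'-most start.
#'
#' @param seq Nucleotide sequence (DNA; U read as T).
#' @param frames Forward frames to scan (subset of 1:3).
#' @param min_codons Minimum ORF length in codons (ATG included, stop
#'   excluded); shorter ORFs give an NA result.
#' @return List with `frame`, `start`/`end` (0-based half-open nt span of
#'   the coding sequence, stop excluded), and `protein`; all NA when no
#'   qualifying ORF exists.
#' @export
find_longest_orf <- function(seq, frames = 1:3, min_codons = 20) {
  s <- chartr("U", "T", toupper(seq))
  best <- NULL
  for (f in frames) {
    sub <- substring(s, f)
    n <- nchar(sub) - nchar(sub) %% 3
    if (n < 6) next
    codons <- substring(sub, seq(1, n, 3), seq(3, n, 3))
    aas <- aa_of(codons)
    i <- 1
    while (i <= length(codons)) {
      if (codons[i] == "ATG") {
        stops <- which(aas == "*" & seq_along(aas) > i)
        if (length(stops) > 0) {
          j <- min(stops)
          len <- j - i
          start_nt <- (f - 1) + (i - 1) * 3
          if (len >= min_codons &&
              (is.null(best) || len > best$len ||
               (len == best$len && start_nt < best$start))) {
            best <- list(frame = f, start = start_nt,
                         end = start_nt + 3 * len, len = len,
                         protein = paste(aas[i:(j - 1)], collapse = ""))
          }
          i <- j + 1
          next
        }
      }
      i <- i + 1
    }
  }
  if (is.null(best)) {
    return(list(frame = NA_integer_, start = NA_integer_,
                end = NA_integer_, protein = NA_character_))
  }
  best[c("frame", "start", "end", "protein")]
}

#' Codon alignment of two coding sequences via their proteins
#'
#' Translates both CDSs, aligns the proteins globally (BLOSUM62), and
#' back-maps each aligned amino-acid column to its source codons; columns
#' gapped in either protein are dropped.
#'
#' @param cds1,cds2 In-frame coding sequences (no stop codon inside).
#' @return Data frame with `codon1`, `codon2` (one row per retained
#'   aligned codon column).
#' @export
codon_align <- function(cds1, cds2) {
  if (nchar(cds1) %% 3 != 0 || nchar(cds2) %% 3 != 0) {
    stop("CDS length not a multiple of 3 (frameshifted input)")
  }
  p1 <- translate_dna(chartr("U", "T", toupper(cds1)))
  p2 <- translate_dna(chartr("U", "T", toupper(cds2)))
  if (grepl("\\*", substr(p1, 1, nchar(p1) - 1)) ||
      grepl("\\*", substr(p2, 1, nchar(p2) - 1))) {
    stop("internal stop codon at protein position ",
         regexpr("\\*", p1), "/", regexpr("\\*", p2))
  }
  p1 <- sub("\\*$", "", p1); p2 <- sub("\\*$", "", p2)
  aln <- align_protein(p1, p2)
  a1 <- strsplit(aln$query_aln, "")[[1]]
  a2 <- strsplit(aln$subject_aln, "")[[1]]
  cod1 <- split_codons(substr(cds1, 1, 3 * nchar(p1)))
  cod2 <- split_codons(substr(cds2, 1, 3 * nchar(p2)))
  i1 <- 0L; i2 <- 0L; rows <- list()
  for (k in seq_along(a1)) {
    if (a1[k] != "-") i1 <- i1 + 1L
    if (a2[k] != "-") i2 <- i2 + 1L
    if (a1[k] != "-" && a2[k] != "-") {
      if (aa_of(cod1[i1]) != a1[k] || aa_of(cod2[i2]) != a2[k]) {
        stop("codon/protein mismatch at aligned column ", k)
      }
      rows[[length(rows) + 1L]] <- data.frame(codon1 = cod1[i1],
                                              codon2 = cod2[i2],
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; observed synonymous /
#' nonsynonymous differences are pathway-averaged per codon; proportions
#' are Jukes-Cantor corrected (d = -3/4 log(1 - 4p/3)).
#'
#' @param codon_pairs Data frame from [codon_align()] (>= 20 rows).
#' @return A `selection_result` list: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega` (NA when dS = 0), `n_codons`, `saturated`,
#'   `p_neutral` and `regime` (filled by [test_neutrality()]).
#' @export
dnds_ng86 <- function(codon_pairs) {
  if (nrow(codon_pairs) < 20) stop("need at least 20 codon pairs")
  tab <- codon_tables()
  c1 <- chartr("U", "T", toupper(codon_pairs$codon1))
  c2 <- chartr("U", "T", toupper(codon_pairs$codon2))
  if (!all(c1 %in% tab$sense) || !all(c2 %in% tab$sense)) {
    stop("stop or invalid codon in input")
  }
  i1 <- match(c1, tab$sense); i2 <- match(c2, tab$sense)
  S <- (sum(tab$sites[i1, "S"]) + sum(tab$sites[i2, "S"])) / 2
  N <- (sum(tab$sites[i1, "N"]) + sum(tab$sites[i2, "N"])) / 2
  Sd <- sum(tab$path[cbind(i1, i2, 1)])
  Nd <- sum(tab$path[cbind(i1, i2, 2)])
  pS <- Sd / S; pN <- Nd / N
  saturated <- pS >= 3 / 4 || pN >= 3 / 4
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (saturated || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = nrow(codon_pairs), saturated = saturated,
                 p_neutral = NA_real_, regime = NA_character_),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("dN = %.4f  dS = %.4f  omega = %s  (%d codons)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "NA" else sprintf("%.3f", x$omega),
              x$n_codons))
  if (!is.na(x$p_neutral)) {
    cat(sprintf("neutrality: p = %.4f, regime = %s\n", x$p_neutral, x$regime))
  }
  invisible(x)
}

#' Test departure from neutral evolution (dN/dS = 1) by codon bootstrap
#'
#' Codon columns are resampled with replacement; the two-sided p-value is
#' twice the smaller tail fraction of resamples with dN above/below dS
#' (capped at 1). Regimes: `purifying` (omega < 1, p <= alpha),
#' `positive` (omega > 1, p <= alpha), otherwise `neutral/NS`; `NA` when
#' omega is undefined (dS = 0 or saturation).
#'
#' @param result A `selection_result` from [dnds_ng86()].
#' @param codon_pairs The codon pairs the result was computed from.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional RNG seed.
#' @param alpha Significance level.
#' @return The `selection_result` with `p_neutral` and `regime` filled.
#' @export
test_neutrality <- function(result, codon_pairs, n_boot = 1000, seed = NULL,
                            alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(result$omega)) {
    result$regime <- NA_character_
    return(result)
  }
  tab <- codon_tables()
  i1 <- match(chartr("U", "T", toupper(codon_pairs$codon1)), tab$sense)
  i2 <- match(chartr("U", "T", toupper(codon_pairs$codon2)), tab$sense)
  n <- length(i1)
  sA <- tab$sites[i1, "S"]; sB <- tab$sites[i2, "S"]
  nA <- tab$sites[i1, "N"]; nB <- tab$sites[i2, "N"]
  sd_i <- tab$path[cbind(i1, i2, 1)]; nd_i <- tab$path[cbind(i1, i2, 2)]
  jc <- function(p) ifelse(p >= 3 / 4, NA_real_, -3 / 4 * log(1 - 4 * p / 3))
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    S <- (sum(sA[idx]) + sum(sB[idx])) / 2
    N <- (sum(nA[idx]) + sum(nB[idx])) / 2
    dS <- jc(sum(sd_i[idx]) / S); dN <- jc(sum(nd_i[idx]) / N)
    stat[b] <- if (is.na(dS) || is.na(dN)) NA_real_ else dN - dS
  }
  stat <- stat[!is.na(stat)]
  if (length(stat) == 0) {
    result$regime <- NA_character_
    return(result)
  }
  p <- 2 * min(mean(stat >= 0), mean(stat <= 0))
  result$p_neutral <- min(1, p)
  result$regime <- if (result$omega < 1 && result$p_neutral <= alpha) {
    "purifying"
  } else if (result$omega > 1 && result$p_neutral <= alpha) {
    "positive"
  } else "neutral/NS"
  result
}

#' Selection analysis of a retrocopy against its parental gene
#'
#' Finds the longest ORF in each sequence, codon-aligns them, and runs
#' NG86 plus the neutrality bootstrap.
#'
#' @param retro_seq,parent_seq Nucleotide sequences.
#' @param n_boot,seed Passed to [test_neutrality()].
#' @return A `selection_result`, or NULL when either ORF is missing or
#'   fewer than 20 codon pairs align.
#' @export
selection_on_pair <- function(retro_seq, parent_seq, n_boot = 1000,
                              seed = NULL) {
  o1 <- find_longest_orf(retro_seq)
  o2 <- find_longest_orf(parent_seq)
  if (is.na(o1$frame) || is.na(o2$frame)) return(NULL)
  cds1 <- substr(chartr("U", "T", toupper(retro_seq)), o1$start + 1, o1$end)
  cds2 <- substr(chartr("U", "T", toupper(parent_seq)), o2$start + 1, o2$end)
  pairs <- codon_align(cds1, cds2)
  if (is.null(pairs) || nrow(pairs) < 20) return(NULL)
  res <- dnds_ng86(pairs)
  test_neutrality(res, pairs, n_boot = n_boot, seed = seed)
}
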