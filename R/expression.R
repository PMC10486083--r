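#' Library-size normalization of a count matrix
#'
#' RPM scales each column to a million; TPM first divides by feature
#' length (so columns also sum to a million). A zero-depth sample yields
#' an all-zero column with a warning.
#'
#' @param counts Numeric matrix, features x samples.
#' @param lengths Named numeric vector of feature lengths (nt); required
#'   for TPM.
#' @param mode `"RPM"` or `"TPM"`.
#' @return Normalized matrix with a `normalization` attribute.
#' @export
normalize_expression <- function(counts, lengths = NULL,
                                 mode = c("TPM", "RPM")) {
  mode <- match.arg(mode)
  if (any(counts < 0)) stop("negative counts")
  x <- as.matrix(counts)
  if (mode == "TPM") {
    if (is.null(lengths)) stop("TPM requires feature lengths")
    len <- lengths[rownames(x)]
    if (any(is.na(len))) stop("missing lengths for some features")
    x <- x / len
  }
  depth <- colSums(x)
  zero <- depth == 0
  if (any(zero)) {
    warning("zero-depth sample(s): ", paste(colnames(x)[zero], collapse = ", "))
    depth[zero] <- 1
  }
  out <- sweep(x, 2, depth, "/") * 1e6
  out[, zero] <- 0
  attr(out, "normalization") <- mode
  out
}

#' Per-tissue medians and expression breadth
#'
#' @param mat Normalized matrix (features x samples).
#' @param tissue Character vector of tissue labels per sample.
#' @return List: `medians` (features x tissues matrix of per-tissue
#'   medians) and `breadth` (named vector: number of tissues with median
#'   above zero).
#' @export
summarize_expression <- function(mat, tissue) {
  stopifnot(length(tissue) == ncol(mat))
  tl <- unique(tissue)
  med <- sapply(tl, function(t) {
    apply(mat[, tissue == t, drop = FALSE], 1, stats::median)
  })
  med <- matrix(med, nrow = nrow(mat),
                dimnames = list(rownames(mat), tl))
  list(medians = med, breadth = rowSums(med > 0))
}

#' Find the nearest upstream transcription start site of a retro-miR
#'
#' Searches for a same-strand TSS upstream of the retro-miR's 5' end (in
#' its expected transcription orientation) within `window` bp; the TSS at
#' the 5' end itself (distance 0) counts.
#'
#' @param locus Single-row interval data frame (the retro-miR precursor).
#' @param tss BED-style data frame of TSS positions with strand.
#' @param window Maximum upstream distance (bp).
#' @return List: `tss_found`, `distance` (NA when none), `tss_name`.
#' @export
associate_tss <- function(locus, tss, window = 4000) {
  if (!locus$strand %in% c("+", "-")) stop("retro-miR needs explicit strand")
  five_prime <- if (locus$strand == "+") locus$start else locus$end
  best <- NULL
  for (i in seq_len(nrow(tss))) {
    t <- tss[i, ]
    if (t$chrom != locus$chrom) next
    if (t$strand != "." && t$strand != locus$strand) next
    pos <- t$start
    d <- if (locus$strand == "+") five_prime - pos else pos - five_prime
    if (d < 0 || d > window) next
    if (is.null(best) || d < best$distance) {
      best <- list(distance = d, name = t$name)
    }
  }
  if (is.null(best)) {
    list(tss_found = FALSE, distance = NA_real_, tss_name = NA_character_)
  } else {
    list(tss_found = TRUE, distance = best$distance, tss_name = best$name)
  }
}

#' Is a candidate cis-regulatory element near a locus?
#'
#' @param locus Single-row interval data frame.
#' @param ccre BED-style data frame of cCREs (strand may be `"."`).
#' @param window_bp Maximum distance (bp); overlapping elements count as
#'   distance 0.
#' @return List: `ccre_nearby` (logical) and `distance` (NA when none
#'   within the window).
#' @export
associate_ccre <- function(locus, ccre, window_bp = 20000) {
  best <- Inf
  for (i in seq_len(nrow(ccre))) {
    e <- ccre[i, ]
    if (e$chrom != locus$chrom) next
    d <- max(0, max(locus$start, e$start) - min(locus$end, e$end))
    best <- min(best, d)
  }
  if (is.finite(best) && best <= window_bp) {
    list(ccre_nearby = TRUE, distance = best)
  } else {
    list(ccre_nearby = FALSE, distance = NA_real_)
  }
}

#' Significance stars for tumor-vs-normal p-values
#'
#' Bands: `*` for 0.01 <= p <= 0.05, `**` for 1e-4 <= p < 0.01, `***`
#' for p < 1e-4, empty otherwise.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 1e-4) return("***")
    if (x < 0.01) return("**")
    if (x <= 0.05) return("*")
    ""
  }, character(1))
}

#' Tumor-versus-normal test for one feature
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test: exact when both
#' groups have at most 8 samples and no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param values Numeric expression vector across samples.
#' @param condition Character vector: `"tumor"` / `"normal"` per sample.
#' @return List: `U` statistic (tumor vs normal), `p`, `stars`.
#' @export
tumor_vs_normal <- function(values, condition) {
  tu <- values[condition == "tumor"]
  no <- values[condition == "normal"]
  if (length(tu) == 0 || length(no) == 0) stop("both groups required")
  exact <- min(length(tu), length(no)) <= 8 &&
    !any(duplicated(c(tu, no)))
  wt <- suppressWarnings(
    stats::wilcox.test(tu, no, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, stars = p_stars(wt$p.value))
}

#' Tumor-versus-normal testing across all features
#'
#' @param mat Normalized matrix (features x samples).
#' @param condition Per-sample condition labels.
#' @return Data frame: feature, U, p, stars, ordered as the input.
#' @export
tumor_vs_normal_all <- function(mat, condition) {
  rows <- lapply(rownames(mat), function(f) {
    r <- tumor_vs_normal(mat[f, ], condition)
    data.frame(feature = f, U = r$U, p = r$p, stars = r$stars,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Collapse mature miRNAs with identical sequences into one feature
#'
#' Quantification cannot apportion reads among identical mature
#' sequences; such features are summed into a single mature-sequence
#' feature and flagged ambiguous rather than split arbitrarily.
#'
#' @param counts Count matrix with mature ids as rownames.
#' @param mature_seqs Named character vector id -> mature sequence.
#' @return List: `counts` (collapsed) and `groups` data frame
#'   (feature, members, ambiguous).
#' @export
collapse_identical_matures <- function(counts, mature_seqs) {
  ids <- rownames(counts)
  seqs <- mature_seqs[ids]
  key <- ifelse(is.na(seqs), paste0("id:", ids), paste0("seq:", seqs))
  groups <- split(ids, key)
  out <- t(vapply(groups, function(g) {
    colSums(counts[g, , drop = FALSE])
  }, numeric(ncol(counts))))
  rep_ids <- vapply(groups, function(g) paste(sort(g), collapse = "|"),
                    character(1))
  rownames(out) <- rep_ids
  info <- data.frame(feature = rep_ids,
                     n_members = lengths(groups),
                     ambiguous = lengths(groups) > 1,
                     stringsAsFactors = FALSE)
  list(counts = out[order(rownames(out)), , drop = FALSE],
       groups = info[order(info$feature), , drop = FALSE])
}
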