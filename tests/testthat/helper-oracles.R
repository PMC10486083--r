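# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity by enumeration, not by the
# package's own algorithms.

# maximum nested base pairing by exhaustive recursion (no DP table)
brute_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  pairable <- function(a, b) {
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
    gu <- allow_gu && ((a == "G" && b == "U") || (a == "U" && b == "G"))
    wc || gu
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + 1L):j) {
      if (k - i > min_loop && pairable(s[i], s[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(s))
}

# optimal global affine-gap alignment score by exhaustive recursion over
# alignment moves (match/mismatch, gap-in-q, gap-in-s) with gap-state
# tracking; exponential, only for very short strings
brute_affine_score <- function(q, s, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(qc) && j > length(sc)) return(0)
    best <- -Inf
    if (i <= length(qc) && j <= length(sc)) {
      sub <- if (qc[i] == sc[j]) match else mismatch
      best <- max(best, sub + rec(i + 1, j + 1, 0L))
    }
    if (i <= length(qc)) {  # gap in subject
      cost <- gap_extend + if (state == 1L) 0 else gap_open
      best <- max(best, cost + rec(i + 1, j, 1L))
    }
    if (j <= length(sc)) {  # gap in query
      cost <- gap_extend + if (state == 2L) 0 else gap_open
      best <- max(best, cost + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Mann-Whitney U by direct pair counting (ties count 1/2)
brute_U <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# NG86 by independent enumeration: per-codon site fractions and
# pathway-averaged differences, written without the package's tables
brute_ng86 <- function(cods1, cods2) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(code[codon])
  bases <- c("A", "C", "G", "T")
  site_S <- function(codon) {
    aa <- translate1(codon)
    tot <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- b
        if (translate1(alt) == aa) tot <- tot + 1
      }
    }
    tot / 3
  }
  diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    perms <- if (length(pos) == 1) matrix(pos, 1) else {
      m <- expand.grid(rep(list(seq_along(pos)), length(pos)))
      m <- m[apply(m, 1, function(r) length(unique(r)) == length(pos)), ,
             drop = FALSE]
      t(apply(m, 1, function(r) pos[as.integer(r)]))
    }
    paths <- list()
    for (r in seq_len(nrow(perms))) {
      cur <- c1; sy <- 0; ns <- 0; ok <- TRUE
      for (p in perms[r, ]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (translate1(nxt) == "*") { ok <- FALSE; break }
        if (translate1(nxt) == translate1(cur)) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      if (ok) paths[[length(paths) + 1]] <- c(sy, ns)
    }
    if (length(paths) == 0) {
      for (r in seq_len(nrow(perms))) {
        cur <- c1; sy <- 0; ns <- 0
        for (p in perms[r, ]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (translate1(nxt) == translate1(cur)) sy <- sy + 1 else ns <- ns + 1
          cur <- nxt
        }
        paths[[length(paths) + 1]] <- c(sy, ns)
      }
    }
    colMeans(do.call(rbind, paths))
  }
  S <- mean(c(sum(vapply(cods1, site_S, 1)), sum(vapply(cods2, site_S, 1))))
  N <- 3 * length(cods1) - S
  d <- t(mapply(diffs, cods1, cods2))
  Sd <- sum(d[, 1]); Nd <- sum(d[, 2])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(pS), dN = jc(pN))
}

# seed-site scan by regex, independent of the package scanner
regex_scan <- function(mature, utr) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- strsplit(substr(chartr("T", "U", toupper(mature)), 2, 8), "")[[1]]
  core <- paste(rev(unname(comp[seed])), collapse = "")
  core <- chartr("U", "T", core)
  utr <- chartr("U", "T", toupper(utr))
  out <- list()
  st <- gregexpr(core, utr, fixed = TRUE)[[1]]
  if (st[1] == -1) return(data.frame(position = integer(0),
                                     site_type = character(0)))
  for (h in as.integer(st)) {
    a <- substr(utr, h + 7, h + 7)
    out[[length(out) + 1]] <- data.frame(
      position = h - 1L,
      site_type = if (identical(a, "A")) "8mer-1a" else "7mer-m8",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
rand_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

# small shared simulated dataset, built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(
        seed = 7, n_genes = 6, plant = c(R = 2, EJ = 2, N = 2),
        expr = list(n_tissues = 3, n_per_tissue = 4, n_tumor = 12,
                    n_normal = 12, baseline_mu = 200, fold = 4,
                    dispersion = 0.3, n_background = 40),
        surv = list(n_patients = 120, baseline_hazard = 0.001,
                    beta = log(2), censoring_rate = 0.3),
        utr = list(n_utrs = 30, utr_len = 400, n_8mer = 1, n_7mer = 1)))
    }
    cache
  }
})
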