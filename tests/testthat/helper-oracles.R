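# Independent oracles used across the suite.  Each is written from the
# definition of the operation it checks, sharing no code with the package
# implementation.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# --- exhaustive affine-gap dynamic programming (Gotoh) ---------------------
# gap of length k costs go + k * ge; N never matches.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               go = 2, ge = 1, mode = "local") {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
    for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  sc <- function(x, y) {
    if (x == y && x %in% BASES) match else mismatch
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sc(A[i], B[j])
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- if (mode == "local") max(diag_best + s, 0)
                         else diag_best + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge,
                             X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge,
                             X[i + 1, j] - go - ge)
    }
  }
  if (mode == "global") {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  } else {
    max(M, 0)
  }
}

# --- brute-force IUPAC position scan ---------------------------------------
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
          W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
          N = "N")

oracle_revcomp_pattern <- function(pat) {
  paste(rev(COMP[strsplit(pat, "")[[1]]]), collapse = "")
}

# every 0-based offset where the IUPAC pattern matches; subject N never
# matches because IUPAC sets contain only ACGT letters
oracle_pattern_offsets <- function(seq, pat) {
  S <- strsplit(seq, "")[[1]]
  P <- strsplit(pat, "")[[1]]
  w <- length(P); L <- length(S)
  if (L < w) return(integer(0))
  hits <- integer(0)
  for (p in 0:(L - w)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(S[p + k] %in% IUPAC_SETS[[P[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# both-strand motif scan: forward spelling on +, reverse complement on -;
# palindromes counted once
oracle_scan <- function(seq, pat) {
  fwd <- oracle_pattern_offsets(seq, pat)
  out <- if (length(fwd)) data.frame(offset = fwd, strand = "+") else NULL
  rc <- oracle_revcomp_pattern(pat)
  if (rc != pat) {
    rev <- oracle_pattern_offsets(seq, rc)
    if (length(rev)) out <- rbind(out, data.frame(offset = rev, strand = "-"))
  }
  if (is.null(out)) data.frame(offset = integer(0), strand = character(0))
  else out[order(out$offset, out$strand), , drop = FALSE]
}

# --- column-scan footprint oracle ------------------------------------------
# rows: character vector of equal-length gapped strings (reference first)
oracle_footprints <- function(rows, min_len) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nc <- ncol(mat)
  inv <- logical(nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    ok <- col[1] != "-" && col[1] != "N"
    if (ok) for (i in seq_along(col)[-1]) {
      if (col[i] != col[1]) { ok <- FALSE; break }
    }
    inv[j] <- ok
  }
  regions <- NULL
  j <- 1L
  while (j <= nc) {
    if (inv[j]) {
      k <- j
      while (k < nc && inv[k + 1L]) k <- k + 1L
      if (k - j + 1L >= min_len) {
        regions <- rbind(regions, c(j - 1L, k))  # 0-based half-open
      }
      j <- k + 1L
    } else j <- j + 1L
  }
  if (is.null(regions)) matrix(integer(0), 0, 2) else regions
}

# --- position-scan digestion oracle ----------------------------------------
oracle_convert <- function(seq, meth = integer(0)) {
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_along(ch)) {
    if (ch[i] == "C" && !((i - 1L) %in% meth)) ch[i] <- "T"
  }
  paste(ch, collapse = "")
}

oracle_digest <- function(amplicon, site, cut_offset, meth = integer(0)) {
  conv <- oracle_convert(amplicon, meth)
  L <- nchar(conv)
  w <- nchar(site)
  cuts <- integer(0)
  for (p in oracle_pattern_offsets(conv, site)) {
    cuts <- c(cuts, p + cut_offset)
  }
  # one double-strand break per site occurrence: bottom-strand loci are
  # distinct only when the site is not its own reverse complement
  if (oracle_revcomp_pattern(site) != site) {
    for (q in oracle_pattern_offsets(conv, oracle_revcomp_pattern(site))) {
      cuts <- c(cuts, q + w - cut_offset)
    }
  }
  cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  sort(diff(c(0L, cuts, L)))
}

# --- quadratic interval-intersection oracle --------------------------------
oracle_intersect <- function(query, subject, min_overlap = 1L) {
  n <- nrow(query)
  flags <- logical(n); bp <- integer(n)
  for (i in seq_len(n)) {
    tot <- 0L
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- min(query$end[i], subject$end[j]) -
            max(query$start[i], subject$start[j])
      if (ov >= min_overlap) {
        flags[i] <- TRUE
        tot <- tot + ov
      }
    }
    bp[i] <- tot
  }
  data.frame(overlaps = flags, overlap_bp = bp)
}

# --- closed forms ----------------------------------------------------------
# two lineages diverging independently at per-site rate r (substitution to
# one of the 3 other bases): P(site differs)
expected_pairwise_mismatch <- function(r) 2 * r * (1 - r) + (2 / 3) * r^2

# k lineages: P(an alignment column is invariant)
expected_invariant_col <- function(r, k) (1 - r)^k + 3 * (r / 3)^k

# reciprocal-overlap check between a called and a true interval
reciprocal_overlap_ok <- function(cs, ce, ts, te, frac = 0.8) {
  ov <- max(0, min(ce, te) - max(cs, ts))
  ov / (te - ts) >= frac && ov / (ce - cs) >= frac
}
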