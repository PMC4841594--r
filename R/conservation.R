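# Conserved-element (ECR) calling between two genomic intervals, plus
# BLAT-like ortholog search of element probes against other species.

# Ruzzo-Tompa all-maximal positive-scoring subsequences.  x is a numeric
# score vector; returns a matrix with columns start, end (1-based, inclusive)
# of every maximal segment with positive total, disjoint and in order.
.max_scoring_segments <- function(x) {
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  Lv <- numeric(0); Rv <- numeric(0)
  y <- 0
  k <- 1L
  while (k <= n) {
    if (x[k] <= 0) { y <- y + x[k]; k <- k + 1L; next }
    # run of positive scores becomes one candidate
    j <- k
    while (j < n && x[j + 1L] > 0) j <- j + 1L
    s <- k; e <- j
    Lc <- y; Rc <- y + sum(x[s:e])
    y <- Rc
    k <- j + 1L
    repeat {
      m <- length(starts)
      idx <- if (m) max(which(Lv < Lc), -Inf) else -Inf
      if (!is.finite(idx)) { # no candidate with smaller left score
        starts <- c(starts, s); ends <- c(ends, e)
        Lv <- c(Lv, Lc); Rv <- c(Rv, Rc)
        break
      }
      if (Rv[idx] >= Rc) {   # previous candidate dominates; keep both
        starts <- c(starts, s); ends <- c(ends, e)
        Lv <- c(Lv, Lc); Rv <- c(Rv, Rc)
        break
      }
      # merge candidate idx..current into one and retest
      s <- starts[idx]
      Lc <- Lv[idx]; Rc <- Rc
      keep <- seq_len(idx - 1L)
      starts <- starts[keep]; ends <- ends[keep]
      Lv <- Lv[keep]; Rv <- Rv[keep]
    }
  }
  cbind(start = starts, end = ends)
}

#' Call conserved elements from a global pairwise alignment
#'
#' Scans the aligned columns for maximal high-identity blocks: disjoint
#' segments within which the fraction of matching columns exceeds
#' `params$min_identity` and whose span on the reference exceeds
#' `params$min_length` bp (both strict inequalities).  Candidate segments
#' are the all-maximal positive-scoring subsequences (Ruzzo-Tompa) of the
#' per-column score `match - baseline`, with the baseline placed just
#' below `min_identity` (0.1 under it): that keeps it above the ~0.55
#' per-column identity an optimal global alignment extracts even from
#' unrelated flanking sequence, so segment boundaries stay on the true
#' edges of a conserved block; each candidate is then reported only if it
#' clears the identity and length thresholds.
#'
#' @param alignment A `"pairwise_alignment"` from [pairwise_align()], usually
#'   in `"global"` mode so the whole interval pair is covered.
#' @param params A [conservation_params()] object.
#' @return A data.frame with one row per element: `id`, `ref_start`,
#'   `ref_end`, `query_start`, `query_end` (0-based half-open on the input
#'   sequences), `length` (reference bp), `identity`, `n_columns`.  Rows are
#'   ordered 5'->3' on the reference and never overlap on the reference.
#' @export
call_conserved_elements <- function(alignment, params = conservation_params()) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  m <- as.numeric(alignment$match)
  n <- length(m)
  empty <- data.frame(id = character(0), ref_start = integer(0),
                      ref_end = integer(0), query_start = integer(0),
                      query_end = integer(0), length = integer(0),
                      identity = numeric(0), n_columns = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  baseline <- max(0.3, params$min_identity - 0.1)
  segs <- .max_scoring_segments(m - baseline)
  if (!nrow(segs)) return(empty)
  # cumulative reference / query base counts for coordinate mapping
  ra <- cumsum(ca != "-")  # ref bases up to and including column
  rb <- cumsum(cb != "-")
  off_a <- alignment$start_a
  off_b <- alignment$start_b
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, 1]; e <- segs[i, 2]
    ref_len <- ra[e] - (if (s > 1) ra[s - 1] else 0L)
    if (ref_len <= params$min_length) return(NULL)
    if (mean(m[s:e]) <= params$min_identity) return(NULL)
    data.frame(
      ref_start = off_a + (if (s > 1) ra[s - 1] else 0L),
      ref_end = off_a + ra[e],
      query_start = off_b + (if (s > 1) rb[s - 1] else 0L),
      query_end = off_b + rb[e],
      length = ref_len,
      identity = mean(m[s:e]),
      n_columns = e - s + 1L,
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  rows <- rows[order(rows$ref_start), , drop = FALSE]
  rows <- cbind(id = sprintf("CE%d", seq_len(nrow(rows))), rows,
                stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  rows
}

#' Call conserved elements between two sequences
#'
#' Convenience wrapper: globally aligns `seq_a` (reference) against `seq_b`
#' (query) and calls elements with [call_conserved_elements()].  The
#' alignment is computed in a canonical orientation internally so that
#' swapping the two inputs yields exactly the same element set with
#' reference/query intervals exchanged.
#'
#' @inheritParams pairwise_align
#' @param params A [conservation_params()] object.
#' @return As [call_conserved_elements()].
#' @export
find_conserved_elements <- function(seq_a, seq_b,
                                    params = conservation_params()) {
  swap <- seq_a > seq_b  # canonical order makes the call symmetric
  al <- if (swap) pairwise_align(seq_b, seq_a, params, mode = "global")
        else pairwise_align(seq_a, seq_b, params, mode = "global")
  el <- call_conserved_elements(al, params)
  if (swap && nrow(el)) {
    el <- data.frame(id = el$id,
                     ref_start = el$query_start, ref_end = el$query_end,
                     query_start = el$ref_start, query_end = el$ref_end,
                     length = el$length, identity = el$identity,
                     n_columns = el$n_columns, stringsAsFactors = FALSE)
    el <- el[order(el$ref_start), , drop = FALSE]
    el$id <- sprintf("CE%d", seq_len(nrow(el)))
    rownames(el) <- NULL
  }
  el
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Seed hits of probe k-mers against one orientation of the target.
.seed_hits <- function(probe, target, w) {
  L <- nchar(probe)
  starts <- seq_len(L - w + 1L)
  kmers <- substring(probe, starts, starts + w - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(NULL)
  uk <- unique(kmers[ok])
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  mt <- Biostrings::matchPDict(pd, Biostrings::DNAString(target))
  pp <- integer(0); tp <- integer(0)
  for (i in seq_along(uk)) {
    ts <- BiocGenerics::start(mt[[i]])
    if (!length(ts)) next
    ps <- starts[ok][kmers[ok] == uk[i]]
    g <- expand.grid(ps = ps, ts = ts)
    pp <- c(pp, g$ps); tp <- c(tp, g$ts)
  }
  if (!length(pp)) return(NULL)
  data.frame(ppos = pp, tpos = tp, diag = tp - pp)
}

#' Seed-and-extend ortholog search
#'
#' Searches a target sequence (both strands) for orthologous copies of a
#' probe, BLAT-style: exact `seed_word_length`-mers of the probe are hashed
#' over the target, seed hits are clustered by diagonal, and each cluster is
#' extended by local affine-gap alignment of the probe against the
#' surrounding target window.  Words containing `N` are never used as seeds
#' and `N` never matches during extension.
#'
#' @param probe,target Character scalars over ACGTN.
#' @param params A [conservation_params()] object; hits scoring below
#'   `params$min_hit_score` are dropped.
#' @param probe_id Optional label carried into the result.
#' @return A data.frame sorted by decreasing score: `probe_id`, `strand`
#'   (`"+"`/`"-"`), `target_start`, `target_end` (0-based half-open on the
#'   forward target), `score`, `identity`.
#' @export
ortholog_search <- function(probe, target, params = conservation_params(),
                            probe_id = "probe") {
  probe <- .check_dna(probe, "probe")
  target <- .check_dna(target, "target")
  w <- params$seed_word_length
  if (nchar(probe) < w) stop("probe shorter than seed word length")
  Lt <- nchar(target)
  out <- list()
  for (strand in c("+", "-")) {
    tg <- if (strand == "+") target else .revcomp(target)
    sh <- .seed_hits(probe, tg, w)
    if (is.null(sh)) next
    sh <- sh[order(sh$diag, sh$tpos), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(sh$diag) > 15 |
                            abs(diff(sh$tpos)) > nchar(probe) + 50L))
    for (g in split(sh, grp)) {
      pad <- 25L
      ws <- max(1L, min(g$tpos - (g$ppos - 1L)) - pad)
      we <- min(Lt, max(g$tpos + (nchar(probe) - g$ppos)) + pad)
      al <- pairwise_align(probe, substr(tg, ws, we), params, mode = "local")
      if (al$score < params$min_hit_score) next
      nb <- sum(strsplit(al$aligned_b, "")[[1]] != "-")
      s0 <- ws - 1L + al$start_b       # 0-based on this orientation
      e0 <- s0 + nb
      if (strand == "-") { tmp <- s0; s0 <- Lt - e0; e0 <- Lt - tmp }
      out[[length(out) + 1L]] <- data.frame(
        probe_id = probe_id, strand = strand,
        target_start = s0, target_end = e0,
        score = al$score, identity = al$identity,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(0), strand = character(0),
                      target_start = integer(0), target_end = integer(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(-hits$score, hits$target_start, hits$strand), , drop = FALSE]
  # drop hits whose target interval overlaps a better hit (duplicate seeds)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (hits$target_start[i] < hits$target_end[j] &&
          hits$target_end[i] > hits$target_start[j]) { keep[i] <- FALSE; break }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build the species-by-probe presence matrix
#'
#' Summarises ortholog-search results across species into the familiar
#' presence chart: one row per species, one column per probe, each cell the
#' best (maximum) hit score for that species/probe or `NA` when no hit was
#' found.
#'
#' @param hits A data.frame with columns `species`, `probe_id`, `score`
#'   (zero or more rows per species/probe pair), e.g. row-bound
#'   [ortholog_search()] results with a `species` column added.
#' @param species,probes Optional label vectors fixing row/column order and
#'   including species or probes with no hits at all.
#' @return A list of class `"presence_matrix"`: `matrix` (numeric, `NA` =
#'   absent), `species_per_probe` (named count of species with a hit per
#'   probe) and `mean_species_per_probe`.
#' @export
build_presence_matrix <- function(hits, species = NULL, probes = NULL) {
  stopifnot(all(c("species", "probe_id", "score") %in% names(hits)))
  species <- species %||% sort(unique(hits$species))
  probes <- probes %||% sort(unique(hits$probe_id))
  if (anyDuplicated(species) || anyDuplicated(probes)) {
    stop("species and probe labels must be unique")
  }
  m <- matrix(NA_real_, length(species), length(probes),
              dimnames = list(species, probes))
  if (nrow(hits)) {
    best <- aggregate(score ~ species + probe_id, data = hits, FUN = max)
    for (i in seq_len(nrow(best))) {
      m[best$species[i], best$probe_id[i]] <- best$score[i]
    }
  }
  cnt <- colSums(!is.na(m))
  structure(list(matrix = m,
                 species_per_probe = cnt,
                 mean_species_per_probe = if (length(cnt)) mean(cnt) else 0),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix: %d species x %d probes, mean %.2f species/probe>\n",
              nrow(x$matrix), ncol(x$matrix), x$mean_species_per_probe))
  invisible(x)
}
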