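# Enhancer chromatin-state classification: interval intersection of ECRs
# with per-tissue histone-mark peaks and hypomethylated regions.

.check_intervals <- function(x, what = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$end <= x$start | x$start < 0)) {
    stop("malformed ", what, ": need 0 <= start < end")
  }
  x
}

.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Intersect two interval sets
#'
#' Half-open interval overlap: for every query interval, reports whether it
#' overlaps any subject interval by at least `min_overlap` bp and the total
#' overlapped length.  Adjacent intervals such as `[0,10)` and `[10,20)` do
#' not overlap.
#'
#' @param query,subject Data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_overlap Minimum overlap in bp to count (default 1).
#' @return A data.frame with one row per query interval: `overlaps`
#'   (logical) and `overlap_bp` (total overlapped bases).
#' @export
intersect_intervals <- function(query, subject, min_overlap = 1L) {
  query <- .check_intervals(query, "query intervals")
  subject <- .check_intervals(subject, "subject intervals")
  n <- nrow(query)
  res <- data.frame(overlaps = logical(n), overlap_bp = integer(n))
  if (n == 0 || nrow(subject) == 0) return(res)
  hits <- GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject),
                                      minoverlap = min_overlap)
  if (!length(hits)) return(res)
  qh <- S4Vectors::queryHits(hits)
  ov <- BiocGenerics::width(GenomicRanges::pintersect(
    .as_granges(query)[qh], .as_granges(subject)[S4Vectors::subjectHits(hits)]))
  bp <- tapply(ov, qh, sum)
  idx <- as.integer(names(bp))
  res$overlaps[idx] <- TRUE
  res$overlap_bp[idx] <- as.integer(bp)
  res
}

#' Classify the enhancer chromatin state of one (element, tissue) pair
#'
#' Applies the two-mark enhancer grammar: H3K4me1 together with H3K27ac
#' marks an active enhancer; H3K4me1 alone a poised one; H3K27ac alone is
#' reported separately; neither mark means no enhancer signature.  The DNA
#' hypomethylation flag is carried alongside, as an independent line of
#' evidence.
#'
#' @param k4me1,k27ac,hypometh Logical overlap flags from
#'   [intersect_intervals()].
#' @return A list: `state` (`"ACTIVE"`, `"POISED"`, `"ACETYL_ONLY"` or
#'   `"NONE"`) and `hypomethylated`.
#' @export
classify_state <- function(k4me1, k27ac, hypometh = FALSE) {
  stopifnot(is.logical(k4me1), is.logical(k27ac), is.logical(hypometh))
  state <- if (k4me1 && k27ac) "ACTIVE"
           else if (k4me1) "POISED"
           else if (k27ac) "ACETYL_ONLY"
           else "NONE"
  list(state = state, hypomethylated = isTRUE(hypometh))
}

#' Build the per-tissue enhancer-state matrix for a set of elements
#'
#' For each element and tissue, intersects the element's interval with that
#' tissue's H3K4me1 peaks, H3K27ac peaks and hypomethylated regions, and
#' classifies the enhancer state.
#'
#' @param ecrs Data.frame of element intervals (`chrom`, `start`, `end`,
#'   `name`).
#' @param tracks A nested named list: `tracks[[tissue]]$k4me1`,
#'   `$k27ac`, `$hypometh`, each an interval data.frame (possibly empty),
#'   as produced by [generate_tissue_tracks()] or [read_track_dir()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A data.frame: `ecr`, `tissue`, `state`, `hypomethylated`.
#' @export
profile_enhancers <- function(ecrs, tracks, min_overlap = 1L) {
  ecrs <- .check_intervals(ecrs, "ECR intervals")
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out <- list()
  for (tissue in names(tracks)) {
    tr <- tracks[[tissue]]
    f4 <- intersect_intervals(ecrs, tr$k4me1 %||% empty, min_overlap)$overlaps
    fa <- intersect_intervals(ecrs, tr$k27ac %||% empty, min_overlap)$overlaps
    fh <- intersect_intervals(ecrs, tr$hypometh %||% empty, min_overlap)$overlaps
    for (i in seq_len(nrow(ecrs))) {
      cs <- classify_state(f4[i], fa[i], fh[i])
      out[[length(out) + 1L]] <- data.frame(
        ecr = ecrs$name[i], tissue = tissue, state = cs$state,
        hypomethylated = cs$hypomethylated, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call enhancer breadth (ubiquitous vs tissue-specific) per element
#'
#' Counts, per element, the tissues in which it shows enhancer evidence and
#' classifies it as `ubiquitous` (evidence in a strict majority of tissues),
#' `tissue_specific` (in at least one but not a majority) or `inactive`
#' (in none).  Evidence is configurable: histone marks (ACTIVE or POISED
#' state), DNA hypomethylation, or either (the default, since both lines of
#' evidence identify broadly active elements).
#'
#' @param profile A data.frame from [profile_enhancers()].
#' @param criterion `"either"`, `"marks"` or `"hypomethylation"`.
#' @return A data.frame, one row per element: `ecr`, `n_tissues_marked`,
#'   `n_tissues_hypomethylated`, `n_tissues_evidence`, `n_tissues_total`,
#'   `call`.
#' @export
call_breadth <- function(profile,
                         criterion = c("either", "marks", "hypomethylation")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(profile) > 0,
            all(c("ecr", "tissue", "state", "hypomethylated") %in% names(profile)))
  out <- list()
  for (e in unique(profile$ecr)) {
    sub <- profile[profile$ecr == e, , drop = FALSE]
    n_total <- nrow(sub)
    marked <- sub$state %in% c("ACTIVE", "POISED")
    hypo <- sub$hypomethylated
    evid <- switch(criterion,
                   either = marked | hypo,
                   marks = marked,
                   hypomethylation = hypo)
    n_ev <- sum(evid)
    call <- if (n_ev == 0) "inactive"
            else if (n_ev > n_total / 2) "ubiquitous"   # strict majority
            else "tissue_specific"
    out[[length(out) + 1L]] <- data.frame(
      ecr = e, n_tissues_marked = sum(marked),
      n_tissues_hypomethylated = sum(hypo),
      n_tissues_evidence = n_ev, n_tissues_total = n_total,
      call = call, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
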