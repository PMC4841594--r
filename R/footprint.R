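# Phylogenetic footprinting: reference-anchored multiple alignment of an
# ortholog set and detection of invariant sub-regions.

#' Reference-anchored multiple alignment of an ortholog set
#'
#' Aligns each non-reference sequence pairwise (global, affine gaps) against
#' the reference and merges the pairwise alignments on reference coordinates
#' into one block, the same anchoring strategy as aligning every ortholog
#' against the probe species one pair at a time.  Bases a species inserts
#' relative to the reference get their own columns (gap in every other row);
#' those columns are flagged via `ref_gap`.
#'
#' @param sequences Named character vector (or list) of sequences, one per
#'   species; names are the species labels.
#' @param reference_label Name of the reference (anchor) species.
#' @param params A [conservation_params()] object (alignment scoring).
#' @return A list of class `"multiple_alignment"`: `rows` (named character
#'   vector of equal-length gapped sequences, reference first), `reference`,
#'   `ref_gap` (logical per column: `TRUE` where the reference has a gap)
#'   and `ref_pos` (0-based reference position per column, `NA` in
#'   insertion columns).  Removing the gaps from any row reproduces that
#'   species' input sequence.
#' @export
align_ortholog_set <- function(sequences, reference_label,
                               params = conservation_params()) {
  sequences <- vapply(as.list(sequences), function(s) .check_dna(s), "")
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (!reference_label %in% names(sequences)) {
    stop("reference label '", reference_label, "' not among sequences")
  }
  ref <- sequences[[reference_label]]
  L <- nchar(ref)
  others <- setdiff(names(sequences), reference_label)
  # per species: base aligned to each ref position ("-" = deletion) and
  # insertion strings keyed by the ref base they follow (0 = before base 1)
  aligned_base <- list()
  insertions <- list()
  for (sp in others) {
    al <- pairwise_align(ref, sequences[[sp]], params, mode = "global")
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    base <- rep("-", L)
    ins <- rep("", L + 1L)
    refidx <- 0L
    for (k in seq_along(ca)) {
      if (ca[k] != "-") {
        refidx <- refidx + 1L
        base[refidx] <- cb[k]
      } else {
        ins[refidx + 1L] <- paste0(ins[refidx + 1L], cb[k])
      }
    }
    aligned_base[[sp]] <- base
    insertions[[sp]] <- ins
  }
  labels <- c(reference_label, others)
  refch <- strsplit(ref, "")[[1]]
  cols <- vector("list", 2L * L + 1L)
  flag <- vector("list", 2L * L + 1L)
  rpos <- vector("list", 2L * L + 1L)
  slot <- 0L
  emit_ins <- function(p) {
    blocks <- list()
    for (sp in others) {
      s <- insertions[[sp]][p + 1L]
      if (!nzchar(s)) next
      chars <- strsplit(s, "")[[1]]
      blk <- matrix("-", length(labels), length(chars),
                    dimnames = list(labels, NULL))
      blk[sp, ] <- chars
      blocks[[length(blocks) + 1L]] <- blk
    }
    if (!length(blocks)) return(NULL)
    do.call(cbind, blocks)
  }
  ins0 <- emit_ins(0L)
  if (!is.null(ins0)) {
    slot <- slot + 1L; cols[[slot]] <- ins0
    flag[[slot]] <- rep(TRUE, ncol(ins0)); rpos[[slot]] <- rep(NA_integer_, ncol(ins0))
  }
  for (p in seq_len(L)) {
    slot <- slot + 1L
    col <- matrix(c(refch[p],
                    vapply(others, function(sp) aligned_base[[sp]][p], "")),
                  ncol = 1, dimnames = list(labels, NULL))
    cols[[slot]] <- col; flag[[slot]] <- FALSE; rpos[[slot]] <- p - 1L
    insp <- emit_ins(p)
    if (!is.null(insp)) {
      slot <- slot + 1L; cols[[slot]] <- insp
      flag[[slot]] <- rep(TRUE, ncol(insp)); rpos[[slot]] <- rep(NA_integer_, ncol(insp))
    }
  }
  mat <- do.call(cbind, cols[seq_len(slot)])
  rows <- apply(mat, 1, paste, collapse = "")
  structure(list(rows = rows, reference = reference_label,
                 ref_gap = unlist(flag[seq_len(slot)]),
                 ref_pos = unlist(rpos[seq_len(slot)])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment: %d species x %d columns, reference '%s'>\n",
              length(x$rows), nchar(x$rows[[1]]), x$reference))
  invisible(x)
}

# alignment -> character matrix (rows = species)
.aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$rows), ""))
}

#' Detect invariant sub-regions (phylogenetic footprints)
#'
#' Finds the maximal runs of alignment columns in which every species shows
#' one identical, unambiguous, non-gap residue — the small regions without
#' any sequence variation that mark candidate transcription-factor binding
#' sites.  Runs shorter than `min_footprint_length` columns are dropped.
#'
#' @param alignment A `"multiple_alignment"` from [align_ortholog_set()].
#' @param min_footprint_length Minimum run length in columns; the default 6
#'   is the length of the shortest motif of interest (e.g. the E box).
#' @return A data.frame: `col_start`, `col_end` (0-based half-open alignment
#'   columns), `n_columns`, `ref_start`, `ref_end` (0-based half-open on the
#'   ungapped reference).
#' @export
find_invariant_regions <- function(alignment, min_footprint_length = 6L) {
  stopifnot(inherits(alignment, "multiple_alignment"),
            min_footprint_length >= 1)
  mat <- .aln_matrix(alignment)
  inv <- apply(mat, 2, function(col) {
    col[1] != "-" && col[1] != "N" && all(col == col[1])
  })
  empty <- data.frame(col_start = integer(0), col_end = integer(0),
                      n_columns = integer(0), ref_start = integer(0),
                      ref_end = integer(0))
  if (!any(inv)) return(empty)
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_footprint_length
  if (!any(keep)) return(empty)
  s <- starts[keep]; e <- ends[keep]
  data.frame(col_start = s - 1L, col_end = e,
             n_columns = e - s + 1L,
             ref_start = alignment$ref_pos[s],
             ref_end = alignment$ref_pos[e] + 1L)
}
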