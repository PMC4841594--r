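#' Conservation-calling and search parameters
#'
#' Bundles the thresholds and scoring scheme used for conserved-element
#' calling and seed-and-extend ortholog search.  The element thresholds are
#' strict inequalities: an element must be *longer than* `min_length` base
#' pairs and show identity *greater than* `min_identity`, the criteria under
#' which the ECRs of the Peg3 domain were originally defined.
#'
#' @param min_length Minimum element length in bp (strict `>`). Default 50.
#' @param min_identity Minimum fractional identity (strict `>`). Identity is
#'   defined as matches / aligned columns, where columns containing a gap
#'   count against identity. Default 0.75.
#' @param match,mismatch Per-base alignment scores. Defaults +1 / -1.
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap of
#'   length k costs `gap_open + k * gap_extend`). Defaults 2 and 1.
#' @param seed_word_length Exact-match word size for the ortholog search
#'   (BLAT-like). Default 11.
#' @param min_hit_score Minimum local-alignment score for a reported ortholog
#'   hit. Default 30.
#' @return A list of class `"conservation_params"`.
#' @export
conservation_params <- function(min_length = 50L, min_identity = 0.75,
                                match = 1, mismatch = -1,
                                gap_open = 2, gap_extend = 1,
                                seed_word_length = 11L, min_hit_score = 30) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_length >= 1, seed_word_length >= 4,
            match > 0, mismatch < match, gap_open >= 0, gap_extend >= 0)
  structure(list(min_length = as.integer(min_length),
                 min_identity = min_identity,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_word_length = as.integer(seed_word_length),
                 min_hit_score = min_hit_score),
            class = "conservation_params")
}

# Substitution matrix over A,C,G,T,N: N never matches anything (scores as a
# mismatch), per the element-calling rules.
.submat <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

.check_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (!nzchar(x)) stop(what, " is empty")
  if (grepl("[^ACGTN]", x)) stop(what, " contains non-nucleotide characters")
  x
}

#' Pairwise affine-gap alignment
#'
#' Aligns two nucleotide sequences under an affine gap model, either locally
#' (Smith-Waterman style, the mode used for ortholog hit extension) or
#' globally (Needleman-Wunsch style, used to align two genomic intervals
#' end-to-end before element calling).  `N` is allowed but never counts as a
#' match.
#'
#' @param seq_a,seq_b Character scalars over ACGTN (`seq_a` is the reference/
#'   pattern, `seq_b` the query/subject).
#' @param params A [conservation_params()] object.
#' @param mode `"local"` or `"global"`.
#' @return A list of class `"pairwise_alignment"` with elements
#'   `aligned_a`, `aligned_b` (gapped strings), `score`, `match` (logical
#'   per-column match flags), `identity` (matches / aligned columns, gaps
#'   counting against), `start_a`, `start_b` (0-based offsets of the aligned
#'   region in each input) and `mode`.
#' @export
pairwise_align <- function(seq_a, seq_b, params = conservation_params(),
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  seq_a <- .check_dna(seq_a, "seq_a")
  seq_b <- .check_dna(seq_b, "seq_b")
  sm <- .submat(params$match, params$mismatch)
  al <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b,
    type = mode, substitutionMatrix = sm,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  a <- as.character(Biostrings::alignedPattern(al))
  b <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mt <- ca == cb & ca != "-" & ca != "N"
  structure(list(
    aligned_a = a, aligned_b = b,
    score = Biostrings::score(al),
    match = mt,
    identity = if (length(mt)) mean(mt) else 0,
    start_a = al@pattern@range@start - 1L,
    start_b = al@subject@range@start - 1L,
    mode = mode), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment: %s, score %.1f, %d columns, identity %.3f>\n",
              x$mode, x$score, length(x$match), x$identity))
  invisible(x)
}
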