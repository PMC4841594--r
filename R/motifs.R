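# IUPAC motif scanning on both strands and the per-ECR motif
# frequency/enrichment matrix.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

#' Reverse-complement an IUPAC pattern
#' @param pattern Character scalar over IUPAC nucleotide codes.
#' @return The reverse-complement spelling.
#' @export
iupac_revcomp <- function(pattern) {
  ch <- rev(strsplit(toupper(pattern), "")[[1]])
  bad <- setdiff(ch, names(.IUPAC_COMP))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste(.IUPAC_COMP[ch], collapse = "")
}

# IUPAC pattern -> regex over the literal sequence alphabet.  Subject N is
# never matched: character classes are built from ACGT only.
.iupac_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(ch, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste(vapply(ch, function(c) {
    s <- .IUPAC[[c]]
    if (nchar(s) == 1) s else paste0("[", s, "]")
  }, ""), collapse = "")
}

.iupac_palindromic <- function(pattern) {
  toupper(pattern) == iupac_revcomp(pattern)
}

#' The default cis-regulatory motif library
#'
#' Ships the four motifs recurrently found in the conserved elements of the
#' Peg3 domain: the E box (CAGCTG, bound by bHLH factors such as MYOD, E47
#' and AP4), PITX2 (GGGATTA, equivalently TAATCCC on the other strand),
#' NF-kB (GGAATTTT/AAAATTCC) and RFX1 (CCATGG).  Patterns may use IUPAC
#' degeneracy; each motif is scanned on both strands, with the
#' reverse-complement spelling derived automatically.
#'
#' @param degenerate_ebox If `TRUE`, the E box is scanned as the degenerate
#'   CANNTG instead of the strict hexamer CAGCTG. Default `FALSE`.
#' @return A data.frame with columns `name`, `pattern`, `revcomp_pattern`.
#' @export
default_motif_library <- function(degenerate_ebox = FALSE) {
  lib <- data.frame(
    name = c("Ebox", "PITX2", "NFkB", "RFX1"),
    pattern = c(if (degenerate_ebox) "CANNTG" else "CAGCTG",
                "GGGATTA", "GGAATTTT", "CCATGG"),
    stringsAsFactors = FALSE)
  lib$revcomp_pattern <- vapply(lib$pattern, iupac_revcomp, "")
  lib
}

#' Scan a sequence for motif occurrences on both strands
#'
#' Reports every position where a motif pattern matches, on the forward
#' strand with the forward spelling and on the reverse strand via the
#' reverse-complement spelling scanned against the forward sequence.
#' Overlapping occurrences are all counted.  A palindromic pattern (one
#' whose reverse complement equals itself, e.g. the E box CAGCTG) yields one
#' hit per genomic position, not two.  `N` in the sequence never matches.
#'
#' @param sequence Character scalar over ACGTN.
#' @param motif_library A data.frame with columns `name` and `pattern`
#'   (IUPAC), e.g. [default_motif_library()].
#' @return A data.frame: `motif`, `offset` (0-based start on the forward
#'   sequence), `strand` (`"+"`/`"-"`).
#' @export
scan_motifs <- function(sequence, motif_library = default_motif_library()) {
  sequence <- .check_dna(sequence, "sequence")
  stopifnot(nrow(motif_library) > 0,
            all(c("name", "pattern") %in% names(motif_library)))
  out <- list()
  find_all <- function(rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  for (i in seq_len(nrow(motif_library))) {
    pat <- toupper(motif_library$pattern[i])
    fwd <- find_all(.iupac_regex(pat))
    if (length(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        motif = motif_library$name[i], offset = fwd, strand = "+",
        stringsAsFactors = FALSE)
    }
    if (!.iupac_palindromic(pat)) {
      rev <- find_all(.iupac_regex(iupac_revcomp(pat)))
      if (length(rev)) {
        out[[length(out) + 1L]] <- data.frame(
          motif = motif_library$name[i], offset = rev, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$motif, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-ECR motif frequency and enrichment matrix
#'
#' Aggregates per-species motif scans into the motif-by-element summary:
#' for each (element, motif) pair, the total number of occurrences across
#' all species carrying a sequence for that element, the number of species
#' with at least one occurrence, the per-species ratio
#' `total_hits / n_species_with_sequence`, and the enrichment flag, set when
#' the ratio is *strictly greater than* 0.5.  Species with no identified
#' ortholog for an element do not count towards its denominator.
#'
#' @param hit_counts A data.frame with columns `ecr`, `species`, `motif`,
#'   `n_hits`, containing one row per scanned (element, species, motif)
#'   triple including zero counts; see [scan_ortholog_sets()].
#' @param motif_library The motif library the scans used (fixes motif order).
#' @return A data.frame: `ecr`, `motif`, `total_hits`,
#'   `n_species_with_sequence`, `n_species_with_hit`, `ratio`, `enriched`.
#' @export
motif_frequency_matrix <- function(hit_counts,
                                   motif_library = default_motif_library()) {
  stopifnot(all(c("ecr", "species", "motif", "n_hits") %in% names(hit_counts)))
  ecrs <- unique(hit_counts$ecr)
  out <- list()
  for (e in ecrs) {
    sub <- hit_counts[hit_counts$ecr == e, , drop = FALSE]
    nsp <- length(unique(sub$species))
    if (nsp == 0) stop("no species with sequence for element ", e)
    for (m in motif_library$name) {
      ms <- sub[sub$motif == m, , drop = FALSE]
      tot <- sum(ms$n_hits)
      ratio <- tot / nsp
      out[[length(out) + 1L]] <- data.frame(
        ecr = e, motif = m, total_hits = tot,
        n_species_with_sequence = nsp,
        n_species_with_hit = sum(ms$n_hits > 0),
        ratio = ratio, enriched = ratio > 0.5,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan every sequence of per-ECR ortholog sets against a motif library
#'
#' @param ortholog_sets A named list (one entry per element) of named
#'   character vectors (one sequence per species), as returned by
#'   [read_ortholog_sets()] or [generate_ortholog_set()].
#' @param motif_library A motif library data.frame.
#' @return A data.frame of per (element, species, motif) hit counts suitable
#'   for [motif_frequency_matrix()], with zero counts included.
#' @export
scan_ortholog_sets <- function(ortholog_sets,
                               motif_library = default_motif_library()) {
  out <- list()
  for (e in names(ortholog_sets)) {
    seqs <- ortholog_sets[[e]]
    for (sp in names(seqs)) {
      hits <- scan_motifs(seqs[[sp]], motif_library)
      cnt <- table(factor(hits$motif, levels = motif_library$name))
      out[[length(out) + 1L]] <- data.frame(
        ecr = e, species = sp, motif = motif_library$name,
        n_hits = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
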