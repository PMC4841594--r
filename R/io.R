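# Plain-format I/O: multi-FASTA ortholog sets (`species|ECRn` headers),
# BED6 intervals, band tables and element/matrix TSVs.

#' Write per-element ortholog sets as multi-FASTA files
#'
#' One file per element (`<ECR>.fa`), one record per species with header
#' `species|element`.
#'
#' @param sets Named list of named character vectors (sequences by species).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_ortholog_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (e in names(sets)) {
    x <- Biostrings::DNAStringSet(unlist(sets[[e]]))
    names(x) <- paste0(names(sets[[e]]), "|", e)
    p <- file.path(dir, paste0(e, ".fa"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-element ortholog sets from multi-FASTA files
#'
#' Parses FASTA files whose record headers follow the `species|element`
#' layout, grouping records by element.
#'
#' @param path A directory containing `.fa`/`.fasta` files, or a character
#'   vector of file paths.
#' @return A named list (by element) of named character vectors (by
#'   species).
#' @export
read_ortholog_sets <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no FASTA files found in ", path)
  sets <- list()
  for (f in files) {
    x <- Biostrings::readDNAStringSet(f)
    hdr <- strsplit(names(x), "|", fixed = TRUE)
    for (i in seq_along(x)) {
      if (length(hdr[[i]]) < 2) {
        stop("header '", names(x)[i], "' is not in species|element layout")
      }
      sp <- hdr[[i]][1]; e <- hdr[[i]][2]
      sets[[e]][sp] <- as.character(x[[i]])
    }
  }
  # natural element order (ECR2 before ECR10)
  ord <- order(suppressWarnings(as.integer(gsub("\\D", "", names(sets)))),
               names(sets))
  sets[ord]
}

#' Write intervals as BED6
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` (0-based half-open, BED-compatible).
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  intervals <- .check_intervals(intervals)
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start, end = intervals$end,
                    name = intervals$name %||% ".",
                    score = intervals$score %||% 0,
                    strand = intervals$strand %||% ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval data.frame
#'
#' @param path BED3+ file (0-based half-open).
#' @return Data.frame `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cn[seq_len(min(ncol(x), 6L))]
  .check_intervals(x)
}

#' Read a directory of per-tissue track BEDs
#'
#' Expects files named `<tissue>.<mark>.bed` with mark one of `k4me1`,
#' `k27ac`, `hypometh`.
#'
#' @param dir Directory of BED files.
#' @return Nested list `[[tissue]]$k4me1/$k27ac/$hypometh`, suitable for
#'   [profile_enhancers()].
#' @export
read_track_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(k4me1|k27ac|hypometh)\\.bed$")
  if (!length(files)) stop("no track BEDs found in ", dir)
  tracks <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.bed$", "", f), ".", fixed = TRUE)[[1]]
    mark <- parts[length(parts)]
    tissue <- paste(parts[-length(parts)], collapse = ".")
    tracks[[tissue]][[mark]] <- read_bed(file.path(dir, f))
  }
  tracks
}

#' Write per-tissue tracks as BED files
#'
#' @param tracks Nested list as from [generate_tissue_tracks()].
#' @param dir Output directory.
#' @export
write_track_dir <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tissue in names(tracks)) {
    for (mark in names(tracks[[tissue]])) {
      write_bed(tracks[[tissue]][[mark]],
                file.path(dir, paste0(tissue, ".", mark, ".bed")))
    }
  }
  invisible(dir)
}

#' Write a band table as TSV
#' @param bands Data.frame `fragment_length_bp`, `intensity`.
#' @param path Output file.
#' @param header Optional comment lines (written prefixed with `#`).
#' @export
write_band_table <- function(bands, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(bands[c("fragment_length_bp", "intensity")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band table TSV
#' @param path File with columns `fragment_length_bp`, `intensity`.
#' @return Data.frame.
#' @export
read_band_table <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("fragment_length_bp", "intensity") %in% names(x)))
  x
}

#' Write a single-sequence or multi-sequence FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# TSV with provenance header lines
.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
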