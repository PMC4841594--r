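# Synthetic-data generators: every pipeline input with known ground truth.
# Ortholog sets diverge from one ancestor on a star phylogeny (independent
# lineages, uniform substitution to one of the three other bases); planted
# motif sites are copied unmutated.  Genome pairs carry planted conserved
# blocks at a controlled identity inside independent random flanks.  COBRA
# gels simulate per-molecule methylation, conversion, digestion and
# densitometry noise.  Tissue tracks emit peak files consistent with an
# assigned enhancer-state truth.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Simulation configuration
#'
#' @param seed Master seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param n_species Number of lineages for ortholog sets (>= 2).
#' @param substitution_rate Per-site substitution probability per lineage.
#' @param indel_rate Per-site single-base indel probability (default 0,
#'   indels off; indels never fall inside planted motifs).
#' @param ancestral_length Ancestor length in bp for ortholog sets.
#' @param planted_motifs List of motif plantings, each a list with
#'   `pattern` (concrete ACGT string), `position` (0-based start on the
#'   ancestor) and optional `species` (labels carrying the site; default
#'   all).  Plantings must not overlap.
#' @param n_elements Number of conserved blocks for genome pairs.
#' @param element_length Length of each planted block in bp.
#' @param element_identity Fractional identity of planted blocks.
#' @param flank_length Random flank length between/around blocks.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_species = 20L, substitution_rate = 0.05,
                       indel_rate = 0, ancestral_length = 300L,
                       planted_motifs = list(), n_elements = 3L,
                       element_length = 150L, element_identity = 0.85,
                       flank_length = 300L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            element_identity >= 0, element_identity <= 1,
            n_species >= 2, ancestral_length >= 1)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 ancestral_length = as.integer(ancestral_length),
                 planted_motifs = planted_motifs,
                 n_elements = as.integer(n_elements),
                 element_length = as.integer(element_length),
                 element_identity = element_identity,
                 flank_length = as.integer(flank_length)),
            class = "sim_config")
}

.validate_plantings <- function(motifs, length) {
  if (!length(motifs)) return(invisible())
  iv <- t(vapply(motifs, function(m) {
    stopifnot(!is.null(m$pattern), !is.null(m$position))
    if (grepl("[^ACGT]", m$pattern)) stop("planted motif must be concrete ACGT")
    w <- nchar(m$pattern)
    if (w > length) stop("motif longer than ancestral sequence")
    if (m$position < 0 || m$position + w > length) {
      stop("planted motif outside ancestral sequence")
    }
    c(m$position, m$position + w)
  }, numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    stop("overlapping planted motifs")
  }
  invisible()
}

# substitute each TRUE position to one of the 3 other bases, uniformly
.substitute <- function(ch, idx) {
  if (!length(idx)) return(ch)
  cur <- match(ch[idx], .BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  ch[idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  ch
}

# deterministically destroy every occurrence of the given IUPAC patterns
# (both strands) that does not overlap a protected interval; used so that
# planted motif counts are the exact truth of a generated sequence
.scrub_motifs <- function(seq, patterns, protected_iv = NULL) {
  for (iter in 1:12) {
    hits <- NULL
    for (p in patterns) {
      for (pat in unique(c(p, iupac_revcomp(p)))) {
        m <- gregexpr(paste0("(?=", .iupac_regex(pat), ")"), seq,
                      perl = TRUE)[[1]]
        if (m[1] == -1) next
        st <- as.integer(m) - 1L
        hits <- rbind(hits, cbind(st, st + nchar(pat)))
      }
    }
    if (is.null(hits)) return(seq)
    ch <- strsplit(seq, "")[[1]]
    changed <- FALSE
    prot <- rep(FALSE, length(ch))
    if (!is.null(protected_iv)) {
      for (i in seq_len(NROW(protected_iv))) {
        prot[(protected_iv[i, 1] + 1L):protected_iv[i, 2]] <- TRUE
      }
    }
    for (i in seq_len(nrow(hits))) {
      span <- (hits[i, 1] + 1L):hits[i, 2]
      cand <- span[!prot[span]]
      if (!length(cand)) next       # the planted site itself: keep
      # mutate the most central mutable base; transversion, deterministic
      mid <- cand[ceiling(length(cand) / 2)]
      ch[mid] <- c(A = "C", C = "A", G = "T", T = "G")[[ch[mid]]]
      changed <- TRUE
    }
    if (!changed) return(paste(ch, collapse = ""))
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Generate a diverged ortholog set with planted invariant motifs
#'
#' Evolves `n_species` sequences independently from one random ancestor
#' (star phylogeny): each site substitutes with probability
#' `substitution_rate` to one of the three other bases, except planted
#' motif sites, which are copied unmutated into every species that carries
#' them.  Species listed outside a planting's `species` set instead get the
#' site knocked out by a single deterministic substitution at its centre.
#'
#' @param config A [sim_config()].
#' @param species_labels Optional species names (default `species01`...).
#' @param scrub_patterns Optional IUPAC patterns whose *chance* occurrences
#'   (outside plantings) are destroyed in every output sequence, making the
#'   planted sites the exact motif content; used by the synthetic ortholog
#'   compendium.
#' @return A list: `sequences` (named character vector), `ancestor`, and
#'   `truth` — a data.frame of per-species motif sites (`species`,
#'   `pattern`, `start` 0-based, `present`).
#' @export
generate_ortholog_set <- function(config, species_labels = NULL,
                                  scrub_patterns = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$ancestral_length
  .validate_plantings(config$planted_motifs, L)
  set.seed(derive_seed(config$seed, 11L))
  species <- species_labels %||% sprintf("species%02d", seq_len(config$n_species))
  stopifnot(length(species) == config$n_species)
  anc <- strsplit(.random_dna(L), "")[[1]]
  protected <- rep(FALSE, L)
  for (m in config$planted_motifs) {
    w <- nchar(m$pattern)
    anc[(m$position + 1L):(m$position + w)] <- strsplit(m$pattern, "")[[1]]
    protected[(m$position + 1L):(m$position + w)] <- TRUE
  }
  seqs <- character(0)
  truth <- list()
  for (sp in species) {
    ch <- anc
    # knock out plantings this species does not carry (centre substitution)
    for (m in config$planted_motifs) {
      carriers <- m$species %||% species
      if (!sp %in% carriers) {
        mid <- m$position + nchar(m$pattern) %/% 2 + 1L
        ch[mid] <- c(A = "C", C = "A", G = "T", T = "G")[[ch[mid]]]
      }
    }
    sub_idx <- which(runif(L) < config$substitution_rate & !protected)
    ch <- .substitute(ch, sub_idx)
    # optional single-base indels, never inside planted motifs
    keep <- rep(1L, L)
    ins <- character(L)
    if (config$indel_rate > 0) {
      u <- runif(L)
      del <- u < config$indel_rate / 2 & !protected
      insm <- u >= config$indel_rate / 2 & u < config$indel_rate & !protected
      keep[del] <- 0L
      ins[insm] <- sample(.BASES, sum(insm), replace = TRUE)
    }
    pieces <- paste0(ifelse(keep == 1L, ch, ""), ins)
    sq <- paste(pieces, collapse = "")
    # species coordinate of ancestral position p (0-based):
    # bases emitted before p = cumsum of per-site emission lengths
    emitted <- keep + nchar(ins)
    offs <- c(0L, cumsum(emitted))
    for (m in config$planted_motifs) {
      carriers <- m$species %||% species
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, pattern = m$pattern,
        start = offs[m$position + 1L],
        present = sp %in% carriers, stringsAsFactors = FALSE)
    }
    if (!is.null(scrub_patterns)) {
      prot_iv <- NULL
      for (m in config$planted_motifs) {
        if (sp %in% (m$species %||% species)) {
          prot_iv <- rbind(prot_iv, c(offs[m$position + 1L],
                                      offs[m$position + 1L] + nchar(m$pattern)))
        }
      }
      sq <- .scrub_motifs(sq, scrub_patterns, prot_iv)
    }
    seqs[sp] <- sq
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(0), pattern = character(0),
               start = integer(0), present = logical(0))
  list(sequences = seqs, ancestor = paste(anc, collapse = ""), truth = truth)
}

#' Generate a genome pair with planted conserved blocks
#'
#' Builds two sequences that share `n_elements` planted blocks at
#' `element_identity`, embedded in independently random flanks: genome A
#' carries each block verbatim; genome B carries a copy with exactly
#' `round((1 - identity) * length)` substituted positions.
#'
#' @param config A [sim_config()]; uses `n_elements`, `element_length`,
#'   `element_identity`, `flank_length`, `seed`.
#' @return A list: `genome_a`, `genome_b` (characters) and `truth`, a
#'   data.frame of planted intervals (`element`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `identity`; 0-based half-open).
#' @export
generate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_elements > 0 && config$element_identity < 0.25) {
    stop("element_identity < 0.25 is indistinguishable from background")
  }
  set.seed(derive_seed(config$seed, 13L))
  n <- config$n_elements
  w <- config$element_length
  fl <- config$flank_length
  blocks <- replicate(n, .random_dna(w))
  ga <- character(0); gb <- character(0)
  truth <- list()
  pos_a <- 0L; pos_b <- 0L
  n_sub <- round((1 - config$element_identity) * w)
  for (i in seq_len(n + 1L)) {
    fa <- .random_dna(fl); fb <- .random_dna(fl)
    ga <- c(ga, fa); gb <- c(gb, fb)
    pos_a <- pos_a + fl; pos_b <- pos_b + fl
    if (i > n) break
    ba <- blocks[i]
    ch <- strsplit(ba, "")[[1]]
    ch <- .substitute(ch, sample.int(w, n_sub))
    bb <- paste(ch, collapse = "")
    ga <- c(ga, ba); gb <- c(gb, bb)
    truth[[i]] <- data.frame(
      element = sprintf("block%d", i),
      start_a = pos_a, end_a = pos_a + w,
      start_b = pos_b, end_b = pos_b + w,
      identity = 1 - n_sub / w, stringsAsFactors = FALSE)
    pos_a <- pos_a + w; pos_b <- pos_b + w
  }
  list(genome_a = paste(ga, collapse = ""),
       genome_b = paste(gb, collapse = ""),
       truth = if (n) do.call(rbind, truth) else
         data.frame(element = character(0), start_a = integer(0),
                    end_a = integer(0), start_b = integer(0),
                    end_b = integer(0), identity = numeric(0)))
}

#' Simulate a COBRA gel for an amplicon with known methylation
#'
#' Simulates `n_molecules` alleles of the amplicon, methylating each CpG
#' independently at its given fraction, bisulfite-converting and digesting
#' each molecule, binning fragments by length, and adding multiplicative
#' Gaussian densitometry noise to each band.
#'
#' @param amplicon Amplicon sequence in the genomic frame.
#' @param methylation_fraction Scalar (applied to every CpG) or vector of
#'   per-CpG methylation probabilities, in CpG order.
#' @param enzyme Enzyme name or spec; must be informative for the amplicon.
#' @param n_molecules Number of simulated molecules (default 10000).
#' @param noise_sd Multiplicative band-intensity noise SD (default 0.02).
#' @param seed Seed for this gel.
#' @return A data.frame of class `"band_table"`: `fragment_length_bp`,
#'   `intensity`; attribute `truth` holds the per-CpG fractions.
#' @export
generate_cobra_gel <- function(amplicon, methylation_fraction, enzyme,
                               n_molecules = 10000L, noise_sd = 0.02,
                               seed = 1L) {
  amplicon <- .check_dna(amplicon, "amplicon")
  stopifnot(noise_sd >= 0, n_molecules >= 1,
            all(methylation_fraction >= 0), all(methylation_fraction <= 1))
  cls <- classify_enzyme(enzyme, amplicon)
  if (cls$class == "uninformative") {
    stop("enzyme ", cls$enzyme, " is uninformative for this amplicon")
  }
  cpgs <- .cpg_positions(amplicon)
  frac <- rep_len(methylation_fraction, length(cpgs))
  set.seed(derive_seed(seed, 17L))
  # only CpGs that alter the cut pattern matter for the fragment spectrum
  rel <- which(cpgs %in% cls$assayed_cpgs)
  if (!length(rel)) rel <- seq_along(cpgs)[0]
  if (length(rel)) {
    meth <- matrix(runif(n_molecules * length(rel)) <
                     rep(frac[rel], each = n_molecules),
                   nrow = n_molecules)
    code <- as.integer(meth %*% 2^(seq_along(rel) - 1L))
    counts <- tabulate(code + 1L, 2L^length(rel))
  } else {
    counts <- n_molecules
  }
  acc <- new.env()
  add <- function(frags, k) {
    for (f in frags) {
      key <- as.character(f)
      acc[[key]] <- (acc[[key]] %||% 0) + k
    }
  }
  for (pat in seq_along(counts)) {
    if (counts[pat] == 0) next
    bits <- as.logical(bitwAnd(pat - 1L, 2L^(seq_along(rel) - 1L)))
    m_set <- cpgs[rel][bits]
    add(digest_amplicon(amplicon, enzyme, methylated_cpgs = m_set),
        counts[pat])
  }
  keys <- sort(as.integer(ls(acc)))
  intensity <- vapply(as.character(keys), function(k) acc[[k]], 0)
  if (noise_sd > 0) {
    intensity <- pmax(0, intensity * (1 + rnorm(length(intensity), 0, noise_sd)))
  }
  out <- data.frame(fragment_length_bp = keys, intensity = unname(intensity))
  attr(out, "truth") <- setNames(frac, cpgs)
  attr(out, "enzyme") <- cls$enzyme
  attr(out, "seed") <- seed
  class(out) <- c("band_table", "data.frame")
  out
}

#' Generate per-tissue histone-mark and hypomethylation tracks
#'
#' Emits, for each tissue, H3K4me1 and H3K27ac peak sets and hypomethylated
#' regions consistent with an assigned enhancer-state truth: ACTIVE
#' elements get both marks, POISED only H3K4me1, ACETYL_ONLY only H3K27ac,
#' NONE no overlapping peak.  Peak edges are jittered by up to `jitter` bp
#' (elements must be spaced more than `2 * jitter` apart for the truth to
#' round-trip exactly).
#'
#' @param ecr_intervals Data.frame `chrom`, `start`, `end`, `name`.
#' @param state_assignment Data.frame `ecr`, `tissue`, `state`,
#'   `hypomethylated` covering every (element, tissue) pair.
#' @param seed Seed for the jitter stream.
#' @param jitter Maximum peak-edge extension in bp (default 30).
#' @return A list: `tracks` (nested list `[[tissue]]$k4me1/$k27ac/$hypometh`
#'   interval data.frames) and `truth` (the state assignment).
#' @export
generate_tissue_tracks <- function(ecr_intervals, state_assignment,
                                   seed = 1L, jitter = 30L) {
  ecr_intervals <- .check_intervals(ecr_intervals, "ECR intervals")
  stopifnot(all(c("ecr", "tissue", "state", "hypomethylated") %in%
                  names(state_assignment)),
            all(state_assignment$state %in%
                  c("ACTIVE", "POISED", "ACETYL_ONLY", "NONE")))
  tissues <- unique(state_assignment$tissue)
  if (!length(tissues)) stop("tissue list is empty")
  set.seed(derive_seed(seed, 19L))
  mk_peak <- function(row) {
    data.frame(chrom = row$chrom,
               start = max(0L, row$start - sample.int(jitter, 1L)),
               end = row$end + sample.int(jitter, 1L))
  }
  tracks <- list()
  for (ts in tissues) {
    sub <- state_assignment[state_assignment$tissue == ts, , drop = FALSE]
    k4 <- list(); ka <- list(); hm <- list()
    for (i in seq_len(nrow(sub))) {
      row <- ecr_intervals[ecr_intervals$name == sub$ecr[i], , drop = FALSE]
      if (!nrow(row)) stop("state assignment names unknown element ", sub$ecr[i])
      st <- sub$state[i]
      if (st %in% c("ACTIVE", "POISED")) k4[[length(k4) + 1L]] <- mk_peak(row)
      if (st %in% c("ACTIVE", "ACETYL_ONLY")) ka[[length(ka) + 1L]] <- mk_peak(row)
      if (sub$hypomethylated[i]) hm[[length(hm) + 1L]] <- mk_peak(row)
    }
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
    tracks[[ts]] <- list(
      k4me1 = if (length(k4)) do.call(rbind, k4) else empty,
      k27ac = if (length(ka)) do.call(rbind, ka) else empty,
      hypometh = if (length(hm)) do.call(rbind, hm) else empty)
  }
  list(tracks = tracks, truth = state_assignment)
}
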