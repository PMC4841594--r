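# In-silico COBRA (Combined Bisulfite Restriction Analysis): bisulfite
# conversion, amplicon extraction, enzyme informativeness, digestion
# prediction, densitometric quantification, and hypo/hyper calling.

#' The default COBRA restriction-enzyme library
#'
#' Ships the enzymes used to read CpG methylation after bisulfite
#' conversion.  FokI (GGATG) and HphI (GGTGA) are the TG-class exemplars:
#' their post-conversion site is completed by a *converted* (unmethylated)
#' CpG, so digestion indicates unmethylation.  TaqI (TCGA), BstUI (CGCG) and
#' HpyCH4IV (ACGT) are CG-class candidates: their site requires a *retained*
#' CpG, so digestion indicates methylation.  The actual informativeness
#' class is always derived per amplicon with [classify_enzyme()], never
#' taken from these labels.
#'
#' @return A data.frame: `name`, `site` (IUPAC recognition sequence),
#'   `cut_offset` (bp from the site start, on the strand of the match, at
#'   which the cut falls; may exceed the site length for offset cutters
#'   such as FokI).
#' @export
default_enzyme_library <- function() {
  data.frame(
    name = c("FokI", "HphI", "TaqI", "BstUI", "HpyCH4IV"),
    site = c("GGATG", "GGTGA", "TCGA", "CGCG", "ACGT"),
    cut_offset = c(14L, 13L, 1L, 2L, 1L),  # FokI GGATG(9), HphI GGTGA(8)
    stringsAsFactors = FALSE)
}

.enzyme_spec <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1) {
    lib <- default_enzyme_library()
    i <- match(enzyme, lib$name)
    if (is.na(i)) stop("unknown enzyme: ", enzyme)
    enzyme <- as.list(lib[i, ])
  }
  stopifnot(all(c("name", "site", "cut_offset") %in% names(enzyme)))
  enzyme
}

.cpg_positions <- function(sequence) {
  m <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Bisulfite conversion of a sequence
#'
#' Converts every unmethylated cytosine to thymine (read-out of the
#' chemical C->U deamination), retaining cytosines at methylated CpG sites.
#' Conversion operates on one strand at a time; the bottom strand is
#' converted on its own sense (the result is the converted bottom strand,
#' 5'->3').
#'
#' @param sequence Character scalar over ACGTN (top-strand, genomic frame).
#' @param methylated_cpgs Integer vector of 0-based start positions (on the
#'   top strand) of methylated CpG dinucleotides. Default none.
#' @param strand `"top"` (default) or `"bottom"`.
#' @param failure_rate Per-cytosine probability that conversion fails
#'   (leaving C); default 0, complete conversion. Requires `seed` when > 0.
#' @param seed Seed for the conversion-failure stream.
#' @return The converted sequence (character scalar).
#' @export
bisulfite_convert <- function(sequence, methylated_cpgs = integer(0),
                              strand = c("top", "bottom"),
                              failure_rate = 0, seed = NULL) {
  strand <- match.arg(strand)
  sequence <- .check_dna(sequence)
  L <- nchar(sequence)
  cpgs <- .cpg_positions(sequence)
  if (length(methylated_cpgs) && !all(methylated_cpgs %in% cpgs)) {
    stop("methylated position(s) not at a CpG dinucleotide")
  }
  if (strand == "bottom") {
    # the bottom strand's C of a CpG sits opposite the top strand's G
    bot <- .revcomp(sequence)
    bot_meth <- if (length(methylated_cpgs)) L - 2L - methylated_cpgs else integer(0)
    return(bisulfite_convert(bot, sort(bot_meth), "top", failure_rate, seed))
  }
  ch <- strsplit(sequence, "")[[1]]
  protect <- rep(FALSE, L)
  protect[methylated_cpgs + 1L] <- TRUE
  is_c <- ch == "C"
  convert <- is_c & !protect
  if (failure_rate > 0) {
    if (is.null(seed)) stop("failure_rate > 0 requires a seed")
    set.seed(derive_seed(seed, 7L))
    fails <- runif(L) < failure_rate
    convert <- convert & !fails
  }
  ch[convert] <- "T"
  paste(ch, collapse = "")
}

#' In-silico PCR on a bisulfite-converted template
#'
#' Locates the primer pair on the converted template and returns the unique
#' amplicon between (and including) the primer sites.  Primers must be
#' CpG-free in the original genomic frame — a primer overlapping a CpG
#' anneals differently depending on that CpG's methylation state and is
#' rejected.
#'
#' @param converted_template Converted top-strand sequence (character).
#' @param forward_primer,reverse_primer Primer sequences, 5'->3'; the
#'   reverse primer is given on the bottom strand as usual.
#' @param cpg_sites 0-based CpG start positions of the *unconverted*
#'   template, used for the CpG-in-primer check (optional but recommended).
#' @return A list: `amplicon` (character), `start`, `end` (0-based half-open
#'   on the template).
#' @export
in_silico_pcr <- function(converted_template, forward_primer, reverse_primer,
                          cpg_sites = integer(0)) {
  converted_template <- .check_dna(converted_template, "template")
  fwd <- .check_dna(forward_primer, "forward primer")
  rev <- .check_dna(reverse_primer, "reverse primer")
  find1 <- function(pat, label) {
    m <- gregexpr(pat, converted_template, fixed = TRUE)[[1]]
    if (m[1] == -1) stop(label, " primer has no binding site")
    if (length(m) > 1) stop(label, " primer is non-unique (", length(m), " sites)")
    as.integer(m) - 1L
  }
  fs <- find1(fwd, "forward")
  rv <- .revcomp(rev)
  rs <- find1(rv, "reverse")
  a_start <- fs
  a_end <- rs + nchar(rv)
  if (a_end <= a_start + nchar(fwd)) stop("primers do not flank an amplicon")
  for (p in cpg_sites) {
    if ((p < a_start + nchar(fwd) && p + 2L > a_start) ||
        (p < a_end && p + 2L > rs)) {
      stop("CpG in primer: primer overlaps CpG at position ", p)
    }
  }
  list(amplicon = substr(converted_template, a_start + 1L, a_end),
       start = a_start, end = a_end)
}

# All recognition-site occurrences of an enzyme on double-stranded DNA, as
# cut positions (0-based; cut falls before that position on the top strand).
.cut_positions <- function(dsdna, enzyme) {
  enzyme <- .enzyme_spec(enzyme)
  L <- nchar(dsdna)
  rx <- .iupac_regex(enzyme$site)
  wlen <- nchar(enzyme$site)
  find_all <- function(s) {
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  fwd <- find_all(dsdna)
  cuts <- fwd + enzyme$cut_offset
  if (!.iupac_palindromic(enzyme$site)) {
    # bottom-strand occurrences are distinct loci only for non-palindromic
    # sites; one double-strand break per occurrence, cut position taken on
    # the strand carrying the site and mapped to top coordinates
    rev <- find_all(.revcomp(dsdna))
    cuts <- c(cuts, L - rev - enzyme$cut_offset)
  }
  inside <- cuts > 0 & cuts < L
  if (any(!inside)) {
    warning("cut position outside amplicon for ", enzyme$name,
            "; site(s) skipped")
  }
  sort(unique(cuts[inside]))
}

#' Classify a restriction enzyme's informativeness for an amplicon
#'
#' Compares the enzyme's recognition sites between the two extreme
#' conversions of the amplicon: fully unmethylated (every CpG reads TG) and
#' fully methylated (every CpG retained as CG).  Sites existing only under
#' unmethylated conversion make the enzyme unmethylation-indicating
#' (TG class, e.g. FokI, HphI: digestion means the CpG was unmethylated);
#' sites existing only under methylated conversion make it
#' methylation-indicating (CG class, e.g. TaqI: digestion means
#' methylation).  An enzyme with differential sites of both kinds, or none,
#' is uninformative for this amplicon.
#'
#' @param enzyme An enzyme name from [default_enzyme_library()] or a list
#'   with `name`, `site`, `cut_offset`.
#' @param amplicon The amplicon in the genomic (unconverted) frame.
#' @return A list of class `"enzyme_classification"`: `enzyme`, `class`
#'   (one of `"unmethylation_indicating"`, `"methylation_indicating"`,
#'   `"uninformative"`), `assayed_cpgs` (0-based CpG starts overlapped by
#'   the differential sites), `cuts_u`, `cuts_m` (cut positions under the
#'   two conversions).
#' @export
classify_enzyme <- function(enzyme, amplicon) {
  enzyme <- .enzyme_spec(enzyme)
  amplicon <- .check_dna(amplicon, "amplicon")
  cpgs <- .cpg_positions(amplicon)
  conv_u <- bisulfite_convert(amplicon)                     # all CpGs convert
  conv_m <- bisulfite_convert(amplicon, methylated_cpgs = cpgs)
  cuts_u <- .cut_positions(conv_u, enzyme)
  cuts_m <- .cut_positions(conv_m, enzyme)
  u_only <- setdiff(cuts_u, cuts_m)
  m_only <- setdiff(cuts_m, cuts_u)
  cls <- if (length(u_only) && !length(m_only)) "unmethylation_indicating"
         else if (length(m_only) && !length(u_only)) "methylation_indicating"
         else "uninformative"
  diff_cuts <- c(u_only, m_only)
  wlen <- nchar(enzyme$site)
  # CpGs near a differential cut: those whose toggling changes the site
  assayed <- cpgs[vapply(cpgs, function(p) {
    cu <- .cut_positions(bisulfite_convert(amplicon, methylated_cpgs = p),
                         enzyme)
    !setequal(cu, cuts_u)
  }, TRUE)]
  structure(list(enzyme = enzyme$name, class = cls,
                 assayed_cpgs = assayed,
                 cuts_u = cuts_u, cuts_m = cuts_m),
            class = "enzyme_classification")
}

#' Predict restriction fragments of a converted amplicon
#'
#' Converts the amplicon under the given methylation state, locates all
#' recognition sites on both strands of the resulting (PCR double-stranded)
#' product, cuts at the enzyme's offset, and returns the fragment lengths.
#' Sites whose cut would fall outside the amplicon are skipped with a
#' warning.
#'
#' @param amplicon The amplicon in the genomic (unconverted) frame.
#' @param enzyme Enzyme name or spec (see [classify_enzyme()]).
#' @param methylated_cpgs 0-based starts of methylated CpGs.
#' @return Sorted integer vector of fragment lengths; always sums to the
#'   amplicon length.
#' @export
digest_amplicon <- function(amplicon, enzyme, methylated_cpgs = integer(0)) {
  amplicon <- .check_dna(amplicon, "amplicon")
  conv <- bisulfite_convert(amplicon, methylated_cpgs = methylated_cpgs)
  cuts <- .cut_positions(conv, enzyme)
  L <- nchar(amplicon)
  sort(diff(c(0L, cuts, L)))
}

# match band lengths to a reference length set within +/- tol bp
.match_lengths <- function(x, ref, tol = 2L) {
  vapply(x, function(l) any(abs(l - ref) <= tol), TRUE)
}

#' Set up a COBRA assay for one locus
#'
#' Derives everything needed to read a gel for one amplicon/enzyme pair:
#' the enzyme's informativeness class, the assayed CpGs, and the expected
#' fragment-length sets of the fully unmethylated (U) and fully methylated
#' (M) alleles.
#'
#' @inheritParams classify_enzyme
#' @param locus Label carried into reports.
#' @return A list of class `"cobra_assay"`.
#' @export
cobra_assay <- function(amplicon, enzyme, locus = "locus") {
  amplicon <- .check_dna(amplicon, "amplicon")
  cls <- classify_enzyme(enzyme, amplicon)
  if (cls$class == "uninformative") {
    stop("enzyme ", cls$enzyme, " is uninformative for this amplicon")
  }
  cpgs <- .cpg_positions(amplicon)
  structure(list(
    locus = locus, amplicon = amplicon, enzyme = cls$enzyme,
    class = cls$class, assayed_cpgs = cls$assayed_cpgs,
    frags_u = digest_amplicon(amplicon, enzyme),
    frags_m = digest_amplicon(amplicon, enzyme, methylated_cpgs = cpgs)),
    class = "cobra_assay")
}

#' Quantify percent methylation from a band table
#'
#' Densitometric read-out: bands are partitioned into the fragment sets
#' expected of the fully methylated (M) and fully unmethylated (U) alleles
#' (within a gel tolerance of +/- `tol` bp; bands common to both alleles are
#' uninformative and ignored).  Intensities are molecule counts per
#' fragment, so each allele's molecule count is its allele-specific
#' intensity divided by the number of allele-specific fragments, and
#' percent methylation is `100 * M / (M + U)`.  For a CG-class
#' (methylation-indicating) enzyme the M allele is the digested one; for a
#' TG-class enzyme it is the undigested one — both cases reduce to the same
#' allele arithmetic.
#'
#' @param bands A data.frame with columns `fragment_length_bp`, `intensity`.
#' @param assay A `"cobra_assay"` from [cobra_assay()].
#' @param tol Gel length tolerance in bp (default 2).
#' @return Percent methylation in `[0, 100]`.
#' @export
quantify_methylation <- function(bands, assay, tol = 2L) {
  stopifnot(inherits(assay, "cobra_assay"),
            all(c("fragment_length_bp", "intensity") %in% names(bands)))
  if (any(bands$intensity < 0)) stop("negative band intensity")
  total <- sum(bands$intensity)
  if (total <= 0) stop("total band intensity is zero")
  u_spec <- assay$frags_u[!.match_lengths(assay$frags_u, assay$frags_m, tol)]
  m_spec <- assay$frags_m[!.match_lengths(assay$frags_m, assay$frags_u, tol)]
  in_u <- .match_lengths(bands$fragment_length_bp, u_spec, tol)
  in_m <- .match_lengths(bands$fragment_length_bp, m_spec, tol)
  shared <- .match_lengths(bands$fragment_length_bp,
                           intersect_tol(assay$frags_u, assay$frags_m, tol), tol)
  if (any(!in_u & !in_m & !shared & bands$intensity > 0)) {
    stop("band(s) match neither allele's expected fragment lengths")
  }
  u_mol <- sum(bands$intensity[in_u & !in_m]) / max(1L, length(u_spec))
  m_mol <- sum(bands$intensity[in_m & !in_u]) / max(1L, length(m_spec))
  if (u_mol + m_mol <= 0) stop("no allele-specific band intensity")
  100 * m_mol / (m_mol + u_mol)
}

# lengths present in both sets within tolerance
intersect_tol <- function(a, b, tol = 2L) {
  a[.match_lengths(a, b, tol)]
}

#' Call differential methylation against a normal reference
#'
#' Compares replicate percent-methylation measurements of a sample against
#' a matched normal.  The verdict is `hypermethylation` or
#' `hypomethylation` only when the mean difference exceeds `min_delta`
#' percentage points in magnitude *and* a two-sided Welch test rejects at
#' `alpha`; otherwise `unchanged`.
#'
#' @param sample_replicates,normal_replicates Numeric vectors of percent
#'   methylation (at least 2 each).
#' @param alpha Significance level (default 0.05).
#' @param min_delta Minimum mean difference in percentage points (default 10).
#' @return A list of class `"methylation_call"`: `verdict`, `delta`
#'   (sample mean minus normal mean), `p_value`, `sample_mean`,
#'   `normal_mean`.
#' @export
call_delta <- function(sample_replicates, normal_replicates,
                       alpha = 0.05, min_delta = 10) {
  if (length(sample_replicates) < 2 || length(normal_replicates) < 2) {
    stop("need at least 2 replicates per group")
  }
  delta <- mean(sample_replicates) - mean(normal_replicates)
  p <- if (isTRUE(all.equal(var(sample_replicates) + var(normal_replicates), 0))) {
    if (abs(delta) > 0) 0 else 1   # degenerate: identical constant groups
  } else {
    stats::t.test(sample_replicates, normal_replicates)$p.value
  }
  verdict <- if (abs(delta) > min_delta && p < alpha) {
    if (delta > 0) "hypermethylation" else "hypomethylation"
  } else "unchanged"
  structure(list(verdict = verdict, delta = delta, p_value = p,
                 sample_mean = mean(sample_replicates),
                 normal_mean = mean(normal_replicates)),
            class = "methylation_call")
}
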