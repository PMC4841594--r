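# deterministic designed amplicons: flanks free of C so the inserted
# context holds the only CpG(s)
fok_amplicon <- function(len = 140, at = 60) {
  set.seed(777)
  bg <- function(n) paste(sample(c("A", "T", "G"), n, replace = TRUE),
                          collapse = "")
  paste0(bg(at), "GGACG", bg(len - at - 5))
}

taq_amplicon <- function(len = 120, at = 50) {
  set.seed(778)
  bg <- function(n) paste(sample(c("A", "T", "G"), n, replace = TRUE),
                          collapse = "")
  paste0(bg(at), "TCGA", bg(len - at - 4))
}

test_that("bisulfite conversion follows the CpG protection rule", {
  expect_equal(bisulfite_convert("ACCGT"), "ATTGT")
  expect_equal(bisulfite_convert("ACCGT", methylated_cpgs = 2L), "ATCGT")
  expect_equal(bisulfite_convert("AGGTT"), "AGGTT")  # no C: unchanged
  expect_error(bisulfite_convert("ACCGT", methylated_cpgs = 1L), "CpG")
})

test_that("bottom-strand conversion works on the bottom strand's own sense", {
  # top TTACGAA -> bottom 5'->3' TTCGTAA; its CpG pairs the top one
  expect_equal(bisulfite_convert("TTACGAA", strand = "bottom"), "TTTGTAA")
  expect_equal(bisulfite_convert("TTACGAA", methylated_cpgs = 3L,
                                 strand = "bottom"), "TTCGTAA")
})

test_that("conversion is idempotent on fully converted sequence", {
  set.seed(61)
  for (i in 1:10) {
    s <- random_dna(100)
    conv <- bisulfite_convert(s)
    expect_equal(bisulfite_convert(conv), conv)
  }
})

test_that("in-silico PCR extracts the unique amplicon", {
  amp <- fok_amplicon(300, 100)
  conv <- bisulfite_convert(amp)
  fwd <- substr(conv, 1, 20)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(conv, 281, 300))))
  res <- in_silico_pcr(conv, fwd, rev)
  expect_equal(nchar(res$amplicon), 300)
  expect_equal(res$start, 0)
  expect_equal(res$end, 300)
})

test_that("in-silico PCR rejects CpG-overlapping and non-unique primers", {
  amp <- fok_amplicon(300, 100)
  conv_m <- bisulfite_convert(amp, methylated_cpgs = 100L + 3L)
  # primer across the retained CpG (positions 95..114 cover CpG at 103)
  expect_error(
    in_silico_pcr(conv_m, substr(conv_m, 96, 115),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(substr(conv_m, 281, 300)))),
                  cpg_sites = 103L),
    "CpG in primer")
  dup <- paste0(strrep("ACGTT", 8), "AAATTTGGG", strrep("ACGTT", 8))
  expect_error(in_silico_pcr(dup, "ACGTTACGTT", "AAA"), "non-unique")
  expect_error(in_silico_pcr("ACGTACGT", "GGGGGG", "CCCC"), "no binding site")
})

test_that("FokI is unmethylation-indicating when conversion creates its site", {
  cls <- classify_enzyme("FokI", fok_amplicon())
  expect_equal(cls$class, "unmethylation_indicating")
  expect_equal(cls$assayed_cpgs, 63)  # the CpG inside GGACG at offset 60+3
})

test_that("TaqI is methylation-indicating when its site needs a retained CpG", {
  cls <- classify_enzyme("TaqI", taq_amplicon())
  expect_equal(cls$class, "methylation_indicating")
  expect_equal(cls$assayed_cpgs, 51)
})

test_that("an enzyme without CpG-dependent sites is uninformative", {
  set.seed(779)
  amp <- paste(sample(c("A", "T", "G"), 150, replace = TRUE), collapse = "")
  cls <- classify_enzyme("TaqI", amp)
  expect_equal(cls$class, "uninformative")
  expect_error(cobra_assay(amp, "TaqI"), "uninformative")
})

test_that("digestion fragments are positioned and conserved correctly", {
  amp <- taq_amplicon(300, 118)  # TCGA at 118, methylated cut at 119
  frags <- digest_amplicon(amp, "TaqI",
                           methylated_cpgs = 119L)
  expect_equal(sum(frags), 300)
  expect_equal(length(frags), 2)
  frags_u <- digest_amplicon(amp, "TaqI")
  expect_equal(frags_u, 300)  # unmethylated allele: site destroyed, uncut
})

test_that("digestion equals the position-scan oracle on random amplicons", {
  set.seed(62)
  lib <- default_enzyme_library()
  for (i in 1:120) {
    amp <- random_dna(sample(80:200, 1))
    cpgs <- gregexpr("(?=CG)", amp, perl = TRUE)[[1]]
    cpgs <- if (cpgs[1] == -1) integer(0) else as.integer(cpgs) - 1L
    meth <- cpgs[runif(length(cpgs)) < 0.5]
    ez <- lib[sample(nrow(lib), 1), ]
    got <- suppressWarnings(
      digest_amplicon(amp, ez$name, methylated_cpgs = meth))
    exp <- oracle_digest(amp, ez$site, ez$cut_offset, meth)
    expect_equal(got, exp, info = paste(ez$name, i))
    expect_equal(sum(got), nchar(amp))
  }
})

test_that("quantification reads a half-and-half gel as 50 percent", {
  amp <- taq_amplicon(300, 118)
  assay <- cobra_assay(amp, "TaqI")
  # 50 uncut molecules; 50 cut molecules each yielding both fragments
  bands <- data.frame(fragment_length_bp = c(300, 120, 180),
                      intensity = c(50, 50, 50))
  expect_equal(quantify_methylation(bands, assay), 50)
})

test_that("a fully digested TG-class gel reads as 0 percent methylation", {
  amp <- fok_amplicon()
  assay <- cobra_assay(amp, "FokI")
  expect_equal(assay$class, "unmethylation_indicating")
  bands <- data.frame(fragment_length_bp = assay$frags_u,
                      intensity = rep(100, length(assay$frags_u)))
  expect_equal(quantify_methylation(bands, assay), 0)
})

test_that("unexpected bands and empty gels are rejected", {
  amp <- fok_amplicon()
  assay <- cobra_assay(amp, "FokI")
  expect_error(quantify_methylation(
    data.frame(fragment_length_bp = 999, intensity = 10), assay), "neither")
  expect_error(quantify_methylation(
    data.frame(fragment_length_bp = 140, intensity = 0), assay), "zero")
})

test_that("simulated gels recover the true methylation fraction", {
  amp <- fok_amplicon()
  assay <- cobra_assay(amp, "FokI")
  gel <- generate_cobra_gel(amp, 0.3, "FokI", n_molecules = 10000,
                            noise_sd = 0.02, seed = 63)
  expect_lt(abs(quantify_methylation(gel, assay) - 30), 3)
})

test_that("fractions 0 and 1 are recovered exactly at zero noise", {
  amp <- taq_amplicon()
  assay <- cobra_assay(amp, "TaqI")
  g0 <- generate_cobra_gel(amp, 0, "TaqI", n_molecules = 1000,
                           noise_sd = 0, seed = 1)
  expect_equal(quantify_methylation(g0, assay), 0)
  g1 <- generate_cobra_gel(amp, 1, "TaqI", n_molecules = 1000,
                           noise_sd = 0, seed = 1)
  expect_equal(quantify_methylation(g1, assay), 100)
})

test_that("TG-class and CG-class enzymes agree on the same truth", {
  # one amplicon carrying both a FokI-creating and a TaqI-requiring CpG
  set.seed(780)
  bg <- function(n) paste(sample(c("A", "T", "G"), n, replace = TRUE),
                          collapse = "")
  amp <- paste0(bg(40), "GGACG", bg(40), "TCGA", bg(40))
  for (enz in c("FokI", "TaqI")) {
    assay <- cobra_assay(amp, enz)
    gel <- generate_cobra_gel(amp, 0.4, enz, n_molecules = 10000,
                              noise_sd = 0.02, seed = 64)
    expect_lt(abs(quantify_methylation(gel, assay) - 40), 3, )
  }
})

test_that("delta calling follows the joint magnitude-and-significance rule", {
  up <- call_delta(c(58, 62, 60), c(4, 6, 5))
  expect_equal(up$verdict, "hypermethylation")
  down <- call_delta(c(4, 6, 5), c(58, 62, 60))
  expect_equal(down$verdict, "hypomethylation")
  same <- call_delta(c(50, 52, 51), c(50, 52, 51))
  expect_equal(same$verdict, "unchanged")
  # large but insignificant, and significant but small, both stay unchanged
  expect_equal(call_delta(c(10, 90), c(30, 40))$verdict, "unchanged")
  expect_equal(call_delta(c(50, 51, 50.5), c(48, 49, 48.5))$verdict,
               "unchanged")
  expect_error(call_delta(50, c(1, 2)), "replicates")
})
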