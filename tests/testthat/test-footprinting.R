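as_msa <- function(rows) {
  # hand-built alignment object for direct footprint tests
  structure(list(rows = rows, reference = names(rows)[1],
                 ref_gap = strsplit(rows[[1]], "")[[1]] == "-",
                 ref_pos = {
    ch <- strsplit(rows[[1]], "")[[1]]
    p <- cumsum(ch != "-") - 1L
    p[ch == "-"] <- NA_integer_
    p
  }), class = "multiple_alignment")
}

test_that("identical sequences align with zero variant columns", {
  set.seed(31)
  s <- random_dna(80)
  seqs <- setNames(rep(s, 5), sprintf("sp%d", 1:5))
  aln <- align_ortholog_set(seqs, "sp1")
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  expect_true(all(apply(mat, 2, function(col) all(col == col[1]))))
  fp <- find_invariant_regions(aln, 6)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$ref_start, 0)
  expect_equal(fp$ref_end, 80)
})

test_that("a single substitution yields exactly one variant column", {
  set.seed(32)
  s <- random_dna(60)
  ch <- strsplit(s, "")[[1]]
  ch[30] <- setdiff(BASES, ch[30])[1]
  seqs <- c(a = s, b = s, c = paste(ch, collapse = ""))
  aln <- align_ortholog_set(seqs, "a")
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  variant <- apply(mat, 2, function(col) any(col != col[1]))
  expect_equal(sum(variant), 1)
  expect_equal(which(variant), 30)
})

test_that("ungapping any alignment row reproduces its input sequence", {
  for (s in 1:5) {
    cfg <- sim_config(seed = s, n_species = 6, substitution_rate = 0.08,
                      indel_rate = 0.02, ancestral_length = 150)
    os <- generate_ortholog_set(cfg)
    aln <- align_ortholog_set(os$sequences, names(os$sequences)[1])
    for (sp in names(aln$rows)) {
      expect_equal(gsub("-", "", aln$rows[[sp]]), unname(os$sequences[[sp]]))
    }
    expect_equal(length(unique(nchar(aln$rows))), 1)
  }
})

test_that("a variant column splits an invariant run as expected", {
  s <- strrep("ACGTA", 6)  # 30 bp
  ch <- strsplit(s, "")[[1]]
  ch[11] <- "T"  # 0-based column 10
  rows <- c(r = s, x = s, y = paste(ch, collapse = ""))
  fp <- find_invariant_regions(as_msa(rows), 6)
  expect_equal(fp$col_start, c(0, 11))
  expect_equal(fp$col_end, c(10, 30))
})

test_that("footprint detection equals the brute-force column scan", {
  set.seed(33)
  for (i in 1:120) {
    nsp <- sample(2:6, 1)
    nc <- sample(10:50, 1)
    mat <- matrix(sample(c(BASES, "-"), nsp * nc, replace = TRUE,
                         prob = c(rep(0.22, 4), 0.12)), nsp, nc)
    # sprinkle invariant stretches so both branches get exercised
    if (i %% 2 == 0) {
      st <- sample(nc - 8, 1)
      mat[, st:(st + 7)] <- matrix(rep(sample(BASES, 8, replace = TRUE),
                                       each = nsp), nsp)
    }
    rows <- setNames(apply(mat, 1, paste, collapse = ""),
                     sprintf("s%d", seq_len(nsp)))
    ml <- sample(3:8, 1)
    got <- find_invariant_regions(as_msa(rows), ml)
    exp <- oracle_footprints(unname(rows), ml)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      expect_equal(got$col_start, unname(exp[, 1]))
      expect_equal(got$col_end, unname(exp[, 2]))
    }
  }
})

test_that("variant-column fraction follows the closed-form expectation", {
  cfg <- sim_config(seed = 41, n_species = 6, substitution_rate = 0.05,
                    ancestral_length = 1000)
  os <- generate_ortholog_set(cfg)
  aln <- align_ortholog_set(os$sequences, names(os$sequences)[1])
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  variant <- mean(apply(mat, 2, function(col) any(col != col[1])))
  p <- 1 - expected_invariant_col(0.05, 6)
  expect_lt(abs(variant - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("a motif planted in all species always sits inside a footprint", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_species = 8, substitution_rate = 0.1,
                      ancestral_length = 150,
                      planted_motifs = list(list(pattern = "CAGCTG",
                                                 position = 70)))
    os <- generate_ortholog_set(cfg)
    aln <- align_ortholog_set(os$sequences, names(os$sequences)[1])
    fp <- find_invariant_regions(aln, 6)
    expect_true(any(fp$ref_start <= 70 & fp$ref_end >= 76))
  }
})

test_that("motif scans find the documented example hits", {
  h <- scan_motifs("TTCAGCTGTT")
  expect_equal(nrow(h), 1)  # E box is palindromic: one hit, not two
  expect_equal(h$offset, 2)
  expect_equal(h$strand, "+")
  h2 <- scan_motifs("AAATAATCCCAAA")
  h2 <- h2[h2$motif == "PITX2", ]
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$offset, 3)
})

test_that("motif scanning equals the brute-force position scan", {
  set.seed(51)
  lib <- rbind(default_motif_library(),
               data.frame(name = "degen", pattern = "CANNTG",
                          revcomp_pattern = "CANNTG"))
  for (i in 1:60) {
    s <- random_dna(200)
    got <- scan_motifs(s, lib)
    for (m in lib$name) {
      exp <- oracle_scan(s, lib$pattern[lib$name == m])
      g <- got[got$motif == m, ]
      expect_equal(g$offset, exp$offset, info = m)
      expect_equal(g$strand, exp$strand, info = m)
    }
  }
})

test_that("scanning a reverse complement mirrors hits and keeps counts", {
  set.seed(52)
  for (i in 1:20) {
    s <- random_dna(300)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_motifs(s)
    h2 <- scan_motifs(rc)
    expect_equal(nrow(h1), nrow(h2))
    for (m in unique(h1$motif)) {
      a <- h1[h1$motif == m, ]
      b <- h2[h2$motif == m, ]
      w <- nchar(default_motif_library()$pattern[
        default_motif_library()$name == m])
      refl <- sort(300 - w - a$offset)
      expect_equal(sort(b$offset), refl, info = m)
    }
  }
})

test_that("N in a sequence never produces a motif hit", {
  expect_equal(nrow(scan_motifs("TTCANCTGTT")), 0)
  expect_error(scan_motifs("ACGT", data.frame(name = "bad", pattern = "CAQT")),
               "IUPAC")
})

test_that("the enrichment ratio uses the strict 0.5 rule", {
  counts <- rbind(
    data.frame(ecr = "ECRa", species = sprintf("s%d", 1:20), motif = "Ebox",
               n_hits = c(rep(2, 14), rep(1, 6))),        # 34 hits
    data.frame(ecr = "ECRb", species = sprintf("s%d", 1:20), motif = "Ebox",
               n_hits = c(rep(1, 10), rep(0, 10))),       # ratio exactly 0.5
    data.frame(ecr = "ECRc", species = sprintf("s%d", 1:20), motif = "Ebox",
               n_hits = 0))
  lib <- default_motif_library()[1, ]
  m <- motif_frequency_matrix(counts, lib)
  a <- m[m$ecr == "ECRa", ]
  expect_equal(a$total_hits, 34)
  expect_equal(a$ratio, 1.7)
  expect_true(a$enriched)
  b <- m[m$ecr == "ECRb", ]
  expect_equal(b$ratio, 0.5)
  expect_false(b$enriched)   # strictly greater than 0.5 required
  c_ <- m[m$ecr == "ECRc", ]
  expect_equal(c_$ratio, 0)
  expect_false(c_$enriched)
})

test_that("per-species counts sum to the matrix totals", {
  comp <- synthetic_s1_compendium(seed = 3)
  counts <- scan_ortholog_sets(comp$sets[c("ECR5", "ECR18")])
  m <- motif_frequency_matrix(counts)
  for (i in seq_len(nrow(m))) {
    sub <- counts[counts$ecr == m$ecr[i] & counts$motif == m$motif[i], ]
    expect_equal(sum(sub$n_hits), m$total_hits[i])
  }
})
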