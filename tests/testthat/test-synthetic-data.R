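test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 99, n_species = 5, substitution_rate = 0.1,
                    ancestral_length = 200,
                    planted_motifs = list(list(pattern = "CAGCTG",
                                               position = 100)))
  a <- generate_ortholog_set(cfg)
  b <- generate_ortholog_set(cfg)
  expect_identical(a, b)
  gp1 <- generate_genome_pair(sim_config(seed = 99))
  gp2 <- generate_genome_pair(sim_config(seed = 99))
  expect_identical(gp1, gp2)
  amp <- paste0(strrep("AT", 30), "TCGA", strrep("GA", 30))
  g1 <- generate_cobra_gel(amp, 0.5, "TaqI", seed = 4)
  g2 <- generate_cobra_gel(amp, 0.5, "TaqI", seed = 4)
  expect_identical(g1, g2)
})

test_that("zero substitution rate reproduces the ancestor in every species", {
  cfg <- sim_config(seed = 7, n_species = 6, substitution_rate = 0,
                    ancestral_length = 150)
  os <- generate_ortholog_set(cfg)
  expect_true(all(os$sequences == os$ancestor))
})

test_that("pairwise divergence matches the closed-form expectation", {
  cfg <- sim_config(seed = 8, n_species = 2, substitution_rate = 0.1,
                    ancestral_length = 1000)
  os <- generate_ortholog_set(cfg)
  a <- strsplit(os$sequences[[1]], "")[[1]]
  b <- strsplit(os$sequences[[2]], "")[[1]]
  mm <- mean(a != b)
  p <- expected_pairwise_mismatch(0.1)
  expect_lt(abs(mm - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("planted motifs appear unmutated at their truth coordinates", {
  cfg <- sim_config(seed = 9, n_species = 8, substitution_rate = 0.1,
                    indel_rate = 0.02, ancestral_length = 300,
                    planted_motifs = list(list(pattern = "CAGCTG",
                                               position = 50)))
  os <- generate_ortholog_set(cfg)
  for (i in seq_len(nrow(os$truth))) {
    t <- os$truth[i, ]
    expect_equal(substr(os$sequences[[t$species]], t$start + 1, t$start + 6),
                 "CAGCTG")
  }
})

test_that("partial plantings are present only in the carrier species", {
  species <- sprintf("sp%d", 1:6)
  cfg <- sim_config(seed = 10, n_species = 6, substitution_rate = 0,
                    ancestral_length = 100,
                    planted_motifs = list(list(pattern = "CAGCTG",
                                               position = 40,
                                               species = species[1:3])))
  os <- generate_ortholog_set(cfg, species_labels = species)
  for (i in seq_len(nrow(os$truth))) {
    t <- os$truth[i, ]
    has <- substr(os$sequences[[t$species]], 41, 46) == "CAGCTG"
    expect_equal(has, t$present)
  }
})

test_that("invalid plantings are rejected", {
  expect_error(generate_ortholog_set(sim_config(
    planted_motifs = list(list(pattern = "CAGCTG", position = 10),
                          list(pattern = "CCATGG", position = 12)))),
    "overlapping")
  expect_error(generate_ortholog_set(sim_config(
    ancestral_length = 5,
    planted_motifs = list(list(pattern = "CAGCTG", position = 0)))),
    "longer than")
})

test_that("a genome pair with no elements has empty truth", {
  gp <- generate_genome_pair(sim_config(seed = 1, n_elements = 0))
  expect_equal(nrow(gp$truth), 0)
  expect_equal(nchar(gp$genome_a), 300)
})

test_that("planted blocks carry exactly the configured identity", {
  gp <- generate_genome_pair(sim_config(seed = 2, n_elements = 3,
                                        element_identity = 0.85))
  for (i in 1:3) {
    t <- gp$truth[i, ]
    a <- strsplit(substr(gp$genome_a, t$start_a + 1, t$end_a), "")[[1]]
    b <- strsplit(substr(gp$genome_b, t$start_b + 1, t$end_b), "")[[1]]
    expect_lt(abs(mean(a == b) - 0.85), 0.05)
  }
  gp1 <- generate_genome_pair(sim_config(seed = 3, n_elements = 2,
                                         element_identity = 1.0))
  for (i in 1:2) {
    t <- gp1$truth[i, ]
    expect_equal(substr(gp1$genome_a, t$start_a + 1, t$end_a),
                 substr(gp1$genome_b, t$start_b + 1, t$end_b))
  }
})

test_that("near-background identity is rejected", {
  expect_error(generate_genome_pair(sim_config(element_identity = 0.2)),
               "indistinguishable")
})

test_that("extreme methylation fractions put all intensity in one band set", {
  amp <- paste0(strrep("TA", 25), "TCGA", strrep("AG", 25))
  assay <- cobra_assay(amp, "TaqI")
  g1 <- generate_cobra_gel(amp, 1, "TaqI", n_molecules = 500, noise_sd = 0,
                           seed = 2)
  expect_equal(sort(g1$fragment_length_bp), sort(assay$frags_m))
  g0 <- generate_cobra_gel(amp, 0, "TaqI", n_molecules = 500, noise_sd = 0,
                           seed = 2)
  expect_equal(g0$fragment_length_bp, assay$frags_u)
})

test_that("the gel generator rejects uninformative enzymes", {
  expect_error(generate_cobra_gel(strrep("AT", 50), 0.5, "TaqI", seed = 1),
               "uninformative")
})

test_that("tissue tracks place peaks only at marked elements", {
  ecrs <- data.frame(chrom = "chr7", start = c(1000, 2000), end = c(1200, 2200),
                     name = c("E1", "E2"))
  assign <- data.frame(ecr = c("E1", "E2"), tissue = "t1",
                       state = c("ACTIVE", "NONE"),
                       hypomethylated = c(TRUE, FALSE))
  tr <- generate_tissue_tracks(ecrs, assign, seed = 3)
  t1 <- tr$tracks$t1
  expect_true(intersect_intervals(ecrs[1, ], t1$k4me1)$overlaps)
  expect_true(intersect_intervals(ecrs[1, ], t1$k27ac)$overlaps)
  expect_true(intersect_intervals(ecrs[1, ], t1$hypometh)$overlaps)
  expect_false(intersect_intervals(ecrs[2, ], t1$k4me1)$overlaps)
  expect_false(intersect_intervals(ecrs[2, ], t1$k27ac)$overlaps)
  expect_error(generate_tissue_tracks(ecrs, assign[0, ], seed = 1), "tissue|rows")
})

test_that("the synthetic compendium plants the survey's headline numbers", {
  comp <- synthetic_s1_compendium(seed = 5)
  s <- ortholog_set_summary(comp$sets)
  expect_equal(s$n_sets, 18)
  expect_equal(s$mean_species_per_ecr, 20)
  expect_equal(length(comp$sets$ECR18), 20)
  expect_true(all(vapply(comp$sets, function(x) "mouse" %in% names(x), TRUE)))
  m <- motif_frequency_matrix(scan_ortholog_sets(comp$sets["ECR18"]))
  expect_equal(m$total_hits[m$motif == "Ebox"], 34)
  expect_equal(m$ratio[m$motif == "Ebox"], 1.7)
  expect_true(m$enriched[m$motif == "Ebox"])
})
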