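#!/usr/bin/env Rscript
# Stage 1: generate every input for the downstream analyses with known
# ground truth, and write them in the exchange formats the pipeline reads
# (per-element multi-FASTA ortholog sets, genome-pair FASTA, per-tissue
# BED tracks, COBRA band tables).

suppressMessages(library(ecrfoot))
seed <- 101L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## cross-species ortholog compendium (18 elements, 45-species panel)
comp <- synthetic_s1_compendium(seed = seed)
write_ortholog_sets(comp$sets, file.path(out, "orthologs"))
cat("wrote", length(comp$sets), "ortholog sets;",
    "ECR18 carried by", length(comp$sets$ECR18), "species\n")

## genome pair with 3 planted conserved blocks at identity 0.85
gp <- generate_genome_pair(sim_config(seed = seed, n_elements = 3,
                                      element_length = 150,
                                      element_identity = 0.85,
                                      flank_length = 300))
write_fasta(c(genomeA = gp$genome_a), file.path(out, "genomeA.fa"))
write_fasta(c(genomeB = gp$genome_b), file.path(out, "genomeB.fa"))
write.table(gp$truth, file.path(out, "genome_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote genome pair with", nrow(gp$truth), "planted blocks\n")

## COBRA gels: 3 normal replicates (5% methylated) and 3 tumour
## replicates (60%) on the demo TG-class locus
loc <- demo_cobra_locus()
for (grp in c("normal", "tumor")) {
  frac <- if (grp == "normal") 0.05 else 0.60
  for (r in 1:3) {
    gel <- generate_cobra_gel(loc$amplicon, frac, loc$enzyme,
                              n_molecules = 10000, noise_sd = 0.02,
                              seed = seed + 10L * (grp == "tumor") + r)
    write_band_table(gel, file.path(out, sprintf("gel_%s_%d.tsv", grp, r)),
                     header = sprintf("enzyme=%s true_fraction=%.2f seed=%d",
                                      loc$enzyme, frac,
                                      seed + 10L * (grp == "tumor") + r))
  }
}
write_fasta(c(demo_locus = loc$amplicon), file.path(out, "cobra_locus.fa"))
cat("wrote 6 COBRA gels (3 normal at 5%, 3 tumor at 60%)\n")

## per-tissue enhancer tracks for 18 elements x 8 tissues
set.seed(seed)
ecrs <- data.frame(chrom = "chr7", start = seq(1000, 9500, by = 500),
                   end = seq(1200, 9700, by = 500),
                   name = sprintf("ECR%d", 1:18))
assign <- expand.grid(ecr = ecrs$name, tissue = sprintf("tissue%d", 1:8),
                      stringsAsFactors = FALSE)
assign$state <- sample(c("ACTIVE", "POISED", "ACETYL_ONLY", "NONE"),
                       nrow(assign), replace = TRUE,
                       prob = c(0.3, 0.2, 0.1, 0.4))
assign$hypomethylated <- assign$state %in% c("ACTIVE", "POISED") &
  runif(nrow(assign)) < 0.6
tr <- generate_tissue_tracks(ecrs, assign, seed = seed)
write_track_dir(tr$tracks, file.path(out, "tracks"))
write_bed(ecrs, file.path(out, "ecrs.bed"))
write.table(assign, file.path(out, "state_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", length(tr$tracks), "tissues x 3 marks of track BEDs\n")
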