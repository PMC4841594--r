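#!/usr/bin/env Rscript
# Stage 4: reference-anchored alignment of each element's ortholog set,
# phylogenetic footprints (invariant runs >= 6 columns), both-strand motif
# scans, and the motif-by-element frequency/enrichment matrix.

suppressMessages(library(ecrfoot))
inp <- "results/inputs/orthologs"
out <- "results"

sets <- read_ortholog_sets(inp)
lib <- default_motif_library()

fps <- list()
for (e in names(sets)) {
  aln <- align_ortholog_set(sets[[e]], "mouse")
  fp <- find_invariant_regions(aln, min_footprint_length = 6)
  if (nrow(fp)) fps[[e]] <- cbind(ecr = e, fp)
}
fps <- do.call(rbind, fps)
write.table(fps, file.path(out, "footprints.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("found %d invariant regions across %d element sets\n",
            nrow(fps), length(unique(fps$ecr))))

counts <- scan_ortholog_sets(sets, lib)
mfm <- motif_frequency_matrix(counts, lib)
write.table(mfm, file.path(out, "motif_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

e18 <- mfm[mfm$ecr == "ECR18" & mfm$motif == "Ebox", ]
cat(sprintf("ECR18 E box: %d hits over %d species (%.1f per species)%s\n",
            e18$total_hits, e18$n_species_with_sequence, e18$ratio,
            if (e18$enriched) ", enriched" else ""))
cat(sprintf("%d of %d (element, motif) cells pass the >0.5 enrichment rule\n",
            sum(mfm$enriched), nrow(mfm)))
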