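#!/usr/bin/env Rscript
# Stage 3: parse the per-element ortholog sets, summarise cross-species
# presence, and demonstrate the seed-and-extend search by re-locating one
# element's mouse probe inside a diverged synthetic target.

suppressMessages(library(ecrfoot))
inp <- "results/inputs/orthologs"
out <- "results"

sets <- read_ortholog_sets(inp)
summ <- ortholog_set_summary(sets)
write.table(summ$per_ecr, file.path(out, "presence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("parsed %d element sets; mean %.1f species per element\n",
            summ$n_sets, summ$mean_species_per_ecr))

## search demo: embed the mouse ECR18 probe in a random background and
## recover it on both strands
probe <- unname(sets$ECR18["mouse"])
set.seed(303)
bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
            collapse = "")
target <- paste0(substr(bg, 1, 1200), probe, substr(bg, 1201, 3000))
hits <- ortholog_search(probe, target, probe_id = "ECR18")
cat(sprintf("probe recovered at [%d,%d) strand %s, score %.0f, identity %.2f\n",
            hits$target_start[1], hits$target_end[1], hits$strand[1],
            hits$score[1], hits$identity[1]))
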