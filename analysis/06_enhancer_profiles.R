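#!/usr/bin/env Rscript
# Stage 6: intersect the element intervals with the per-tissue histone and
# hypomethylation tracks, classify enhancer states, call breadth
# (ubiquitous vs tissue-specific), and verify against the planted truth.

suppressMessages(library(ecrfoot))
inp <- "results/inputs"
out <- "results"

ecrs <- read_bed(file.path(inp, "ecrs.bed"))
tracks <- read_track_dir(file.path(inp, "tracks"))
prof <- profile_enhancers(ecrs, tracks)
breadth <- call_breadth(prof, criterion = "either")
write.table(prof, file.path(out, "enhancer_states.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(breadth, file.path(out, "breadth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(inp, "state_truth.tsv"))
m <- merge(prof, truth, by = c("ecr", "tissue"))
cat(sprintf("classified %d (element, tissue) pairs; %.1f%% match the truth\n",
            nrow(prof), 100 * mean(m$state.x == m$state.y)))
print(table(breadth$call))
ub <- breadth$ecr[breadth$call == "ubiquitous"]
cat("ubiquitous elements:", paste(ub, collapse = ", "), "\n")
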