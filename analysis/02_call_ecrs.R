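#!/usr/bin/env Rscript
# Stage 2: call conserved elements between the two genomic intervals
# (criteria: length strictly > 50 bp, identity strictly > 75%) and check
# the calls against the simulation truth.

suppressMessages(library(ecrfoot))
inp <- "results/inputs"
out <- "results"

ga <- unname(read_fasta(file.path(inp, "genomeA.fa"))[1])
gb <- unname(read_fasta(file.path(inp, "genomeB.fa"))[1])
el <- find_conserved_elements(ga, gb)
write.table(el, file.path(out, "elements.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_bed(data.frame(chrom = "genomeA", start = el$ref_start,
                     end = el$ref_end, name = el$id,
                     score = round(100 * el$identity)),
          file.path(out, "elements.bed"))

truth <- read.delim(file.path(inp, "genome_truth.tsv"))
cat(sprintf("called %d elements (truth: %d planted blocks)\n",
            nrow(el), nrow(truth)))
for (i in seq_len(nrow(truth))) {
  t <- truth[i, ]
  ov <- vapply(seq_len(nrow(el)), function(j) {
    max(0, min(el$ref_end[j], t$end_a) - max(el$ref_start[j], t$start_a)) /
      (t$end_a - t$start_a)
  }, 0)
  cat(sprintf("  %s [%d,%d) best truth coverage %.2f\n",
              t$element, t$start_a, t$end_a, max(ov)))
}
cat(sprintf("mean called identity %.3f, mean length %.0f bp\n",
            mean(el$identity), mean(el$length)))
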