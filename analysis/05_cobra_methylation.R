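#!/usr/bin/env Rscript
# Stage 5: in-silico COBRA of the demo locus — enzyme informativeness,
# expected fragments, densitometric quantification of the simulated gels,
# and the replicate-supported tumour-vs-normal call.

suppressMessages(library(ecrfoot))
inp <- "results/inputs"
out <- "results"

amplicon <- unname(read_fasta(file.path(inp, "cobra_locus.fa"))[1])
assay <- cobra_assay(amplicon, "FokI", locus = "demo_locus")
cat(sprintf("FokI on demo locus: %s; assayed CpG at %d\n",
            assay$class, assay$assayed_cpgs))
cat(sprintf("expected fragments U allele: %s | M allele: %s\n",
            paste(assay$frags_u, collapse = ","),
            paste(assay$frags_m, collapse = ",")))

quant <- function(grp) {
  vapply(1:3, function(r) {
    quantify_methylation(
      read_band_table(file.path(inp, sprintf("gel_%s_%d.tsv", grp, r))),
      assay)
  }, 0)
}
normal <- quant("normal")
tumor <- quant("tumor")
call <- call_delta(tumor, normal)
rep <- data.frame(locus = assay$locus, enzyme = assay$enzyme,
                  class = assay$class,
                  normal_percent = mean(normal), tumor_percent = mean(tumor),
                  delta = call$delta, p_value = call$p_value,
                  verdict = call$verdict)
write.table(rep, file.path(out, "cobra.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("normal %.1f%% (reps %s), tumor %.1f%% (reps %s)\n",
            mean(normal), paste(sprintf("%.1f", normal), collapse = "/"),
            mean(tumor), paste(sprintf("%.1f", tumor), collapse = "/")))
cat(sprintf("verdict: %s (delta %.1f points, p = %.2g)\n",
            call$verdict, call$delta, call$p_value))
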