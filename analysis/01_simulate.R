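#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream stages consume, with known
# ground truth: a 16-chromosome genome annotation, qPCR plates and 1-kb
# depth windows for the six disome strains plus the euploid reference, and
# mRNA/FP count matrices for the D2 strain pair.

suppressMessages(library(aneudose))
seed <- 20260929L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- simulate_genome(16, 125, seed = seed, include_mito = TRUE)
write_annotation(ann, file.path(out, "annotation.tsv"))
write_annotation_gff3(ann[ann$chromosome != "chrMito", ],
                      file.path(out, "annotation.gff3"))
cat(sprintf("annotation: %d genes on %d chromosomes (incl. chrMito)\n",
            nrow(ann), length(unique(ann$chromosome))))

eu <- karyotype(character())
for (kn in names(disome_karyotypes())) {
  karyo <- disome_karyotypes()[[kn]]
  tag <- gsub("/", "-", kn)
  off <- match(kn, names(disome_karyotypes()))
  write_karyotype(karyo, file.path(out, sprintf("karyotype_true_%s.tsv", tag)))
  utils::write.table(simulate_qpcr(karyo, ct_sd = 0.1, seed = seed + off),
                     file.path(out, sprintf("qpcr_%s.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    simulate_wgs_depth(karyo, 200, 0.2, seed = seed + 100 + off),
    file.path(out, sprintf("wgs_%s.tsv", tag)),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
utils::write.table(simulate_qpcr(eu, ct_sd = 0.1, seed = seed + 50),
                   file.path(out, "qpcr_WT.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(simulate_wgs_depth(eu, 200, 0.2, seed = seed + 150),
                   file.path(out, "wgs_WT.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("qPCR plates and depth windows written for 6 disomes + WT\n")

# count matrices for the D2/WT pair, both assays
cfg <- simulation_config(seed = seed)
for (assay in c("mRNA", "FP")) {
  write_counts(simulate_counts(ann, eu, cfg, assay, seed_offset = 1,
                               sample_names = paste0("WT_", assay)),
               file.path(out, sprintf("counts_WT_%s.tsv", assay)))
  write_counts(simulate_counts(ann, karyotype("chrII"), cfg, assay,
                               seed_offset = 2,
                               sample_names = paste0("D2_", assay)),
               file.path(out, sprintf("counts_D2_%s.tsv", assay)))
}
cat("count matrices written for the D2/WT pair (mRNA and FP)\n")
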