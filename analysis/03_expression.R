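#!/usr/bin/env Rscript
# Stage 3: RPKM quantification, euploid-anchored median-ratio normalization,
# per-gene log2 fold changes, ribosome density, and per-chromosome dosage
# summaries for the D2/WT pair written by stage 1 — the computational form
# of the chromosome-dosage expression plots.

suppressMessages(library(aneudose))
ind <- "results/simulated"
ann <- read_annotation(file.path(ind, "annotation.tsv"))
k_d2 <- read_karyotype(file.path(ind, "karyotype_true_D2.tsv"))

profiles <- list()
for (assay in c("mRNA", "FP")) {
  eu <- compute_rpkm(read_counts(file.path(ind,
                                           sprintf("counts_WT_%s.tsv", assay))),
                     ann)[, 1]
  an <- compute_rpkm(read_counts(file.path(ind,
                                           sprintf("counts_D2_%s.tsv", assay))),
                     ann)[, 1]
  norm <- normalize_to_euploid(an, eu, ann, k_d2)
  lfc <- log2_fold_changes(norm$rpkm, eu)
  profiles[[assay]] <- list(eu = eu, norm = norm$rpkm, lfc = lfc)
  cat(sprintf("%-4s scale factor %.4f; %d/%d genes with defined log2 FC\n",
              assay, norm$scale_factor, sum(!is.na(lfc)), length(lfc)))

  ds <- chromosome_dosage_summary(lfc, ann, k_d2)
  utils::write.table(ds, sprintf("results/dosage_D2_%s.tsv", assay),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  chrII median log2 FC %.3f (expected 1); nonduplicated pool %.4f; compensated chromosomes: %d\n",
              ds$median_log2_fc[ds$chromosome == "chrII"],
              median(lfc[ann$chromosome[match(names(lfc),
                                              ann$gene_id)] != "chrII"],
                     na.rm = TRUE),
              sum(ds$compensated)))
}

rd <- ribosome_density(profiles$FP$norm, profiles$mRNA$norm,
                       profiles$FP$lfc, profiles$mRNA$lfc)
utils::write.table(rd, "results/ribosome_density_D2.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("ribosome density: median RD log2 FC %.4f (dosage-neutral translation)\n",
            median(rd$rd_log2_fc, na.rm = TRUE)))

per_gene <- tibble::tibble(
  gene_id = names(profiles$FP$lfc),
  chromosome = ann$chromosome[match(names(profiles$FP$lfc), ann$gene_id)],
  mRNA_log2_fc = unname(profiles$mRNA$lfc[names(profiles$FP$lfc)]),
  FP_log2_fc = unname(profiles$FP$lfc)
)
utils::write.table(per_gene, "results/log2fc_D2.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
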