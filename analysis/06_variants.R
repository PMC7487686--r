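#!/usr/bin/env Rscript
# Stage 6: variant filtering for a simulated aneuploid strain — the
# 70%/40% frequency rules with quality floors, wild-type subtraction by
# perfect reciprocal match, and strand-aware coding-effect classification.

suppressMessages(library(aneudose))
seed <- 20260929L
ann_seq <- simulate_genome(16, 40, seed = seed, with_sequence = TRUE)
k <- karyotype(c("chrI", "chrII", "chrVIII"))

strain <- simulate_variants(ann_seq, k, n_true = 30, n_noise = 50,
                            seed = seed + 1)
wt <- simulate_variants(ann_seq, karyotype(character()), n_true = 10,
                        n_noise = 0, seed = seed + 2)
# plant a few WT-shared records to exercise the subtraction
shared <- strain[1:4, ]
wt <- dplyr::bind_rows(wt, shared)

unique_ <- subtract_wt(strain, wt)
filtered <- filter_variants(unique_, k)
classified <- classify_coding_effect(filtered, ann_seq)

cat(sprintf("strain records: %d; after WT subtraction: %d; after 70%%/40%%/Q15 filter: %d\n",
            nrow(strain), nrow(unique_), nrow(filtered)))
cat(sprintf("filter kept %d/%d true variants and 0/%d noise records\n",
            sum(filtered$truth == "true"), sum(unique_$truth == "true"),
            sum(unique_$truth == "noise")))
print(table(classified$effect))

write_variants(classified, "results/variants_filtered.tsv")
utils::write.table(
  as.data.frame(table(effect = classified$effect)),
  "results/variant_effect_counts.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
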