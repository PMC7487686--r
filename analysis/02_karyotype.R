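#!/usr/bin/env Rscript
# Stage 2: call chromosome copy numbers for every simulated strain from the
# qPCR plates (arm-averaged delta-Ct) and from the 1-kb depth windows
# (median log2 ratio), then compare both call sets to the ground truth.

suppressMessages(library(aneudose))
ind <- "results/simulated"
dir.create("results", showWarnings = FALSE)

qpcr_wt <- utils::read.delim(file.path(ind, "qpcr_WT.tsv"))
wgs_wt <- tibble::as_tibble(utils::read.delim(file.path(ind, "wgs_WT.tsv")))

rows <- list()
for (kn in names(disome_karyotypes())) {
  tag <- gsub("/", "-", kn)
  truth <- read_karyotype(file.path(ind, sprintf("karyotype_true_%s.tsv", tag)))
  q <- estimate_copy_number_qpcr(
    utils::read.delim(file.path(ind, sprintf("qpcr_%s.tsv", tag))), qpcr_wt)
  w <- wgs_window_copy_profile(
    tibble::as_tibble(utils::read.delim(file.path(ind,
                                                  sprintf("wgs_%s.tsv", tag)))),
    wgs_wt)
  rows[[kn]] <- tibble::tibble(
    strain = kn, chromosome = q$chromosome,
    truth = as.integer(truth[q$chromosome]),
    qpcr_copy_mean = q$copy_mean, qpcr_copy_sd = q$copy_sd,
    qpcr_call = q$call,
    wgs_call = w$estimates$call[match(q$chromosome,
                                      w$estimates$chromosome)],
    segmental_flag = q$chromosome %in% w$segmental_flags
  )
  agree <- all(rows[[kn]]$qpcr_call == rows[[kn]]$truth) &&
    all(rows[[kn]]$wgs_call == rows[[kn]]$truth)
  cat(sprintf("%-10s qPCR and depth calls %s ground truth; %d segmental flags\n",
              kn, if (agree) "match" else "MISMATCH",
              sum(rows[[kn]]$segmental_flag)))
}
calls <- dplyr::bind_rows(rows)
utils::write.table(calls, "results/karyotype_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("overall per-chromosome accuracy: qPCR %.1f%%, depth %.1f%%\n",
            100 * mean(calls$qpcr_call == calls$truth),
            100 * mean(calls$wgs_call == calls$truth)))
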