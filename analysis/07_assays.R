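#!/usr/bin/env Rscript
# Stage 7: the small-formula biochemical readouts — beta-galactosidase
# Miller units, ER-GFP folding ratios, pulse-chase turnover with the
# final-timepoint Student test, HAC1 splicing fractions, and growth-curve
# doubling times with the ORF-burden correlation.

suppressMessages(library(aneudose))
seed <- 20260929L
dir.create("results", showWarnings = FALSE)
lines <- character()
say <- function(...) {
  msg <- sprintf(...)
  cat(msg, "\n")
  lines <<- c(lines, msg)
}

# UPR reporter: uninduced vs tunicamycin-induced readings (synthetic)
basal <- miller_units(od420 = 0.22, od550 = 0.02, od600 = 0.35, t_min = 10)
induced <- miller_units(od420 = 1.31, od550 = 0.03, od600 = 0.33, t_min = 10)
say("Miller units: basal %.1f, tunicamycin-induced %.1f (%.1fx)",
    basal, induced, induced / basal)

# ER-GFP folding capacity relative to WT
wt_ratio <- ergfp_ratio(1200, 60, 12)
say("ER-GFP normalized to WT: same-as-WT %.0f%%, doubled fluorescence %.0f%%",
    normalized_ergfp(1200, 60, 12, wt_ratio = wt_ratio),
    normalized_ergfp(2400, 60, 12, wt_ratio = wt_ratio))

# pulse-chase: a WT-like and a slower-turnover strain
tp <- c(0, 15, 30, 60)
wt_chase <- pulse_chase_turnover(simulate_decay(28, tp, noise_sd = 4,
                                                n_replicates = 3,
                                                seed = seed + 1))
slow_chase <- pulse_chase_turnover(simulate_decay(45, tp, noise_sd = 4,
                                                  n_replicates = 3,
                                                  seed = seed + 2))
final_wt <- wt_chase$replicates$percent_remaining[
  wt_chase$replicates$time_min == max(tp)]
final_slow <- slow_chase$replicates$percent_remaining[
  slow_chase$replicates$time_min == max(tp)]
tt <- compare_final(final_wt, final_slow)
say("pulse-chase half-lives: WT-like %.1f min, slow strain %.1f min",
    wt_chase$half_life_min, slow_chase$half_life_min)
say("final-timepoint Student t = %.2f, p = %.4f %s", tt$t, tt$p, tt$stars)
utils::write.table(
  dplyr::bind_rows(WT = wt_chase$curve, slow = slow_chase$curve,
                   .id = "strain"),
  "results/pulse_chase_curves.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# Welch test for unequal group sizes (as used for the ER-GFP comparisons)
wt_vals <- c(98, 102, 100, 101)
d2_vals <- c(188, 196, 203)
wres <- welch_t(d2_vals, wt_vals)
say("Welch t on ER-GFP-style groups: t = %.2f, df = %.2f, p = %.2g %s",
    wres$t, wres$df, wres$p, wres$stars)

# HAC1 splicing before/after UPR induction
say("HAC1 spliced fraction: mock %.2f, induced %.2f",
    hac1_splice_fraction(12, 88, act1_intensity = 50),
    hac1_splice_fraction(70, 30, act1_intensity = 50))

# growth and ORF burden: six strains with synthetic doubling times
t_h <- seq(0, 8, by = 0.5)
dts <- vapply(c(2.0, 2.1, 2.05, 2.2, 2.3, 2.15), function(dt) {
  doubling_time(t_h, 0.05 * 2^(t_h / dt))
}, numeric(1))
extra_orfs <- c(456, 573, 894, 1242, 438, 505)  # D2, D1/2, D1/2/8, D1/2/8/11, D1/8, D13
say("doubling times (h): %s", paste(sprintf("%.2f", dts), collapse = ", "))
say("Pearson r (doubling time vs extra ORFs): %.2f",
    orf_burden_correlation(dts, extra_orfs))

writeLines(lines, "results/assay_summary.txt")
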