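test_that("simulated genomes satisfy the annotation invariants and are seed-deterministic", {
  ann <- simulate_genome(16, 10, length_range = c(300, 3000), seed = 1)
  expect_equal(nrow(ann), 160)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$cds_start <= ann$cds_end))
  expect_equal(ann$cds_length_bp, ann$cds_end - ann$cds_start + 1L)
  expect_true(all(ann$cds_length_bp >= 300 & ann$cds_length_bp <= 3000))
  expect_true(all(ann$cds_length_bp %% 3 == 0))

  # non-overlapping within each chromosome
  by_chrom <- split(ann, ann$chromosome)
  for (chrom_genes in by_chrom) {
    o <- order(chrom_genes$cds_start)
    expect_true(all(diff(chrom_genes$cds_start[o]) >
                      chrom_genes$cds_length_bp[o][-nrow(chrom_genes)]))
  }

  expect_identical(ann, simulate_genome(16, 10, c(300, 3000), seed = 1))
  ann2 <- simulate_genome(16, 10, c(300, 3000), seed = 2)
  expect_false(identical(ann$cds_length_bp, ann2$cds_length_bp))

  with_mito <- simulate_genome(4, 5, seed = 1, include_mito = TRUE)
  expect_true("chrMito" %in% with_mito$chromosome)
  expect_error(simulate_genome(0, 5), "n_chromosomes")
  expect_error(simulate_genome(4, 5, length_range = c(2, 10)), "length_range")
})

test_that("expected counts track copy number, compensation, and planted effects", {
  ann <- simulate_genome(4, 100, seed = 3)
  dis <- karyotype("chrII", n_chromosomes = 4)
  eu <- karyotype(character(), n_chromosomes = 4)

  # Poisson limit, no compensation: duplicated/euploid mean count ratio -> 2,
  # measured over 100 duplicated genes against the nonduplicated baseline.
  cfg <- simulation_config(library_size = 2e6, nb_dispersion = 0,
                           compensation_fraction = 0, seed = 4)
  c_eu <- simulate_counts(ann, eu, cfg, "mRNA", seed_offset = 1)[, 1]
  c_an <- simulate_counts(ann, dis, cfg, "mRNA", seed_offset = 2)[, 1]
  dup <- ann$chromosome == "chrII"
  ratio <- (sum(c_an[dup]) / sum(c_eu[dup])) /
    (sum(c_an[!dup]) / sum(c_eu[!dup]))
  expect_equal(ratio, 2, tolerance = 0.01)

  # full compensation collapses the exponent
  cfg1 <- simulation_config(library_size = 2e6, nb_dispersion = 0,
                            compensation_fraction = 1, seed = 4)
  c_an1 <- simulate_counts(ann, dis, cfg1, "mRNA", seed_offset = 2)[, 1]
  c_eu1 <- simulate_counts(ann, eu, cfg1, "mRNA", seed_offset = 1)[, 1]
  ratio1 <- (sum(c_an1[dup]) / sum(c_eu1[dup])) /
    (sum(c_an1[!dup]) / sum(c_eu1[!dup]))
  expect_equal(ratio1, 1, tolerance = 0.01)

  # an activated set on a euploid karyotype doubles its members
  members <- ann$gene_id[ann$chromosome == "chrIII"][1:50]
  cfg_act <- simulation_config(library_size = 2e6, nb_dispersion = 0,
                               activated_sets = list(
                                 list(members = members, log2_effect = 1)),
                               seed = 4)
  c_act <- simulate_counts(ann, eu, cfg_act, "mRNA", seed_offset = 1)[, 1]
  c_null <- simulate_counts(ann, eu, cfg, "mRNA", seed_offset = 1)[, 1]
  in_set <- ann$gene_id %in% members
  act_ratio <- (sum(c_act[in_set]) / sum(c_null[in_set])) /
    (sum(c_act[!in_set]) / sum(c_null[!in_set]))
  expect_equal(act_ratio, 2, tolerance = 0.05)

  # totals land near the configured library size; fixed seeds reproduce
  expect_lt(abs(sum(c_eu) - 2e6) / 2e6, 0.02)
  expect_identical(c_eu, simulate_counts(ann, eu, cfg, "mRNA",
                                         seed_offset = 1)[, 1])
  expect_error(simulate_counts(toy_annotation(),
                               karyotype("chrII", n_chromosomes = 2),
                               cfg, "mRNA"),
               "absent from karyotype")
})

test_that("qPCR simulation follows the efficiency-2 Ct model", {
  dis <- karyotype("chrV")
  noiseless <- simulate_qpcr(dis, ct_sd = 0, reference_ct = 20, seed = 1)
  expect_equal(unique(noiseless$ct[noiseless$chromosome == "chrV"]), 19)
  expect_equal(unique(noiseless$ct[noiseless$chromosome != "chrV"]), 20)
  expect_equal(nrow(noiseless), 16 * 2 * 3)
  expect_identical(simulate_qpcr(dis, 0.1, seed = 7),
                   simulate_qpcr(dis, 0.1, seed = 7))
  expect_error(simulate_qpcr(dis, ct_sd = -1), "ct_sd")
})

test_that("windowed depth is proportional to copy number on a 1-kb grid", {
  dis <- karyotype("chrII")
  eu <- karyotype(character())
  w_dis <- simulate_wgs_depth(dis, 50, depth_noise_cv = 0, seed = 1)
  w_eu <- simulate_wgs_depth(eu, 50, depth_noise_cv = 0, seed = 2)
  expect_true(all(w_dis$window_end - w_dis$window_start + 1L == 1000L))
  r <- w_dis$rpkm / w_eu$rpkm
  expect_equal(unique(r[w_dis$chromosome == "chrII"]), 2)
  expect_equal(unique(r[w_dis$chromosome != "chrII"]), 1)
  # noiseless per-chromosome median log2 ratio is exactly 1 for the disome
  prof <- wgs_window_copy_profile(w_dis, w_eu)
  expect_equal(
    prof$estimates$median_log2_ratio[prof$estimates$chromosome == "chrII"], 1)
})

test_that("decay series follow the half-life definition", {
  clean <- simulate_decay(30, timepoints = c(0, 30, 60), noise_sd = 0,
                          n_replicates = 2, seed = 1)
  expect_equal(clean$intensity[clean$time_min == 0], c(100, 100))
  expect_equal(clean$intensity[clean$time_min == 30], c(50, 50))
  expect_equal(clean$intensity[clean$time_min == 60], c(25, 25))
  noisy <- simulate_decay(30, noise_sd = 5, seed = 2)
  expect_true(all(noisy$intensity >= 0))
})
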