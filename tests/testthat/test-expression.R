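test_that("RPKM follows its definition and excludes mitochondrial genes from totals", {
  ann <- toy_annotation()
  counts <- matrix(c(10L, 0L, 20L, 5L, 965L, 50L),
                   ncol = 1, dimnames = list(ann$gene_id, "s1"))
  rpkm <- compute_rpkm(counts, ann)
  expect_false("f" %in% rownames(rpkm))          # chrMito dropped
  # nuclear total is 1000 reads; gene a: 10 / 1 kb / 0.001 M = 10000
  expect_equal(rpkm["a", 1], 10 / (1000 / 1000) / (1000 / 1e6))
  expect_equal(rpkm["b", 1], 0)
  # scale invariance: doubling every count leaves RPKM unchanged
  expect_equal(compute_rpkm(counts * 2L, ann), rpkm)
  # direct formula case: count 10, length 1000 bp, total 10^6 -> 10.0
  big <- matrix(c(10L, 999990L, 0L, 0L, 0L, 0L),
                ncol = 1, dimnames = list(ann$gene_id, "s1"))
  expect_equal(compute_rpkm(big, ann)["a", 1], 10)
  zero <- matrix(0L, 6, 1, dimnames = list(ann$gene_id, "s1"))
  expect_error(compute_rpkm(zero, ann), "zero mapped reads")
})

test_that("euploid-anchored normalization pins the nonduplicated median ratio at 1", {
  ann <- toy_annotation()
  k <- karyotype("chrII")
  eu <- stats::setNames(c(10, 20, 30, 40, 50), c("a", "b", "c", "d", "e"))

  # identical profiles: unit scale factor, unchanged values
  n0 <- normalize_to_euploid(eu, eu, ann, k)
  expect_equal(n0$scale_factor, 1)
  expect_equal(n0$rpkm, eu)

  # uniform 3x inflation on nonduplicated genes: scale factor 3
  an <- eu * 3
  n3 <- normalize_to_euploid(an, eu, ann, k)
  expect_equal(n3$scale_factor, 3)
  expect_equal(n3$rpkm / eu, stats::setNames(rep(1, 5), names(eu)))

  # genes with zero euploid RPKM are ignored when taking the median
  eu0 <- eu; eu0["a"] <- 0
  expect_equal(normalize_to_euploid(an, eu0, ann, k)$scale_factor, 3)
  expect_error(normalize_to_euploid(an, eu * 0, ann, k), "no nonduplicated")
})

test_that("log2 fold changes flag zeros as missing instead of infinities", {
  eu <- c(a = 2, b = 4, c = 0, d = 1)
  an <- c(a = 2, b = 8, c = 5, d = 0)
  lfc <- log2_fold_changes(an, eu)
  expect_equal(lfc[["a"]], 0)
  expect_equal(lfc[["b"]], 1)
  expect_true(is.na(lfc[["c"]]) && is.na(lfc[["d"]]))
})

test_that("simulated disome shows dosage without compensation after normalization", {
  ann <- std_genome()
  k <- karyotype("chrII")
  pair <- sim_rpkm_pair(ann, k, seed = 5)
  norm <- normalize_to_euploid(pair$an, pair$eu, ann, k)

  # definition-level identity, and idempotence of the normalization
  chrom <- ann$chromosome[match(names(pair$eu), ann$gene_id)]
  nondup <- chrom != "chrII" & pair$eu > 0
  expect_equal(stats::median((norm$rpkm / pair$eu)[nondup]), 1,
               tolerance = 1e-12)
  again <- normalize_to_euploid(norm$rpkm, pair$eu, ann, k)
  expect_equal(again$scale_factor, 1, tolerance = 1e-12)
  expect_equal(again$rpkm, norm$rpkm)

  lfc <- log2_fold_changes(norm$rpkm, pair$eu)
  ds <- chromosome_dosage_summary(lfc, ann, k)
  expect_equal(ds$median_log2_fc[ds$chromosome == "chrII"], 1,
               tolerance = 0.1)
  expect_true(all(abs(ds$median_log2_fc[ds$chromosome != "chrII"]) < 0.1))
  expect_lt(abs(stats::median(lfc[chrom != "chrII"], na.rm = TRUE)), 0.05)
  expect_false(any(ds$compensated))
  expect_equal(ds$expected_log2_fc[ds$chromosome == "chrII"], 1)
})

test_that("the compensation dial moves the duplicated-chromosome median accordingly", {
  ann <- std_genome()
  k <- karyotype("chrII")
  for (comp in c(0.5, 1)) {
    pair <- sim_rpkm_pair(ann, k, seed = 6, compensation = comp)
    norm <- normalize_to_euploid(pair$an, pair$eu, ann, k)
    lfc <- log2_fold_changes(norm$rpkm, pair$eu)
    ds <- chromosome_dosage_summary(lfc, ann, k)
    expect_equal(ds$median_log2_fc[ds$chromosome == "chrII"],
                 (1 - comp) * log2(2), tolerance = 0.1)
    expect_equal(ds$compensated[ds$chromosome == "chrII"], comp >= 0.5)
  }
})

test_that("ribosome density is the FP/mRNA ratio and its fold change the difference", {
  fp <- c(a = 4, b = 2, c = 0)
  mrna <- c(a = 2, b = 0, c = 5)
  rd <- ribosome_density(fp, mrna, fp_log2_fc = c(a = 1.5, b = 1, c = 0),
                         mrna_log2_fc = c(a = 0.5, b = 1, c = 0))
  expect_equal(rd$rd[rd$gene_id == "a"], 2)
  expect_true(is.na(rd$rd[rd$gene_id == "b"]))
  expect_equal(rd$rd_log2_fc, c(1, 0, 0))

  # a footprint-only activated set shifts RD by its effect
  ann <- std_genome()
  eu_k <- karyotype(character())
  members <- ann$gene_id[ann$chromosome == "chrVI"][1:40]
  act <- list(list(members = members, log2_effect = 1, assay = "FP"))
  fp_pair <- sim_rpkm_pair(ann, eu_k, seed = 7, assay = "FP",
                           activated_sets = act)
  mr_pair <- sim_rpkm_pair(ann, eu_k, seed = 7, assay = "mRNA",
                           activated_sets = act)
  fp_lfc <- log2_fold_changes(
    normalize_to_euploid(fp_pair$an, fp_pair$eu, ann, eu_k)$rpkm, fp_pair$eu)
  mr_lfc <- log2_fold_changes(
    normalize_to_euploid(mr_pair$an, mr_pair$eu, ann, eu_k)$rpkm, mr_pair$eu)
  rd_fc <- fp_lfc - mr_lfc
  expect_equal(mean(rd_fc[members], na.rm = TRUE), 1, tolerance = 0.1)
})
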