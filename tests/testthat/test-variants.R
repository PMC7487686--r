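make_record <- function(chromosome = "chrI", position = 100L, ref = "A",
                        alt = "T", frequency = 0.95, base_quality = 30,
                        mapping_quality = 40) {
  tibble::tibble(chromosome = chromosome, position = position, ref = ref,
                 alt = alt, frequency = frequency,
                 base_quality = base_quality,
                 mapping_quality = mapping_quality)
}

test_that("the frequency/quality filter applies the 70%/40%/15 rules inclusively", {
  k <- karyotype("chrII")
  recs <- dplyr::bind_rows(
    make_record(position = 1L, frequency = 0.69),                 # low freq
    make_record(position = 2L, frequency = 0.70),                 # boundary
    make_record("chrII", 3L, frequency = 0.45),                   # dup, ok
    make_record(position = 4L, frequency = 0.45),                 # haploid, no
    make_record("chrII", 5L, frequency = 0.40),                   # boundary
    make_record(position = 6L, base_quality = 14.9),              # low BQ
    make_record(position = 7L, mapping_quality = 14.9),           # low MQ
    make_record(position = 8L, base_quality = 15, mapping_quality = 15)
  )
  kept <- filter_variants(recs, k)
  expect_equal(kept$position, c(2L, 3L, 5L, 8L))

  # idempotent and order-independent
  expect_identical(filter_variants(kept, k), kept)
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  expect_setequal(filter_variants(shuffled, k)$position, kept$position)
  expect_error(filter_variants(make_record("chrXVII"), k),
               "absent from karyotype")
})

test_that("wild-type subtraction removes exact reciprocal matches only", {
  a <- dplyr::bind_rows(make_record(position = 1L),
                        make_record(position = 2L, alt = "G"),
                        make_record(position = 3L))
  expect_equal(nrow(subtract_wt(a, a)), 0)
  expect_identical(subtract_wt(a, a[0, ]), a)
  # shared position but different alt allele is retained
  wt <- make_record(position = 2L, alt = "C")
  expect_equal(subtract_wt(a, wt)$position, c(1L, 2L, 3L))
  wt2 <- make_record(position = 2L, alt = "G")
  expect_equal(subtract_wt(a, wt2)$position, c(1L, 3L))
})

test_that("the simulated variant strata are separated perfectly by the filter", {
  ann <- simulate_genome(8, 20, seed = 9)
  k <- karyotype(c("chrII", "chrVIII"), n_chromosomes = 8)
  sim <- simulate_variants(ann, k, n_true = 40, n_noise = 60, seed = 10)
  kept <- filter_variants(sim, k)
  expect_setequal(kept$position[kept$truth == "true"],
                  sim$position[sim$truth == "true"])
  expect_true(all(kept$truth == "true"))          # specificity 1
  expect_equal(nrow(kept), 40)                    # sensitivity 1

  # with no noise the filter is a no-op on the true records
  clean <- simulate_variants(ann, k, n_true = 15, n_noise = 0, seed = 11)
  expect_equal(nrow(filter_variants(clean, k)), 15)

  # injected WT-shared variants are removed exactly
  wt_shared <- sim[1:5, ]
  merged <- dplyr::bind_rows(sim[-(1:5), ], wt_shared)
  left <- subtract_wt(merged, wt_shared)
  expect_setequal(paste(left$chromosome, left$position, left$ref, left$alt),
                  paste(sim$chromosome, sim$position, sim$ref,
                        sim$alt)[-(1:5)])
})

test_that("coding effects are classified strand-aware with the standard code", {
  ann <- tibble::tibble(
    gene_id = c("plus", "minus"),
    chromosome = c("chrI", "chrI"),
    cds_start = c(101L, 301L),
    cds_end = c(109L, 309L),
    strand = c("+", "-"),
    cds_length_bp = c(9L, 9L),
    # plus: ATG GGA TAA ; minus (coding orientation): ATG CAA TAG
    cds_seq = c("ATGGGATAA", "ATGCAATAG")
  )
  # wobble change GGA -> GGG at the third codon position: synonymous
  syn <- classify_coding_effect(make_record(position = 106L, ref = "A",
                                            alt = "G"), ann)
  expect_equal(syn$effect, "synonymous")
  # CAA -> TAA: premature stop
  non <- classify_coding_effect(make_record(position = 104L, ref = "G",
                                            alt = "A"), ann)
  # on the plus gene position 104 is codon 2 base 1 (G); GGA->AGA = missense
  expect_equal(non$effect, "missense")
  stop_rec <- classify_coding_effect(
    make_record(position = 306L, ref = "G", alt = "A"), ann)
  # minus strand: coding base = complement, codon 2 base 1 C -> T: CAA -> TAA
  expect_equal(stop_rec$effect, "nonsense")

  # between genes -> intergenic (the geometry of an isolated intergenic hit)
  inter <- classify_coding_effect(make_record(position = 200L), ann)
  expect_equal(inter$effect, "intergenic")
  # indels are left unclassified
  indel <- classify_coding_effect(make_record(position = 106L, ref = "AT",
                                              alt = "A"), ann)
  expect_equal(indel$effect, "unclassified")
})
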