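# Shared in-code fixtures for the suite.

# A tiny annotation with explicit coordinates, used where the geometry of
# the genes matters more than their number.
toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    chromosome = c("chrI", "chrI", "chrII", "chrII", "chrIII", "chrMito"),
    cds_start = c(1000L, 5000L, 1000L, 5000L, 1000L, 100L),
    cds_end = c(1999L, 6999L, 2999L, 5999L, 1499L, 399L),
    strand = c("+", "-", "+", "-", "+", "+"),
    cds_length_bp = c(1000L, 2000L, 2000L, 1000L, 500L, 300L)
  )
}

# Standard medium-sized simulation shared by several expression tests.
std_genome <- function(seed = 1) {
  simulate_genome(16, 125, seed = seed, include_mito = TRUE)
}

# One aneuploid/euploid RPKM pair for a given karyotype and seed.
sim_rpkm_pair <- function(annotation, karyo, seed, assay = "FP",
                          compensation = 0, activated_sets = list(),
                          nb_dispersion = 0.01) {
  # activated programs belong to the aneuploid strain; the euploid reference
  # shares baselines (same seed) but carries no activation
  cfg_eu <- simulation_config(seed = seed, nb_dispersion = nb_dispersion)
  cfg_an <- simulation_config(seed = seed, compensation_fraction = compensation,
                              activated_sets = activated_sets,
                              nb_dispersion = nb_dispersion)
  eu <- simulate_counts(annotation, karyotype(character()), cfg_eu, assay,
                        seed_offset = 1)
  an <- simulate_counts(annotation, karyo, cfg_an, assay, seed_offset = 2)
  list(eu = compute_rpkm(eu, annotation)[, 1],
       an = compute_rpkm(an, annotation)[, 1])
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every n-draw from
# a universe of size N with K marked elements and count draws with >= k
# marks. Independent of the analytical path under test.
hyper_enum_p <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}
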