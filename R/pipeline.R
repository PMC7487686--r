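#' Build and validate a pipeline configuration
#'
#' Collects every knob of an end-to-end synthetic run: the strain's
#' karyotype, generator settings, the analysis thresholds (all defaulting
#' to the study values), and the sample-to-reference pairing map. The
#' pairing map is mandatory because every fold change is defined against
#' the euploid sample prepared in the same batch.
#'
#' @param strain Strain label.
#' @param duplicated Duplicated chromosomes of the strain.
#' @param pairing Named character vector mapping each aneuploid sample id
#'   to its batch euploid sample id.
#' @param seed Integer master seed.
#' @param n_chromosomes,genes_per_chromosome Genome size.
#' @param library_size,nb_dispersion,compensation_fraction,activated_sets
#'   Count-generator settings (see [simulation_config()]).
#' @param ct_sd,windows_per_chromosome,depth_noise_cv Karyotyping
#'   generator settings.
#' @param n_true_variants,n_noise_variants Variant-generator settings.
#' @param gene_sets Optional named list of gene sets to score.
#' @param thresholds List of analysis thresholds; missing entries take the
#'   defaults `up_log2 = 0.585`, `common_log2 = 0.38`,
#'   `min_freq_haploid = 0.70`, `min_freq_duplicated = 0.40`,
#'   `min_basequal = 15`, `min_mapqual = 15`, `compensation_tolerance = 0.3`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(strain = "D2", duplicated = "chrII",
                            pairing = c(aneuploid = "euploid"),
                            seed = 1, n_chromosomes = 16,
                            genes_per_chromosome = 125,
                            library_size = 5e6, nb_dispersion = 0.01,
                            compensation_fraction = 0,
                            activated_sets = list(),
                            ct_sd = 0.1, windows_per_chromosome = 200,
                            depth_noise_cv = 0.2,
                            n_true_variants = 20, n_noise_variants = 30,
                            gene_sets = NULL, thresholds = list()) {
  defaults <- list(up_log2 = 0.585, common_log2 = 0.38,
                   min_freq_haploid = 0.70, min_freq_duplicated = 0.40,
                   min_basequal = 15, min_mapqual = 15,
                   compensation_tolerance = 0.3)
  thresholds <- utils::modifyList(defaults, thresholds)
  if (is.null(pairing) || length(pairing) == 0 || is.null(names(pairing))) {
    stop("pairing map (aneuploid sample -> euploid sample) is required")
  }
  stopifnot(thresholds$up_log2 >= 0, thresholds$common_log2 >= 0,
            thresholds$min_freq_haploid >= 0,
            thresholds$min_freq_haploid <= 1)
  structure(list(
    strain = strain, duplicated = duplicated, pairing = pairing,
    seed = as.integer(seed), n_chromosomes = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    library_size = library_size, nb_dispersion = nb_dispersion,
    compensation_fraction = compensation_fraction,
    activated_sets = activated_sets, ct_sd = ct_sd,
    windows_per_chromosome = windows_per_chromosome,
    depth_noise_cv = depth_noise_cv,
    n_true_variants = n_true_variants,
    n_noise_variants = n_noise_variants,
    gene_sets = gene_sets, thresholds = thresholds
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  conf <- yaml::read_yaml(path)
  if (!is.null(conf$pairing)) conf$pairing <- unlist(conf$pairing)
  do.call(pipeline_config, conf)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a genome, simulates all inputs for one aneuploid strain plus
#' its euploid reference, and runs every analysis stage: qPCR and
#' windowed-depth karyotyping, RPKM + euploid-anchored normalization and
#' fold changes for both assays, ribosome density, per-chromosome dosage
#' summaries, optional signature scoring, per-chromosome enrichment of the
#' upregulated set, and variant filtering with wild-type subtraction. The
#' run is fully deterministic given the configuration.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a JSON manifest recording the package version,
#'   seed, thresholds and output checksums.
#' @return Named list of result objects (see Details in the vignette).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds

  annotation <- simulate_genome(config$n_chromosomes,
                                config$genes_per_chromosome,
                                seed = config$seed, include_mito = TRUE)
  truth <- karyotype(config$duplicated, config$n_chromosomes)
  euploid <- karyotype(character(), config$n_chromosomes)

  # -- karyotyping ---------------------------------------------------------
  qpcr_ref <- simulate_qpcr(euploid, ct_sd = config$ct_sd,
                            seed = config$seed + 11L)
  qpcr_strain <- simulate_qpcr(truth, ct_sd = config$ct_sd,
                               seed = config$seed + 12L)
  karyo_qpcr <- estimate_copy_number_qpcr(qpcr_strain, qpcr_ref)

  wgs_ref <- simulate_wgs_depth(euploid, config$windows_per_chromosome,
                                config$depth_noise_cv,
                                seed = config$seed + 21L)
  wgs_strain <- simulate_wgs_depth(truth, config$windows_per_chromosome,
                                   config$depth_noise_cv,
                                   seed = config$seed + 22L)
  karyo_wgs <- wgs_window_copy_profile(wgs_strain, wgs_ref)

  # -- expression ----------------------------------------------------------
  # the euploid reference shares gene baselines (same seed) but carries
  # neither the strain's copy-number effect nor its activated programs
  sim_eu <- simulation_config(library_size = config$library_size,
                              nb_dispersion = config$nb_dispersion,
                              seed = config$seed)
  sim_an <- simulation_config(library_size = config$library_size,
                              nb_dispersion = config$nb_dispersion,
                              compensation_fraction = config$compensation_fraction,
                              activated_sets = config$activated_sets,
                              seed = config$seed)
  profiles <- list()
  for (assay in c("mRNA", "FP")) {
    eu_counts <- simulate_counts(annotation, euploid, sim_eu, assay,
                                 seed_offset = 1)
    an_counts <- simulate_counts(annotation, truth, sim_an, assay,
                                 seed_offset = 2)
    eu_rpkm <- compute_rpkm(eu_counts, annotation)[, 1]
    an_rpkm <- compute_rpkm(an_counts, annotation)[, 1]
    norm <- normalize_to_euploid(an_rpkm, eu_rpkm, annotation, truth)
    lfc <- log2_fold_changes(norm$rpkm, eu_rpkm)
    profiles[[assay]] <- list(eu_rpkm = eu_rpkm, rpkm = an_rpkm,
                              rpkm_normalized = norm$rpkm,
                              scale_factor = norm$scale_factor,
                              log2_fc = lfc)
  }
  rd <- ribosome_density(profiles$FP$rpkm_normalized,
                         profiles$mRNA$rpkm_normalized,
                         profiles$FP$log2_fc, profiles$mRNA$log2_fc)
  dosage <- lapply(profiles, function(p) {
    chromosome_dosage_summary(p$log2_fc, annotation, truth,
                              tolerance = th$compensation_tolerance)
  })

  signatures <- NULL
  if (!is.null(config$gene_sets)) {
    signatures <- dplyr::bind_rows(lapply(names(config$gene_sets), function(nm) {
      set <- config$gene_sets[[nm]]
      if (!inherits(set, "gene_set")) set <- gene_set(nm, set)
      dplyr::bind_rows(lapply(c("mRNA", "FP"), function(assay) {
        sc <- score_gene_set(profiles[[assay]]$log2_fc, set, annotation, truth)
        tibble::tibble(strain = config$strain, set = nm, assay = assay,
                       mean_log2_fc = sc$score,
                       n_genes_used = sc$n_genes_used)
      }))
    }))
  }

  # -- enrichment of the upregulated FP set over chromosome terms ----------
  up <- select_regulated_genes(profiles$FP$log2_fc, annotation, truth,
                               threshold_log2 = th$up_log2, direction = "up")
  universe <- names(profiles$FP$log2_fc)[!is.na(profiles$FP$log2_fc)]
  terms <- split(annotation$gene_id, annotation$chromosome)
  terms <- terms[names(terms) != "chrMito"]
  enrichment <- hypergeometric_enrichment(intersect(up, universe), terms,
                                          universe)

  # -- variants ------------------------------------------------------------
  var_strain <- simulate_variants(annotation, truth,
                                  config$n_true_variants,
                                  config$n_noise_variants,
                                  seed = config$seed + 31L)
  var_wt <- simulate_variants(annotation, euploid,
                              max(1, config$n_true_variants %/% 2), 0,
                              seed = config$seed + 32L)
  var_unique <- subtract_wt(var_strain, var_wt)
  var_filtered <- filter_variants(var_unique, truth,
                                  min_basequal = th$min_basequal,
                                  min_mapqual = th$min_mapqual,
                                  min_freq_haploid = th$min_freq_haploid,
                                  min_freq_duplicated = th$min_freq_duplicated)

  manifest <- list(
    package = "aneudose",
    version = as.character(utils::packageVersion("aneudose")),
    strain = config$strain, seed = config$seed,
    duplicated = config$duplicated, thresholds = th,
    generator = list(
      n_chromosomes = config$n_chromosomes,
      genes_per_chromosome = config$genes_per_chromosome,
      library_size = config$library_size,
      nb_dispersion = config$nb_dispersion,
      compensation_fraction = config$compensation_fraction,
      ct_sd = config$ct_sd,
      windows_per_chromosome = config$windows_per_chromosome,
      depth_noise_cv = config$depth_noise_cv
    )
  )

  result <- list(
    annotation = annotation, karyotype_true = truth,
    karyotype_qpcr = karyo_qpcr, karyotype_wgs = karyo_wgs,
    profiles = profiles, ribosome_density = rd, dosage = dosage,
    signatures = signatures, upregulated = up, enrichment = enrichment,
    variants = var_filtered, manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wr(karyo_qpcr, "karyotype_qpcr.tsv")
    wr(karyo_wgs$estimates, "karyotype_wgs.tsv")
    for (assay in c("mRNA", "FP")) {
      p <- profiles[[assay]]
      wr(tibble::tibble(gene_id = names(p$log2_fc), rpkm = unname(p$rpkm),
                        rpkm_normalized = unname(p$rpkm_normalized),
                        log2_fc = unname(p$log2_fc)),
         sprintf("profile_%s.tsv", assay))
      wr(dosage[[assay]], sprintf("dosage_%s.tsv", assay))
    }
    wr(rd, "ribosome_density.tsv")
    if (!is.null(signatures)) wr(signatures, "signatures.tsv")
    wr(enrichment, "enrichment_FP.tsv")
    write_variants(var_filtered, file.path(out_dir, "variants_filtered.tsv"))
    files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result$manifest <- manifest
  result
}
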