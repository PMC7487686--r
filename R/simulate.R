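#' Simulate a compact yeast-like genome annotation
#'
#' Generates non-overlapping coding sequences on each chromosome with
#' lengths drawn uniformly from `length_range` and rounded to whole codons.
#' Coordinates are 1-based inclusive, as in the exported annotation tables.
#'
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param genes_per_chromosome Genes placed on each chromosome.
#' @param length_range Numeric length-2 vector: min and max CDS length (bp);
#'   minimum must be at least 3 (one codon).
#' @param seed Integer seed; identical seeds give identical annotations.
#' @param include_mito Append a `"chrMito"` chromosome with the same number
#'   of genes (mitochondrial genes are excluded from expression analyses but
#'   must exist to exercise that exclusion).
#' @param intergenic_range Uniform range for gaps between adjacent CDSs (bp).
#' @param with_sequence Attach a random CDS nucleotide sequence per gene
#'   (`cds_seq` column), needed only for coding-effect classification.
#' @return Tibble with columns `gene_id`, `chromosome`, `cds_start`,
#'   `cds_end`, `strand`, `cds_length_bp` (and optionally `cds_seq`).
#' @export
simulate_genome <- function(n_chromosomes = 16, genes_per_chromosome = 10,
                            length_range = c(300, 3000), seed = 1,
                            include_mito = FALSE,
                            intergenic_range = c(200, 2000),
                            with_sequence = FALSE) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  if (length(length_range) != 2 || length_range[1] < 3 ||
      length_range[1] > length_range[2]) {
    stop("length_range must be (min_bp, max_bp) with min_bp >= 3")
  }
  withr::local_seed(seed)
  chroms <- yeast_chromosomes(n_chromosomes, include_mito = include_mito)
  rows <- lapply(seq_along(chroms), function(ci) {
    n <- genes_per_chromosome
    len <- floor(stats::runif(n, length_range[1], length_range[2] + 1))
    len <- pmax(3L, (len %/% 3L) * 3L)  # whole codons
    gap <- floor(stats::runif(n, intergenic_range[1], intergenic_range[2] + 1))
    start <- cumsum(gap) + cumsum(c(0L, len[-n]))
    tibble::tibble(
      gene_id = sprintf("g%s.%03d", sub("^chr", "", chroms[ci]), seq_len(n)),
      chromosome = chroms[ci],
      cds_start = as.integer(start + 1L),
      cds_end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      cds_length_bp = as.integer(len)
    )
  })
  ann <- dplyr::bind_rows(rows)
  if (with_sequence) {
    ann$cds_seq <- vapply(ann$cds_length_bp, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  }
  ann
}

#' Simulation configuration for count generation
#'
#' Bundles the parameters of the expression simulator: genes are expressed
#' proportionally to chromosome copy number attenuated by a dosage
#' compensation fraction, with optional activated gene sets, and counts are
#' drawn from a negative binomial around expectations scaled to a target
#' library size.
#'
#' @param library_size Target total reads per sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param compensation_fraction Dosage-compensation dial in \[0, 1\]:
#'   0 means expression fully proportional to copy number (the behaviour
#'   observed in the tolerant disome strains), 1 means full compensation.
#' @param activated_sets List of activation specs, each a list with
#'   `members` (gene ids), `log2_effect`, and optional `assay`
#'   (`"both"`, `"mRNA"` or `"FP"`; default both) — used to plant
#'   stress-signature-like programs.
#' @param baseline_sdlog Log-normal spread of per-gene baseline abundance.
#' @param seed Integer seed controlling baselines and counts.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(library_size = 5e6, nb_dispersion = 0.01,
                              compensation_fraction = 0,
                              activated_sets = list(),
                              baseline_sdlog = 1, seed = 1) {
  if (compensation_fraction < 0 || compensation_fraction > 1) {
    stop("compensation_fraction must lie in [0, 1]")
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(
    library_size = library_size,
    nb_dispersion = nb_dispersion,
    compensation_fraction = compensation_fraction,
    activated_sets = activated_sets,
    baseline_sdlog = baseline_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a read-count matrix for one assay
#'
#' Expected expression of gene g is
#' `baseline_g * cn_g^(1 - compensation_fraction) * 2^(activation effect)`,
#' rescaled so expectations sum to the configured library size; counts are
#' negative binomial. Baselines depend only on the configuration seed, so
#' aneuploid and euploid samples simulated from the same config share them —
#' fold changes then reflect copy number and planted effects alone.
#'
#' @param annotation Genome annotation from [simulate_genome()].
#' @param karyotype_ Karyotype vector; every nuclear chromosome in the
#'   annotation must be present.
#' @param config A [simulation_config()].
#' @param assay `"mRNA"` or `"FP"` (ribosome footprints).
#' @param n_samples Number of replicate samples (columns).
#' @param sample_names Optional column names.
#' @param seed_offset Distinct offsets give strains simulated from one
#'   config independent sampling noise while sharing baselines.
#' @return Integer matrix, genes x samples, with gene ids as row names.
#' @export
simulate_counts <- function(annotation, karyotype_, config,
                            assay = c("mRNA", "FP"), n_samples = 1,
                            sample_names = NULL, seed_offset = 0) {
  assay <- match.arg(assay)
  stopifnot(inherits(config, "sim_config"))
  cn <- gene_copy_number(annotation, karyotype_)  # errors on missing chrom

  # baselines: a function of the config seed only
  baseline <- withr::with_seed(config$seed,
    stats::rlnorm(nrow(annotation), meanlog = 0, sdlog = config$baseline_sdlog))

  effect <- rep.int(0, nrow(annotation))
  for (act in config$activated_sets) {
    set_assay <- if (is.null(act$assay)) "both" else act$assay
    if (set_assay %in% c("both", assay)) {
      hit <- annotation$gene_id %in% act$members
      effect[hit] <- effect[hit] + act$log2_effect
    }
  }

  rel <- baseline * cn^(1 - config$compensation_fraction) * 2^effect
  mu <- rel / sum(rel) * config$library_size

  counts <- matrix(0L, nrow = nrow(annotation), ncol = n_samples,
                   dimnames = list(annotation$gene_id, sample_names))
  for (j in seq_len(n_samples)) {
    draw_seed <- (config$seed + 7919 * match(assay, c("mRNA", "FP")) +
                    104729 * j + 15485863 * seed_offset) %%
      .Machine$integer.max
    counts[, j] <- withr::with_seed(draw_seed, {
      if (config$nb_dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      }
    })
  }
  if (is.null(sample_names)) {
    colnames(counts) <- sprintf("%s_s%d", assay, seq_len(n_samples))
  }
  counts
}

#' Simulate a qPCR karyotyping plate
#'
#' Under perfect amplification efficiency 2, a chromosome present in `c`
#' copies crosses threshold `log2(c)` cycles earlier than the single-copy
#' reference: `Ct = reference_ct - log2(copy) + Normal(0, ct_sd)`. Both
#' chromosome arms are probed with 3 technical replicates each, matching the
#' arm-probe design of the karyotyping assay.
#'
#' @param karyotype_ Karyotype vector.
#' @param ct_sd Technical replicate noise on Ct (cycles).
#' @param reference_ct Single-copy crossing threshold (cycles).
#' @param n_replicates Technical replicates per probe.
#' @param seed Integer seed.
#' @return Tibble with columns `chromosome`, `arm` (`"L"`/`"R"`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(karyotype_, ct_sd = 0.1, reference_ct = 20,
                          n_replicates = 3, seed = 1) {
  if (ct_sd < 0) stop("ct_sd must be >= 0")
  withr::local_seed(seed)
  grid <- expand.grid(chromosome = names(karyotype_), arm = c("L", "R"),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$chromosome, names(karyotype_)),
                     grid$arm, grid$replicate), ]
  copies <- unname(karyotype_[grid$chromosome])
  ct <- reference_ct - log2(copies) + stats::rnorm(nrow(grid), 0, ct_sd)
  tibble::as_tibble(cbind(grid, ct = ct))
}

#' Simulate 1-kb windowed sequencing depth
#'
#' Window RPKM is proportional to chromosome copy number with multiplicative
#' log-normal noise of the stated coefficient of variation. Exported window
#' coordinates are 1-based inclusive (`window_start`, `window_end`), each
#' window spanning exactly 1000 bp.
#'
#' @param karyotype_ Karyotype vector.
#' @param windows_per_chromosome Windows per chromosome.
#' @param depth_noise_cv Coefficient of variation of the multiplicative
#'   noise (0 = noiseless).
#' @param base_rpkm Mean window RPKM at single copy.
#' @param seed Integer seed.
#' @return Tibble `chromosome`, `window_start`, `window_end`, `rpkm`.
#' @export
simulate_wgs_depth <- function(karyotype_, windows_per_chromosome = 200,
                               depth_noise_cv = 0.2, base_rpkm = 50,
                               seed = 1) {
  if (depth_noise_cv < 0) stop("depth_noise_cv must be >= 0")
  withr::local_seed(seed)
  w <- windows_per_chromosome
  chrom <- rep(names(karyotype_), each = w)
  start <- rep.int((seq_len(w) - 1L) * 1000L + 1L, length(karyotype_))
  copies <- rep(unname(karyotype_), each = w)
  noise <- if (depth_noise_cv == 0) {
    rep.int(1, length(chrom))
  } else {
    sdlog <- sqrt(log(1 + depth_noise_cv^2))
    stats::rlnorm(length(chrom), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble::tibble(
    chromosome = chrom,
    window_start = start,
    window_end = start + 999L,
    rpkm = base_rpkm * copies * noise
  )
}

#' Simulate a variant table with ground-truth labels
#'
#' True variants are haploid homozygous (allele frequency in \[0.9, 1\]) on
#' single-copy chromosomes and heterozygous (frequency near 0.5) on
#' duplicated chromosomes, with high base and mapping qualities. Noise
#' records fail at least one filter by construction: low frequency
#' (< 0.3), or base/mapping quality below 15.
#'
#' @param annotation Genome annotation (positions drawn within its span).
#' @param karyotype_ Karyotype vector.
#' @param n_true,n_noise Numbers of true and noise records.
#' @param seed Integer seed.
#' @return Tibble `chromosome`, `position`, `ref`, `alt`, `frequency`,
#'   `base_quality`, `mapping_quality`, `truth` (`"true"`/`"noise"`).
#' @export
simulate_variants <- function(annotation, karyotype_, n_true = 20,
                              n_noise = 30, seed = 1) {
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  chroms <- names(karyotype_)
  span <- vapply(chroms, function(ch) {
    idx <- annotation$chromosome == ch
    if (any(idx)) max(annotation$cds_end[idx]) + 1000L else 10000L
  }, numeric(1))
  # when the annotation carries CDS sequences, the ref allele of a variant
  # falling inside a gene must be the actual genomic base there
  genomic_base <- function(ch, p) {
    hit <- which(annotation$chromosome == ch & annotation$cds_start <= p &
                   annotation$cds_end >= p)
    if (length(hit) == 0) return(NA_character_)
    g <- annotation[hit[1], ]
    if (g$strand == "+") {
      substr(g$cds_seq, p - g$cds_start + 1L, p - g$cds_start + 1L)
    } else {
      chartr("ACGT", "TGCA",
             substr(g$cds_seq, g$cds_end - p + 1L, g$cds_end - p + 1L))
    }
  }
  draw <- function(n, truth) {
    ch <- sample(chroms, n, replace = TRUE)
    pos <- vapply(ch, function(c_) sample.int(span[[c_]], 1), numeric(1))
    ref <- sample(bases, n, replace = TRUE)
    if ("cds_seq" %in% names(annotation)) {
      actual <- mapply(genomic_base, ch, pos)
      ref[!is.na(actual)] <- actual[!is.na(actual)]
    }
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    dup <- ch %in% duplicated_chromosomes(karyotype_)
    if (truth == "true") {
      freq <- ifelse(dup, stats::runif(n, 0.45, 0.55), stats::runif(n, 0.9, 1))
      bq <- stats::runif(n, 25, 40)
      mq <- stats::runif(n, 30, 60)
    } else {
      mode <- sample(c("freq", "basequal", "mapqual"), n, replace = TRUE)
      freq <- ifelse(mode == "freq", stats::runif(n, 0.02, 0.29),
                     stats::runif(n, 0.5, 1))
      bq <- ifelse(mode == "basequal", stats::runif(n, 2, 14.5),
                   stats::runif(n, 25, 40))
      mq <- ifelse(mode == "mapqual", stats::runif(n, 2, 14.5),
                   stats::runif(n, 30, 60))
    }
    tibble::tibble(chromosome = ch, position = as.integer(pos), ref = ref,
                   alt = alt, frequency = freq, base_quality = bq,
                   mapping_quality = mq, truth = truth)
  }
  out <- dplyr::bind_rows(
    if (n_true > 0) draw(n_true, "true"),
    if (n_noise > 0) draw(n_noise, "noise")
  )
  out[order(match(out$chromosome, chroms), out$position), ]
}

#' Simulate a pulse-chase decay series
#'
#' Labelled protein decays exponentially:
#' `intensity(t) = 100 * 2^(-t / half_life) + Normal(0, noise_sd)`,
#' floored at zero.
#'
#' @param half_life_min True half-life in minutes.
#' @param timepoints Chase times in minutes (should include 0).
#' @param noise_sd Additive measurement noise (intensity units).
#' @param n_replicates Independent experiments.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `time_min`, `intensity`.
#' @export
simulate_decay <- function(half_life_min = 30,
                           timepoints = c(0, 15, 30, 60),
                           noise_sd = 0, n_replicates = 3, seed = 1) {
  if (half_life_min <= 0) stop("half_life_min must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  withr::local_seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      time_min = timepoints,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$replicate, grid$time_min), ]
  mean_int <- 100 * 2^(-grid$time_min / half_life_min)
  intensity <- pmax(0, mean_int + stats::rnorm(nrow(grid), 0, noise_sd))
  tibble::tibble(replicate = grid$replicate, time_min = grid$time_min,
                 intensity = intensity)
}
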