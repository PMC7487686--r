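#' Estimate chromosome copy numbers from qPCR arm probes
#'
#' For each chromosome arm the mean Ct across technical replicates is
#' compared between the strain and a euploid reference; under amplification
#' efficiency 2 the arm copy number is
#' `base_ploidy * 2^(reference_mean_ct - strain_mean_ct)`. The two arm
#' estimates are averaged into `copy_mean`, their standard deviation gives
#' `copy_sd` (the between-arm error bar), and the integer call is the
#' nearest integer to `copy_mean`, floored at 1.
#'
#' @param ct_table qPCR table for the strain: columns `chromosome`, `arm`
#'   (`"L"`/`"R"`), `replicate`, `ct`.
#' @param reference_ct_table Same layout, for the euploid reference strain.
#' @param base_ploidy Reference ploidy (1 for haploids).
#' @return Tibble `chromosome`, `copy_mean`, `copy_sd`, `call`.
#' @export
estimate_copy_number_qpcr <- function(ct_table, reference_ct_table,
                                      base_ploidy = 1) {
  for (tab in list(strain = ct_table, reference = reference_ct_table)) {
    if (any(tab$ct <= 0)) stop("non-positive Ct value encountered")
  }
  chroms <- unique(ct_table$chromosome)
  arm_mean <- function(tab, chrom, arm) {
    v <- tab$ct[tab$chromosome == chrom & tab$arm == arm]
    if (length(v) == 0) {
      stop(sprintf("missing arm %s for chromosome %s", arm, chrom))
    }
    mean(v)
  }
  res <- lapply(chroms, function(ch) {
    arm_copy <- vapply(c("L", "R"), function(a) {
      base_ploidy * 2^(arm_mean(reference_ct_table, ch, a) -
                         arm_mean(ct_table, ch, a))
    }, numeric(1))
    tibble::tibble(
      chromosome = ch,
      copy_mean = mean(arm_copy),
      copy_sd = stats::sd(arm_copy),
      call = max(1L, as.integer(round(mean(arm_copy))))
    )
  })
  dplyr::bind_rows(res)
}

#' Copy-number profile from 1-kb windowed depth
#'
#' Computes per-window log2 depth ratios between an aneuploid strain and
#' the euploid reference, summarises each chromosome by the median window
#' log2 ratio (robust to depth spikes), converts it to a copy-number
#' estimate `base_ploidy * 2^median`, and screens for large segmental
#' abnormalities: a contiguous run of at least `min_run_windows` windows
#' deviating from the chromosome-level call by at least
#' `segment_log2_threshold` raises a flag for that chromosome.
#'
#' Windows with zero euploid RPKM are excluded (and counted); strain-zero
#' windows yield undefined ratios and are likewise excluded from summaries.
#'
#' @param strain_windows,euploid_windows Window tables from
#'   [simulate_wgs_depth()] or equivalent: `chromosome`, `window_start`,
#'   `window_end`, `rpkm`. Grids must match exactly.
#' @param base_ploidy Reference ploidy.
#' @param min_run_windows Minimum run length for the segmental screen.
#' @param segment_log2_threshold Minimum absolute log2 deviation of a run.
#' @return List with `windows` (per-window profile incl. `log2_ratio`),
#'   `estimates` (per-chromosome `copy_mean`, `call`), `segmental_flags`
#'   (chromosomes with flagged runs), `n_excluded_windows`.
#' @export
wgs_window_copy_profile <- function(strain_windows, euploid_windows,
                                    base_ploidy = 1, min_run_windows = 50,
                                    segment_log2_threshold = 0.58) {
  key <- function(w) paste(w$chromosome, w$window_start, w$window_end)
  if (nrow(strain_windows) != nrow(euploid_windows) ||
      !all(key(strain_windows) == key(euploid_windows))) {
    stop("strain and euploid window grids do not match")
  }
  ratio <- strain_windows$rpkm / euploid_windows$rpkm
  defined <- euploid_windows$rpkm > 0 & strain_windows$rpkm > 0
  log2_ratio <- ifelse(defined, log2(ratio), NA_real_)
  windows <- tibble::tibble(
    chromosome = strain_windows$chromosome,
    window_start = strain_windows$window_start,
    window_end = strain_windows$window_end,
    rpkm = strain_windows$rpkm,
    log2_ratio = log2_ratio
  )

  chroms <- unique(windows$chromosome)
  est <- lapply(chroms, function(ch) {
    lr <- windows$log2_ratio[windows$chromosome == ch]
    med <- stats::median(lr, na.rm = TRUE)
    cm <- base_ploidy * 2^med
    tibble::tibble(chromosome = ch, median_log2_ratio = med,
                   copy_mean = cm,
                   call = max(1L, as.integer(round(cm))))
  })
  estimates <- dplyr::bind_rows(est)

  flagged <- vapply(chroms, function(ch) {
    lr <- windows$log2_ratio[windows$chromosome == ch]
    call_ <- estimates$call[estimates$chromosome == ch]
    dev <- abs(lr - log2(call_ / base_ploidy)) >= segment_log2_threshold
    dev[is.na(dev)] <- FALSE
    r <- rle(dev)
    any(r$values & r$lengths >= min_run_windows)
  }, logical(1))

  list(
    windows = windows,
    estimates = estimates,
    segmental_flags = chroms[flagged],
    n_excluded_windows = sum(!defined)
  )
}
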