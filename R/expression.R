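#' Compute RPKM from raw counts
#'
#' RPKM = reads per kilobase of coding sequence per million mapped reads.
#' Mitochondrial genes (`chrMito`) are removed before anything else, so the
#' per-sample mapped-read totals in the denominator are taken over nuclear
#' genes only, keeping the gene universe consistent across all downstream
#' steps.
#'
#' @param counts Integer matrix, genes x samples, gene ids as row names.
#' @param annotation Genome annotation with `gene_id`, `chromosome`,
#'   `cds_length_bp`.
#' @param drop_mito Exclude `chrMito` genes (the default throughout).
#' @return Numeric matrix of RPKM values (mito rows dropped).
#' @export
compute_rpkm <- function(counts, annotation, drop_mito = TRUE) {
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) {
    stop("genes missing from annotation: ",
         paste(utils::head(setdiff(rownames(counts), annotation$gene_id), 5),
               collapse = ", "))
  }
  if (any(ann$cds_length_bp <= 0)) stop("all cds_length_bp must be positive")
  if (drop_mito) {
    keep <- ann$chromosome != "chrMito"
    counts <- counts[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("sample(s) with zero mapped reads: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts / (ann$cds_length_bp / 1000), 2, totals / 1e6, "/")
}

#' Median-ratio normalization anchored on nonduplicated chromosomes
#'
#' Scales an aneuploid sample so that the median aneuploid/euploid RPKM
#' ratio over genes on nonduplicated chromosomes equals exactly 1: the
#' scale factor is the median of `aneu/eu` across nonduplicated genes with
#' positive euploid RPKM, and every aneuploid RPKM is divided by it.
#' Duplicated chromosomes are then read directly as departures from the
#' euploid baseline.
#'
#' @param aneu,eu Named numeric RPKM vectors (one sample each) over a
#'   shared gene universe.
#' @param annotation Genome annotation mapping genes to chromosomes.
#' @param karyotype_ Karyotype of the aneuploid strain.
#' @return List with `scale_factor` and `rpkm` (the normalized aneuploid
#'   vector).
#' @export
normalize_to_euploid <- function(aneu, eu, annotation, karyotype_) {
  shared <- intersect(names(aneu), names(eu))
  if (length(shared) == 0) stop("no shared genes between samples")
  chrom <- annotation$chromosome[match(shared, annotation$gene_id)]
  dup <- duplicated_chromosomes(karyotype_)
  eligible <- shared[!(chrom %in% dup) & chrom != "chrMito" &
                       eu[shared] > 0 & is.finite(aneu[shared])]
  if (length(eligible) == 0) {
    stop("no nonduplicated genes with positive euploid RPKM")
  }
  scale_factor <- stats::median(aneu[eligible] / eu[eligible])
  list(scale_factor = scale_factor, rpkm = aneu / scale_factor)
}

#' Per-gene log2 fold changes versus the euploid reference
#'
#' Genes where either side is zero (or missing) get `NA` rather than an
#' infinite fold change; no pseudocount is applied.
#'
#' @param aneu_norm Normalized aneuploid RPKM (named vector).
#' @param eu Euploid RPKM (named vector).
#' @return Named numeric vector of log2 fold changes over the shared genes.
#' @export
log2_fold_changes <- function(aneu_norm, eu) {
  shared <- intersect(names(aneu_norm), names(eu))
  a <- aneu_norm[shared]
  e <- eu[shared]
  ok <- !is.na(a) & !is.na(e) & a > 0 & e > 0
  lfc <- rep(NA_real_, length(shared))
  lfc[ok] <- log2(a[ok] / e[ok])
  stats::setNames(lfc, shared)
}

#' Ribosome density per gene
#'
#' Ribosome density (RD) is footprint RPKM divided by mRNA RPKM — a proxy
#' for translational efficiency. Its fold change versus the euploid is the
#' difference of the two assays' log2 fold changes.
#'
#' @param fp_rpkm,mrna_rpkm Normalized RPKM vectors for the same sample.
#' @param fp_log2_fc,mrna_log2_fc Optional per-assay log2 fold changes; if
#'   both given, `rd_log2_fc = fp_log2_fc - mrna_log2_fc`.
#' @return Tibble `gene_id`, `rd` (`NA` where mRNA RPKM is 0), and
#'   `rd_log2_fc` when fold changes were supplied.
#' @export
ribosome_density <- function(fp_rpkm, mrna_rpkm,
                             fp_log2_fc = NULL, mrna_log2_fc = NULL) {
  shared <- intersect(names(fp_rpkm), names(mrna_rpkm))
  rd <- ifelse(mrna_rpkm[shared] > 0,
               fp_rpkm[shared] / mrna_rpkm[shared], NA_real_)
  out <- tibble::tibble(gene_id = shared, rd = unname(rd))
  if (!is.null(fp_log2_fc) && !is.null(mrna_log2_fc)) {
    out$rd_log2_fc <- unname(fp_log2_fc[shared] - mrna_log2_fc[shared])
  }
  out
}

#' Per-chromosome dosage summary
#'
#' Summarises each chromosome by the median log2 fold change of its genes
#' and compares it to the expectation `log2(copy / base_ploidy)`. A
#' duplicated chromosome whose median falls short of the expectation by
#' more than `tolerance` is marked compensated; in the tolerant disome
#' strains none are.
#'
#' @param log2_fc Named log2 fold-change vector.
#' @param annotation Genome annotation.
#' @param karyotype_ Karyotype of the strain.
#' @param tolerance Log2 shortfall required to call compensation.
#' @return Tibble `chromosome`, `n_genes`, `median_log2_fc`,
#'   `expected_log2_fc`, `deviation`, `compensated`.
#' @export
chromosome_dosage_summary <- function(log2_fc, annotation, karyotype_,
                                      tolerance = 0.3) {
  chrom <- annotation$chromosome[match(names(log2_fc), annotation$gene_id)]
  bp <- base_ploidy(karyotype_)
  res <- lapply(names(karyotype_), function(ch) {
    v <- log2_fc[!is.na(chrom) & chrom == ch]
    v <- v[!is.na(v)]
    expected <- log2(karyotype_[[ch]] / bp)
    med <- if (length(v)) stats::median(v) else NA_real_
    tibble::tibble(
      chromosome = ch, n_genes = length(v), median_log2_fc = med,
      expected_log2_fc = expected, deviation = med - expected,
      compensated = expected > 0 && !is.na(med) && med < expected - tolerance
    )
  })
  dplyr::bind_rows(res)
}
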