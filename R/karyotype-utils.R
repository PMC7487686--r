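#' Standard yeast chromosome names
#'
#' @param n Number of nuclear chromosomes (16 for *S. cerevisiae*).
#' @param include_mito Append `"chrMito"` for the mitochondrial genome.
#' @return Character vector `"chrI"`, ..., `"chrXVI"` (and optionally
#'   `"chrMito"`).
#' @export
yeast_chromosomes <- function(n = 16, include_mito = FALSE) {
  stopifnot(n >= 1)
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(n))))
  if (include_mito) chroms <- c(chroms, "chrMito")
  chroms
}

#' Construct a karyotype
#'
#' A karyotype is a named integer vector mapping chromosome names to copy
#' numbers, relative to a haploid base ploidy. Duplicated chromosomes are
#' those whose copy number exceeds the base ploidy.
#'
#' @param duplicated Character vector of duplicated chromosome names, or
#'   integer indices into [yeast_chromosomes()].
#' @param n_chromosomes Number of nuclear chromosomes in the genome.
#' @param base_ploidy Base ploidy (1 for the haploid strains modelled here).
#' @param extra_copies Copies added to each duplicated chromosome (1 gives a
#'   disome in a haploid).
#' @return Named integer vector with attribute `base_ploidy`.
#' @examples
#' karyotype("chrII")          # disome II
#' karyotype(c(1, 2, 8))       # chromosomes I, II and VIII duplicated
#' @export
karyotype <- function(duplicated = character(), n_chromosomes = 16,
                      base_ploidy = 1L, extra_copies = 1L) {
  chroms <- yeast_chromosomes(n_chromosomes)
  if (is.numeric(duplicated)) duplicated <- chroms[duplicated]
  if (!all(duplicated %in% chroms)) {
    stop("unknown chromosome(s): ",
         paste(setdiff(duplicated, chroms), collapse = ", "))
  }
  cn <- stats::setNames(rep.int(as.integer(base_ploidy), n_chromosomes), chroms)
  cn[duplicated] <- cn[duplicated] + as.integer(extra_copies)
  attr(cn, "base_ploidy") <- as.integer(base_ploidy)
  cn
}

#' @rdname karyotype
#' @param k A karyotype vector.
#' @export
base_ploidy <- function(k) {
  bp <- attr(k, "base_ploidy")
  if (is.null(bp)) 1L else bp
}

#' @rdname karyotype
#' @export
duplicated_chromosomes <- function(k) {
  names(k)[k > base_ploidy(k)]
}

#' Karyotypes of the six aneuploid study strains
#'
#' The disome strains analysed throughout: D2, D1/2, D1/2/8, D1/2/8/11,
#' D1/8 and D13, where "D" marks a haploid with the listed chromosomes
#' duplicated.
#'
#' @return Named list of karyotype vectors.
#' @export
disome_karyotypes <- function() {
  list(
    "D2"        = karyotype("chrII"),
    "D1/2"      = karyotype(c("chrI", "chrII")),
    "D1/2/8"    = karyotype(c("chrI", "chrII", "chrVIII")),
    "D1/2/8/11" = karyotype(c("chrI", "chrII", "chrVIII", "chrXI")),
    "D1/8"      = karyotype(c("chrI", "chrVIII")),
    "D13"       = karyotype("chrXIII")
  )
}

# internal: map genes to copy numbers, failing loudly on unknown chromosomes
gene_copy_number <- function(annotation, karyotype_) {
  chroms <- annotation$chromosome
  known <- chroms %in% c(names(karyotype_), "chrMito")
  if (!all(known)) {
    stop("chromosome(s) absent from karyotype: ",
         paste(unique(chroms[!known]), collapse = ", "))
  }
  cn <- rep.int(base_ploidy(karyotype_), nrow(annotation))
  idx <- match(chroms, names(karyotype_))
  cn[!is.na(idx)] <- unname(karyotype_[idx[!is.na(idx)]])
  cn
}
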