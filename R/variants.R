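#' Filter variant calls by quality and allele frequency
#'
#' Keeps a record iff base quality and mapping quality are at least the
#' stated minima and the variant allele frequency reaches the
#' chromosome-dependent floor: 70% on single-copy chromosomes (homozygous
#' haploid variants) and 40% on duplicated chromosomes, where a real
#' heterozygous variant on one of the two copies is expected near 50%.
#' All comparisons are inclusive ("minimum ... of" read as >=).
#'
#' @param records Variant table: `chromosome`, `position`, `ref`, `alt`,
#'   `frequency`, `base_quality`, `mapping_quality`.
#' @param karyotype_ Karyotype of the strain (every record's chromosome
#'   must be present).
#' @param min_basequal,min_mapqual Quality floors.
#' @param min_freq_haploid,min_freq_duplicated Frequency floors.
#' @return The surviving records, in input order.
#' @export
filter_variants <- function(records, karyotype_, min_basequal = 15,
                            min_mapqual = 15, min_freq_haploid = 0.70,
                            min_freq_duplicated = 0.40) {
  unknown <- setdiff(unique(records$chromosome), names(karyotype_))
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from karyotype: ",
         paste(unknown, collapse = ", "))
  }
  dup <- records$chromosome %in% duplicated_chromosomes(karyotype_)
  freq_floor <- ifelse(dup, min_freq_duplicated, min_freq_haploid)
  keep <- records$base_quality >= min_basequal &
    records$mapping_quality >= min_mapqual &
    records$frequency >= freq_floor
  records[keep, , drop = FALSE]
}

#' Remove variants shared with the wild-type strain
#'
#' A strain record is removed iff a wild-type record matches it exactly on
#' `(chromosome, position, ref, alt)` — the perfect reciprocal match used
#' to isolate strain-unique variants.
#'
#' @param strain_records,wt_records Variant tables.
#' @return Strain records not present in the wild type.
#' @export
subtract_wt <- function(strain_records, wt_records) {
  dplyr::anti_join(strain_records, wt_records,
                   by = c("chromosome", "position", "ref", "alt"))
}

#' Classify the coding effect of single-nucleotide variants
#'
#' Each SNV falling inside an annotated CDS is translated before and after
#' the substitution (strand-aware, standard genetic code): an unchanged
#' amino acid is `synonymous`, a gained stop is `nonsense`, any other
#' change is `missense`. Positions outside all CDSs are `intergenic`;
#' records whose ref or alt is not a single base are `unclassified`.
#'
#' @param records Variant table (`chromosome`, `position`, `ref`, `alt`).
#' @param annotation Genome annotation carrying `cds_seq` (CDS nucleotide
#'   sequence in coding orientation), e.g. from
#'   `simulate_genome(with_sequence = TRUE)`.
#' @return `records` with an added `effect` column.
#' @export
classify_coding_effect <- function(records, annotation) {
  if (!("cds_seq" %in% names(annotation))) {
    stop("annotation must carry cds_seq (CDS sequences)")
  }
  code <- Biostrings::GENETIC_CODE
  comp <- function(b) chartr("ACGT", "TGCA", b)
  effect <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ref <- records$ref[i]; alt <- records$alt[i]
    if (nchar(ref) != 1 || nchar(alt) != 1) {
      effect[i] <- "unclassified"; next
    }
    hit <- which(annotation$chromosome == records$chromosome[i] &
                   annotation$cds_start <= records$position[i] &
                   annotation$cds_end >= records$position[i])
    if (length(hit) == 0) {
      effect[i] <- "intergenic"; next
    }
    g <- annotation[hit[1], ]
    if (g$strand == "+") {
      cpos <- records$position[i] - g$cds_start + 1L
      ref_c <- ref; alt_c <- alt
    } else {
      cpos <- g$cds_end - records$position[i] + 1L
      ref_c <- comp(ref); alt_c <- comp(alt)
    }
    codon_i <- (cpos - 1L) %/% 3L
    within <- (cpos - 1L) %% 3L + 1L
    codon <- substr(g$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (substr(codon, within, within) != ref_c) {
      stop(sprintf("ref allele %s does not match CDS of %s at position %d",
                   ref, g$gene_id, records$position[i]))
    }
    new_codon <- codon
    substr(new_codon, within, within) <- alt_c
    aa_old <- code[[codon]]
    aa_new <- code[[new_codon]]
    effect[i] <- if (aa_new == aa_old) "synonymous"
                 else if (aa_new == "*") "nonsense"
                 else "missense"
  }
  records$effect <- effect
  records
}
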