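# Readers and writers for the tab-separated dialects the pipeline consumes.
# All tables carry header rows; chromosome names follow "chrI".."chrXVI",
# "chrMito". Round trips are exact.

#' Read and write genome annotation tables
#'
#' @param path File path.
#' @param annotation Annotation tibble (see [simulate_genome()]).
#' @return `read_annotation()` returns the validated annotation tibble.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chromosome", "cds_start", "cds_end", "strand")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  bad <- which(tab$cds_start > tab$cds_end)
  if (length(bad) > 0) {
    stop("cds_start > cds_end at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header row
  }
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(tab$cds_length_bp)) {
    tab$cds_length_bp <- tab$cds_end - tab$cds_start + 1L
  }
  tibble::as_tibble(tab)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(start = annotation$cds_start,
                              end = annotation$cds_end),
    strand = annotation$strand,
    type = "CDS",
    ID = annotation$gene_id,
    phase = 0L
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  tibble::tibble(
    gene_id = df$ID,
    chromosome = as.character(df$seqnames),
    cds_start = df$start,
    cds_end = df$end,
    strand = as.character(df$strand),
    cds_length_bp = df$end - df$start + 1L
  )
}

#' Read and write count matrices
#'
#' Genes x samples, first column `gene_id`. Reading validates that all
#' counts are numeric and non-negative and that gene ids are unique,
#' reporting the offending row and column.
#'
#' @param path File path.
#' @param counts Count matrix with gene-id row names.
#' @return `read_counts()` returns an integer matrix.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("counts must be numeric")
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for gene %s in sample %s",
                 tab$gene_id[idx["row"]], colnames(mat)[idx["col"]]))
  }
  rownames(mat) <- tab$gene_id
  mat
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> members...`.
#' Duplicated members within a set are dropped with a warning.
#'
#' @param path File path.
#' @param sets Named list of character vectors (or of [gene_set()]s).
#' @return `read_gmt()` returns a named list of member vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    m <- sets[[nm]]
    if (anyDuplicated(m)) {
      warning(sprintf("gene set '%s' lists duplicated member(s); deduplicated",
                      nm))
      m <- unique(m)
    }
    m
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    if (inherits(members, "gene_set")) members <- members$members
    paste(c(nm, nm, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write variant tables
#'
#' VCF-like TSV with columns CHROM, POS, REF, ALT, FREQ, BASEQ, MAPQ,
#' mapped to the internal column names.
#'
#' @param path File path.
#' @param records Variant tibble (internal column names).
#' @return `read_variants()` returns the variant tibble.
#' @export
read_variants <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("CHROM", "POS", "REF", "ALT", "FREQ", "BASEQ", "MAPQ")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tab$FREQ < 0 | tab$FREQ > 1)) {
    stop("FREQ must lie in [0, 1] at line(s) ",
         paste(which(tab$FREQ < 0 | tab$FREQ > 1) + 1L, collapse = ", "))
  }
  tibble::tibble(
    chromosome = tab$CHROM, position = as.integer(tab$POS),
    ref = tab$REF, alt = tab$ALT, frequency = tab$FREQ,
    base_quality = tab$BASEQ, mapping_quality = tab$MAPQ
  )
}

#' @rdname read_variants
#' @export
write_variants <- function(records, path) {
  out <- data.frame(
    CHROM = records$chromosome, POS = records$position, REF = records$ref,
    ALT = records$alt, FREQ = records$frequency,
    BASEQ = records$base_quality, MAPQ = records$mapping_quality
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write karyotype tables
#'
#' @param path File path.
#' @param karyotype_ Karyotype vector.
#' @param base_ploidy Base ploidy attached on read.
#' @return `read_karyotype()` returns a karyotype vector.
#' @export
read_karyotype <- function(path, base_ploidy = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  k <- stats::setNames(as.integer(tab$copy_number), tab$chromosome)
  if (any(k < 1)) stop("copy numbers must be >= 1")
  attr(k, "base_ploidy") <- as.integer(base_ploidy)
  k
}

#' @rdname read_karyotype
#' @export
write_karyotype <- function(karyotype_, path) {
  utils::write.table(
    data.frame(chromosome = names(karyotype_),
               copy_number = as.integer(karyotype_)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
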