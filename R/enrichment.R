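#' Select differentially regulated nonduplicated genes
#'
#' Picks genes whose log2 fold change passes the threshold (inclusive at
#' the boundary, matching an "at least x-fold" rule) in the requested
#' direction, after removing genes on duplicated or explicitly excluded
#' chromosomes and genes with undefined fold changes.
#'
#' @param log2_fc Named log2 fold-change vector.
#' @param annotation Genome annotation.
#' @param karyotype_ Karyotype of the strain.
#' @param threshold_log2 Non-negative log2 threshold (0.585 corresponds to
#'   1.5-fold, 0.38 to 1.3-fold).
#' @param direction `"up"` (log2 FC >= threshold) or `"down"` (<= -threshold).
#' @param exclude_chromosomes Additional chromosomes to drop.
#' @return Character vector of gene ids.
#' @export
select_regulated_genes <- function(log2_fc, annotation, karyotype_,
                                   threshold_log2 = 0.585,
                                   direction = c("up", "down"),
                                   exclude_chromosomes = character()) {
  direction <- match.arg(direction)
  if (threshold_log2 < 0) stop("threshold_log2 must be >= 0")
  chrom <- annotation$chromosome[match(names(log2_fc), annotation$gene_id)]
  drop <- c(duplicated_chromosomes(karyotype_), exclude_chromosomes, "chrMito")
  ok <- !is.na(log2_fc) & !is.na(chrom) & !(chrom %in% drop)
  hit <- if (direction == "up") log2_fc >= threshold_log2
         else log2_fc <= -threshold_log2
  names(log2_fc)[ok & hit]
}

#' Hypergeometric enrichment over a term map
#'
#' For each term, tests over-representation of the query set in the term's
#' members within the universe with an upper-tail hypergeometric test:
#' `p = P(X >= k)` for `k` query genes in a term of size `K`, query size
#' `n`, universe size `N`. Bonferroni correction multiplies by the number
#' of terms actually testable (at least one member in the universe).
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param terms Named list: term id -> member gene ids.
#' @param universe Character vector of gene ids defining the background.
#' @return Tibble `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_bonferroni`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(query, terms, universe) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  K <- vapply(terms, function(m) length(intersect(m, universe)), integer(1))
  testable <- names(terms)[K >= 1]
  if (length(testable) == 0) stop("no testable term overlaps the universe")
  res <- lapply(testable, function(tm) {
    K_ <- K[[tm]]
    k <- length(intersect(query, intersect(terms[[tm]], universe)))
    p <- stats::phyper(k - 1, K_, N - K_, n, lower.tail = FALSE)
    tibble::tibble(term_id = tm, k = k, K = K_, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_bonferroni <- pmin(1, out$p_value * length(testable))
  out[order(out$p_value, out$term_id), ]
}

#' Genes upregulated in common across strains, with functional categories
#'
#' Intersects per-strain upregulated gene sets (nonduplicated chromosomes
#' only, default threshold 0.38 log2 = 30% increase), removes genes on the
#' shared duplicated chromosome (chromosome II by default), and assigns
#' each surviving gene to one curated functional category.
#'
#' @param log2_fc_list Named list: strain -> named FP log2 fold-change
#'   vector.
#' @param annotation Genome annotation.
#' @param karyotypes Named list: strain -> karyotype.
#' @param threshold_log2 Log2 threshold for "upregulated".
#' @param exclude_chromosomes Chromosomes removed from the final list.
#' @param categories Two-column data frame (`gene`, `category`), e.g.
#'   [upregulated_gene_categories()]. If `NULL`, categorization is skipped.
#' @return List with `genes` (the intersection), `category_counts`
#'   (tibble `category`, `n`), and `assignments`.
#' @export
common_upregulated <- function(log2_fc_list, annotation, karyotypes,
                               threshold_log2 = 0.38,
                               exclude_chromosomes = "chrII",
                               categories = NULL) {
  per_strain <- lapply(names(log2_fc_list), function(s) {
    select_regulated_genes(log2_fc_list[[s]], annotation, karyotypes[[s]],
                           threshold_log2 = threshold_log2, direction = "up",
                           exclude_chromosomes = exclude_chromosomes)
  })
  genes <- Reduce(intersect, per_strain)
  out <- list(genes = genes)
  if (!is.null(categories)) {
    counted <- categorize_genes(genes, categories)
    out$category_counts <- counted$counts
    out$assignments <- counted$assignments
  }
  out
}

#' Curated functional categories of the shared upregulated genes
#'
#' The packaged curation table maps each of the 251 genes found upregulated
#' by at least 30% at the footprint level in all four chromosome-II disome
#' strains to one of twelve functional categories (ribosome homeostasis,
#' protein degradation/quality control, metabolism, ...), as assigned
#' manually from SGD gene descriptions.
#'
#' @return Tibble with columns `gene` and `category`.
#' @export
upregulated_gene_categories <- function() {
  path <- system.file("extdata", "upregulated_gene_categories.tsv",
                      package = "aneudose", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Assign genes to curated categories and count them
#'
#' @param genes Character vector of gene names.
#' @param categories Data frame `gene`, `category`; each gene belongs to
#'   exactly one category.
#' @return List with `assignments` (tibble `gene`, `category`; unmapped
#'   genes get `"uncategorized"`) and `counts` (tibble `category`, `n`, in
#'   the category order of the curation table).
#' @export
categorize_genes <- function(genes, categories) {
  if (anyDuplicated(categories$gene)) {
    stop("category table assigns some gene more than once")
  }
  cat_of <- categories$category[match(genes, categories$gene)]
  cat_of[is.na(cat_of)] <- "uncategorized"
  levels_ <- unique(c(categories$category, "uncategorized"))
  counts <- table(factor(cat_of, levels = levels_))
  counts <- counts[counts > 0 | names(counts) != "uncategorized"]
  list(
    assignments = tibble::tibble(gene = genes, category = cat_of),
    counts = tibble::tibble(category = names(counts),
                            n = as.integer(counts))
  )
}
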