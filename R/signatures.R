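#' Construct a gene set
#'
#' @param name Set name (e.g. `"ESR_induced"`).
#' @param members Character vector of gene ids; duplicates are dropped.
#' @param direction `"induced"`, `"repressed"`, or `"none"` — how the set
#'   behaves in its canonical stress program.
#' @return List of class `"gene_set"`.
#' @export
gene_set <- function(name, members, direction = c("none", "induced",
                                                  "repressed")) {
  direction <- match.arg(direction)
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set must have at least one member")
  structure(list(name = name, members = members, direction = direction),
            class = "gene_set")
}

#' Score a stress-signature gene set in one sample
#'
#' The signature score is the average log2 fold change (versus the euploid
#' reference) over member genes that lie on nonduplicated chromosomes for
#' the scored strain and have a defined fold change. Members on duplicated
#' chromosomes are excluded so that dosage itself cannot masquerade as a
#' stress response.
#'
#' @param log2_fc Named log2 fold-change vector for one sample.
#' @param set A [gene_set()] (or list with a `members` field).
#' @param annotation Genome annotation.
#' @param karyotype_ Karyotype of the scored strain.
#' @return List with `score` (mean log2 FC) and `n_genes_used`.
#' @export
score_gene_set <- function(log2_fc, set, annotation, karyotype_) {
  members <- set$members
  chrom <- annotation$chromosome[match(members, annotation$gene_id)]
  dup <- duplicated_chromosomes(karyotype_)
  eligible <- members[!is.na(chrom) & !(chrom %in% dup) & chrom != "chrMito"]
  vals <- log2_fc[intersect(eligible, names(log2_fc))]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop(sprintf("gene set '%s' has no eligible member with a defined fold change",
                 if (is.null(set$name)) "<unnamed>" else set$name))
  }
  list(score = mean(vals), n_genes_used = length(vals))
}

#' Build a signature heatmap matrix across strains and replicates
#'
#' Rows are the member genes that are (a) on chromosomes nonduplicated in
#' every strain shown and (b) have a defined log2 fold change in every
#' sample; columns follow the supplied sample order (conventionally
#' suffixed `_1`/`_2` for biological replicates).
#'
#' @param log2_fc_list Named list: sample id -> named log2 fold-change
#'   vector.
#' @param set A [gene_set()].
#' @param annotation Genome annotation.
#' @param karyotypes Named list: sample id -> karyotype (same names as
#'   `log2_fc_list`).
#' @return Numeric matrix, qualifying genes x samples.
#' @export
signature_matrix <- function(log2_fc_list, set, annotation, karyotypes) {
  stopifnot(length(log2_fc_list) >= 1,
            all(names(log2_fc_list) %in% names(karyotypes)))
  dup_any <- unique(unlist(lapply(names(log2_fc_list), function(s) {
    duplicated_chromosomes(karyotypes[[s]])
  })))
  chrom <- annotation$chromosome[match(set$members, annotation$gene_id)]
  candidates <- set$members[!is.na(chrom) & !(chrom %in% dup_any) &
                              chrom != "chrMito"]
  complete <- Reduce(intersect, lapply(log2_fc_list, function(lfc) {
    names(lfc)[!is.na(lfc)]
  }))
  genes <- candidates[candidates %in% complete]
  mat <- vapply(log2_fc_list, function(lfc) unname(lfc[genes]),
                numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(log2_fc_list)))
  mat
}
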