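## Per-gene median exonic read depth and the Cov(S) yardstick. Depth is
## computed over exon bases only (introns may harbour transposable-element
## copies whose misassembly elsewhere distorts coverage). Only primary
## alignments count: duplicated loci attract multi-mappings, and counting
## secondaries would erase the coverage signal under measurement.

## Per-base depth vector over the merged exon bases of one gene.
gene_depth_values <- function(alignments, exons) {
  contig <- exons$contig_id[[1L]]
  aln <- alignments[alignments$target_id == contig &
                      alignments$is_primary, , drop = FALSE]
  exn <- IRanges::reduce(IRanges::IRanges(start = exons$start + 1L,
                                          end = exons$end))
  max_end <- max(IRanges::end(exn))
  if (nrow(aln) == 0L) {
    return(integer(sum(IRanges::width(exn))))
  }
  ir <- IRanges::IRanges(start = aln$target_start + 1L, end = aln$target_end)
  cov <- IRanges::coverage(ir, width = max(max_end, max(IRanges::end(ir))))
  v <- as.integer(cov)
  idx <- unlist(mapply(seq.int, IRanges::start(exn), IRanges::end(exn),
                       SIMPLIFY = FALSE), use.names = FALSE)
  v[idx]
}

#' Median exonic depth of one gene
#'
#' Depth at each exonic base is the number of primary alignments whose
#' target span covers it; an alignment covers its full `[target_start,
#' target_end)` span. The median is taken over all exonic bases, including
#' zero-depth bases; for an even number of bases the mean of the two
#' middle values is used (the [stats::median()] convention).
#'
#' @param alignments Alignment data frame (see [parse_paf()]); may be empty.
#' @param exons Non-empty exon data frame for a single gene on a single
#'   contig (see [read_exon_bed()]).
#' @return List with `gene_id`, `orthogroup_id`, `median_exonic_depth`,
#'   `exonic_positions`.
#' @export
gene_median_depth <- function(alignments, exons) {
  if (is.null(exons) || nrow(exons) == 0L) {
    agm_stop("exon list must be non-empty", "agm_invalid_argument")
  }
  if (length(unique(exons$gene_id)) != 1L ||
      length(unique(exons$contig_id)) != 1L) {
    agm_stop("exons must belong to one gene on one contig",
             "agm_invalid_argument")
  }
  depths <- gene_depth_values(alignments, exons)
  list(gene_id = exons$gene_id[[1L]],
       orthogroup_id = exons$orthogroup_id[[1L]],
       median_exonic_depth = stats::median(depths),
       exonic_positions = length(depths))
}

#' Median exonic depth for every gene in an exon table
#'
#' Applies [gene_median_depth()] gene by gene. Alignments are partitioned
#' by target contig once, so the cost is linear in reads plus genes.
#'
#' @param alignments Alignment data frame (see [parse_paf()]).
#' @param exons Exon data frame covering one or more genes.
#' @return Data frame with `gene_id`, `orthogroup_id`,
#'   `median_exonic_depth`, `exonic_positions`.
#' @export
gene_depths <- function(alignments, exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(gene_id = character(), orthogroup_id = character(),
                      median_exonic_depth = numeric(),
                      exonic_positions = integer(),
                      stringsAsFactors = FALSE))
  }
  by_contig <- split(alignments, alignments$target_id)
  parts <- split(exons, exons$gene_id)
  rows <- lapply(parts, function(g) {
    contig <- g$contig_id[[1L]]
    aln <- by_contig[[contig]]
    if (is.null(aln)) aln <- alignments[0L, , drop = FALSE]
    as.data.frame(gene_median_depth(aln, g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cov(S): the single-copy coverage yardstick
#'
#' The median over single-copy genes' median exonic depths (each
#' single-copy orthogroup contributes its one complete gene); the mean of
#' the two middle values for an even count. This is the reference depth
#' against which multicopy orthogroups are judged.
#'
#' @param s_gene_medians Numeric vector of median exonic depths of the
#'   genes in single-copy (S) orthogroups.
#' @return Cov(S), reads per base.
#' @export
compute_cov_s <- function(s_gene_medians) {
  s_gene_medians <- as.numeric(s_gene_medians)
  if (length(s_gene_medians) == 0L || anyNA(s_gene_medians)) {
    agm_stop("no single-copy genes: Cov(S) (and hence AG) is undefined",
             "agm_no_single_copy_genes")
  }
  stats::median(s_gene_medians)
}

#' Mean coverage of a multicopy orthogroup
#'
#' Arithmetic mean of the member genes' median exonic depths; defined for
#' orthogroups with at least two complete genes.
#'
#' @param gene_medians Numeric vector of median exonic depths, length >= 2.
#' @return Mean coverage, reads per base.
#' @export
orthogroup_mean_coverage <- function(gene_medians) {
  gene_medians <- as.numeric(gene_medians)
  if (length(gene_medians) < 2L || anyNA(gene_medians)) {
    agm_stop("a multicopy orthogroup needs >= 2 gene coverages",
             "agm_invalid_argument")
  }
  mean(gene_medians)
}
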