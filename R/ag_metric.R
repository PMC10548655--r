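## The AG metric: classify multicopy orthogroups into true multicopy (TM,
## paralogues at roughly full coverage) versus false multicopy (FM,
## uncollapsed haplotypes at roughly half coverage), then count genes.
## AG = genes in S orthogroups + genes in TM orthogroups.

#' Classify a multicopy orthogroup as TM or FM
#'
#' True multicopy orthogroups (paralogues) have coverage close to Cov(S);
#' false multicopy orthogroups (haplotypic duplications) close to
#' Cov(S)/2. The decision threshold is `tm_threshold * cov_s` (default
#' 3/4): TM requires mean coverage strictly above it, so a value exactly
#' at the threshold is called FM — the conservative direction when hunting
#' haplotypic duplications.
#'
#' @param og_mean_coverage Mean of member genes' median exonic depths
#'   (vectorized).
#' @param cov_s Cov(S), must be positive.
#' @param tm_threshold Fraction of Cov(S) above which an orthogroup is TM;
#'   default 0.75.
#' @return Character vector of `"TM"` / `"FM"` calls.
#' @export
classify_multicopy <- function(og_mean_coverage, cov_s, tm_threshold = 0.75) {
  if (!is.numeric(cov_s) || length(cov_s) != 1L || is.na(cov_s) ||
      cov_s <= 0) {
    agm_stop("cov_s must be a positive number", "agm_invalid_argument")
  }
  ifelse(og_mean_coverage > tm_threshold * cov_s, "TM", "FM")
}

#' Compute the AG report
#'
#' Takes orthogroup statuses and per-gene coverage, computes Cov(S) from
#' the single-copy genes, classifies every multicopy (D) orthogroup as TM
#' or FM on the mean of its complete genes' median depths, and counts:
#' `AG = n_genes_S + n_genes_TM`. Fragmented genes never contribute to AG
#' and never enter TM/FM means.
#'
#' @param statuses Output of [categorize_orthogroups()].
#' @param depths Per-gene coverage data frame from [gene_depths()] (needs
#'   `gene_id` and `median_exonic_depth`).
#' @param tm_threshold Passed to [classify_multicopy()].
#' @return An object of class `ag_report`: counts (`ag`, `n_genes_S`,
#'   `n_genes_TM`, `n_genes_FM`), per-category orthogroup counts
#'   (`n_orthogroups`, including TM/FM), `cov_s`, `tm_threshold`, and
#'   `per_gene_table` (gene_id, orthogroup_id, category, multicopy_class,
#'   median depth).
#' @export
compute_ag <- function(statuses, depths, tm_threshold = 0.75) {
  empty_counts <- c(S = 0L, D = 0L, F = 0L, M = 0L, TM = 0L, FM = 0L)
  empty_tbl <- data.frame(gene_id = character(), orthogroup_id = character(),
                          category = character(),
                          multicopy_class = character(),
                          median_exonic_depth = numeric(),
                          stringsAsFactors = FALSE)
  if (is.null(statuses) || nrow(statuses) == 0L) {
    return(new_ag_report(0L, 0L, 0L, 0L, empty_counts, NA_real_,
                         tm_threshold, empty_tbl))
  }
  depth_of <- function(gene_ids) {
    idx <- match(gene_ids, depths$gene_id)
    if (anyNA(idx)) {
      agm_stop(sprintf("no coverage entry for gene(s): %s",
                       paste(gene_ids[is.na(idx)], collapse = ", ")),
               "agm_incomplete_coverage")
    }
    depths$median_exonic_depth[idx]
  }
  counts <- empty_counts
  for (cat in c("S", "D", "F", "M")) {
    counts[[cat]] <- sum(statuses$category == cat)
  }
  s_rows <- statuses[statuses$category == "S", , drop = FALSE]
  d_rows <- statuses[statuses$category == "D", , drop = FALSE]
  s_genes <- unlist(s_rows$complete_genes, use.names = FALSE)
  if (is.null(s_genes)) s_genes <- character()
  cov_s <- NA_real_
  if (length(s_genes) > 0L) {
    cov_s <- compute_cov_s(depth_of(s_genes))
  } else if (nrow(d_rows) > 0L) {
    agm_stop("no single-copy genes: Cov(S) (and hence AG) is undefined",
             "agm_no_single_copy_genes")
  }
  tbl_rows <- list()
  if (length(s_genes) > 0L) {
    tbl_rows[[length(tbl_rows) + 1L]] <- data.frame(
      gene_id = s_genes,
      orthogroup_id = rep(s_rows$orthogroup_id,
                          lengths(s_rows$complete_genes)),
      category = "S", multicopy_class = NA_character_,
      median_exonic_depth = depth_of(s_genes), stringsAsFactors = FALSE)
  }
  n_genes_TM <- 0L
  n_genes_FM <- 0L
  for (i in seq_len(nrow(d_rows))) {
    genes <- d_rows$complete_genes[[i]]
    d <- depth_of(genes)
    call <- classify_multicopy(orthogroup_mean_coverage(d), cov_s,
                               tm_threshold)
    counts[[call]] <- counts[[call]] + 1L
    if (call == "TM") n_genes_TM <- n_genes_TM + length(genes)
    else n_genes_FM <- n_genes_FM + length(genes)
    tbl_rows[[length(tbl_rows) + 1L]] <- data.frame(
      gene_id = genes, orthogroup_id = d_rows$orthogroup_id[[i]],
      category = "D", multicopy_class = call, median_exonic_depth = d,
      stringsAsFactors = FALSE)
  }
  frag_genes <- unlist(statuses$fragmented_genes, use.names = FALSE)
  if (length(frag_genes) > 0L) {
    frag_og <- rep(statuses$orthogroup_id, lengths(statuses$fragmented_genes))
    frag_cat <- rep(statuses$category, lengths(statuses$fragmented_genes))
    idx <- match(frag_genes, depths$gene_id)
    tbl_rows[[length(tbl_rows) + 1L]] <- data.frame(
      gene_id = frag_genes, orthogroup_id = frag_og,
      category = frag_cat, multicopy_class = NA_character_,
      median_exonic_depth = ifelse(is.na(idx), NA_real_,
                                   depths$median_exonic_depth[idx]),
      stringsAsFactors = FALSE)
  }
  tbl <- if (length(tbl_rows) > 0L) do.call(rbind, tbl_rows) else empty_tbl
  rownames(tbl) <- NULL
  new_ag_report(length(s_genes), n_genes_TM, n_genes_FM,
                length(s_genes) + n_genes_TM, counts, cov_s, tm_threshold,
                tbl)
}

new_ag_report <- function(n_genes_S, n_genes_TM, n_genes_FM, ag, counts,
                          cov_s, tm_threshold, per_gene_table) {
  structure(list(
    ag = as.integer(ag),
    n_genes_S = as.integer(n_genes_S),
    n_genes_TM = as.integer(n_genes_TM),
    n_genes_FM = as.integer(n_genes_FM),
    n_orthogroups = counts,
    cov_s = cov_s,
    tm_threshold = tm_threshold,
    per_gene_table = per_gene_table
  ), class = "ag_report")
}

#' @export
print.ag_report <- function(x, ...) {
  cat(format_busco_summary(x), "\n")
  cat(sprintf("AG: %d (S genes: %d, TM genes: %d; FM genes: %d; Cov(S): %s)\n",
              x$ag, x$n_genes_S, x$n_genes_TM, x$n_genes_FM,
              if (is.na(x$cov_s)) "undefined" else fmt_num(x$cov_s)))
  invisible(x)
}

#' One-line BUSCO-style category summary
#'
#' Percentages are relative to the total orthogroup count, one decimal
#' place, in the conventional `C:..%[S:..%,D:..%],F:..%,M:..%` layout,
#' followed by the AG, TM and FM counts.
#'
#' @param report An `ag_report` from [compute_ag()].
#' @return A single summary string.
#' @export
format_busco_summary <- function(report) {
  n <- report$n_orthogroups
  total <- sum(n[c("S", "D", "F", "M")])
  pct <- function(k) if (total == 0L) 0 else 100 * k / total
  sprintf("C:%.1f%%[S:%.1f%%,D:%.1f%%],F:%.1f%%,M:%.1f%%,n:%d,AG:%d,TM:%d,FM:%d",
          pct(n[["S"]] + n[["D"]]), pct(n[["S"]]), pct(n[["D"]]),
          pct(n[["F"]]), pct(n[["M"]]), total, report$ag, n[["TM"]],
          n[["FM"]])
}

#' Export an AG report
#'
#' Writes `per_gene.tsv` (the sinaplot-ready per-gene coverage table) and
#' `summary.txt` (the one-line category summary) into a directory.
#'
#' @param report An `ag_report` from [compute_ag()].
#' @param dir Output directory; created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) {
    agm_stop(sprintf("cannot create output directory %s", dir),
             "agm_io_error")
  }
  tsv <- file.path(dir, "per_gene.tsv")
  txt <- file.path(dir, "summary.txt")
  tryCatch({
    utils::write.table(report$per_gene_table, tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(format_busco_summary(report), txt)
  }, error = function(e) {
    agm_stop(sprintf("cannot write report under %s: %s", dir,
                     conditionMessage(e)), "agm_io_error")
  })
  invisible(c(tsv, txt))
}
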