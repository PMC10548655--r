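## Simplified BUSCO-style classification: candidate genes into
## complete/fragmented/rejected, orthogroups into S/D/F/M.

#' Classify one gene candidate
#'
#' A candidate is complete when it passes both completeness criteria:
#' (a) its bit score against the orthogroup profile reaches the
#' orthogroup's score cutoff, and (b) its protein is not much shorter than
#' the reference: at least `length_cutoff - 2 * length_sigma` residues
#' (the two-sigma length rule; configurable via the vectorized interface).
#' Candidates failing (a) are rejected regardless of length; candidates
#' passing (a) but failing (b) are fragmented.
#'
#' @param candidate List or one-row data frame with `orthogroup_id`,
#'   `bitscore` and `protein_length`.
#' @param profile The matching [orthogroup_profile()] carrying
#'   `score_cutoff`, `length_cutoff` and `length_sigma`.
#' @return The candidate with a `status` field added, one of
#'   `"complete"`, `"fragmented"`, `"rejected"`.
#' @export
classify_candidate <- function(candidate, profile) {
  if (!identical(candidate$orthogroup_id, profile$orthogroup_id)) {
    agm_stop(sprintf("candidate orthogroup %s does not match profile %s",
                     candidate$orthogroup_id, profile$orthogroup_id),
             "agm_invalid_argument")
  }
  status <- if (candidate$bitscore < profile$score_cutoff) {
    "rejected"
  } else if (candidate$protein_length <
             profile$length_cutoff - 2 * profile$length_sigma) {
    "fragmented"
  } else {
    "complete"
  }
  candidate$status <- status
  candidate
}

#' Classify a table of gene candidates
#'
#' Vectorized form of [classify_candidate()]: joins candidates to their
#' orthogroup cutoffs and applies the completeness criteria row-wise.
#'
#' @param candidates Data frame with `gene_id`, `orthogroup_id`,
#'   `protein_length`, `bitscore` (extra columns pass through).
#' @param cutoffs Data frame with `orthogroup_id`, `score_cutoff`,
#'   `length_cutoff`, `length_sigma` (e.g. from [read_cutoff_tables()]).
#' @param n_sigma Multiplier in the minimum-length rule
#'   `length_cutoff - n_sigma * length_sigma`; default 2.
#' @return `candidates` with a `status` column added.
#' @export
classify_candidates <- function(candidates, cutoffs, n_sigma = 2) {
  missing <- setdiff(candidates$orthogroup_id, cutoffs$orthogroup_id)
  if (length(missing) > 0L) {
    agm_stop(sprintf("no cutoffs for orthogroup(s): %s",
                     paste(utils::head(missing, 5L), collapse = ", ")),
             "agm_invalid_argument")
  }
  idx <- match(candidates$orthogroup_id, cutoffs$orthogroup_id)
  sc <- cutoffs$score_cutoff[idx]
  min_len <- cutoffs$length_cutoff[idx] - n_sigma * cutoffs$length_sigma[idx]
  status <- ifelse(candidates$bitscore < sc, "rejected",
                   ifelse(candidates$protein_length < min_len,
                          "fragmented", "complete"))
  candidates$status <- status
  candidates
}

#' Categorize orthogroups into S/D/F/M
#'
#' Per-orthogroup counts of complete and fragmented genes determine the
#' category: exactly one complete gene is single-copy (S); two or more
#' complete genes is multicopy (D); no complete but at least one
#' fragmented gene is fragmented (F); otherwise the orthogroup is missing
#' (M) — including orthogroups with no candidates at all or only rejected
#' candidates.
#'
#' @param classified Data frame of classified candidates (output of
#'   [classify_candidates()]), possibly empty.
#' @param all_orthogroup_ids Character vector of every orthogroup assessed;
#'   each receives a status.
#' @return Data frame with one row per orthogroup: `orthogroup_id`,
#'   `category` in `{S, D, F, M}`, `n_complete`, `n_fragmented`, plus
#'   list-columns `complete_genes` and `fragmented_genes`.
#' @export
categorize_orthogroups <- function(classified, all_orthogroup_ids) {
  all_orthogroup_ids <- unique(as.character(all_orthogroup_ids))
  if (nrow(classified) > 0L) {
    stray <- setdiff(classified$orthogroup_id, all_orthogroup_ids)
    if (length(stray) > 0L) {
      agm_stop(sprintf("classified genes reference unknown orthogroup(s): %s",
                       paste(utils::head(stray, 5L), collapse = ", ")),
               "agm_invalid_argument")
    }
  }
  rows <- lapply(all_orthogroup_ids, function(og) {
    sub <- classified[classified$orthogroup_id == og, , drop = FALSE]
    comp <- sub$gene_id[sub$status == "complete"]
    frag <- sub$gene_id[sub$status == "fragmented"]
    category <- if (length(comp) == 1L) "S"
      else if (length(comp) >= 2L) "D"
      else if (length(frag) >= 1L) "F"
      else "M"
    data.frame(orthogroup_id = og, category = category,
               n_complete = length(comp), n_fragmented = length(frag),
               complete_genes = I(list(comp)),
               fragmented_genes = I(list(frag)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a gene-candidate table
#'
#' Tab-separated with a header row and columns `gene_id`, `orthogroup_id`,
#' `protein_length`, `bitscore`, `contig`, `exons`, where `exons` lists
#' 0-based half-open intervals as `"start-end,start-end,..."`.
#'
#' @param x Path to a TSV file, or a character vector of lines.
#' @return List with `candidates` (data frame) and `exons` (data frame in
#'   [read_exon_bed()] layout, merged per gene).
#' @export
read_candidates_tsv <- function(x) {
  lines <- read_input_lines(x)
  tbl <- utils::read.table(text = paste(lines, collapse = "\n"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("gene_id", "orthogroup_id", "protein_length", "bitscore",
              "contig", "exons")
  if (!all(needed %in% names(tbl))) {
    agm_stop(sprintf("candidate table must have columns: %s",
                     paste(needed, collapse = ", ")), "agm_malformed_input")
  }
  exon_rows <- lapply(seq_len(nrow(tbl)), function(i) {
    spans <- strsplit(tbl$exons[[i]], ",", fixed = TRUE)[[1L]]
    parts <- strsplit(spans, "-", fixed = TRUE)
    s <- as.integer(vapply(parts, `[[`, character(1), 1L))
    e <- as.integer(vapply(parts, `[[`, character(1), 2L))
    if (anyNA(s) || anyNA(e) || any(s >= e)) {
      agm_stop(sprintf("bad exon spans for gene %s", tbl$gene_id[[i]]),
               "agm_malformed_interval")
    }
    data.frame(contig_id = tbl$contig[[i]], start = s, end = e,
               gene_id = tbl$gene_id[[i]],
               orthogroup_id = tbl$orthogroup_id[[i]],
               stringsAsFactors = FALSE)
  })
  exons <- merge_gene_exons(do.call(rbind, exon_rows))
  cands <- tbl[, c("gene_id", "orthogroup_id", "protein_length",
                   "bitscore", "contig")]
  list(candidates = cands, exons = exons)
}

#' Parse hmmsearch domain-table output for candidate bit scores
#'
#' Minimal reader for `hmmsearch --domtblout`: keeps the target (gene)
#' name, query (orthogroup) name and full-sequence bit score, for wiring
#' real profile-search results into [classify_candidates()].
#'
#' @param x Path to a domtblout file, or a character vector of lines.
#' @return Data frame with `gene_id`, `orthogroup_id`, `bitscore`.
#' @export
parse_domtblout <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(f) < 8L) {
      agm_stop(sprintf("domtblout line %d is truncated", i),
               "agm_malformed_input")
    }
    bs <- suppressWarnings(as.numeric(f[[8L]]))
    if (is.na(bs)) {
      agm_stop(sprintf("domtblout line %d: non-numeric bit score", i),
               "agm_malformed_input")
    }
    data.frame(gene_id = f[[1L]], orthogroup_id = f[[4L]], bitscore = bs,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), orthogroup_id = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}
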