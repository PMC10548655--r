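# Shared builders for tests. Fixtures are constructed in code; no files
# are shipped.

# A profile whose every position equals the given distribution.
flat_profile <- function(id, dist, L = 1L) {
  orthogroup_profile(id, matrix(rep(dist, each = L), nrow = L),
                     score_cutoff = 50, length_cutoff = 300,
                     length_sigma = 30)
}

# A profile with each position concentrated on one residue.
delta_profile <- function(id, residues) {
  E <- matrix(0, nrow = length(residues), ncol = 20L)
  for (i in seq_along(residues)) E[i, residues[[i]]] <- 1
  orthogroup_profile(id, E)
}

# Catalog of n length-1 profiles with controllable entropies: emission
# mass `w` on residue 1, rest spread uniformly (w = 1/20 gives entropy 0).
graded_catalog <- function(weights, ids = sprintf("og%03d", seq_along(weights))) {
  profiles <- Map(function(w, id) {
    e <- rep((1 - w) / 19, 20L)
    e[1L] <- w
    orthogroup_profile(id, matrix(e, nrow = 1L))
  }, weights, ids)
  new_catalog(profiles)
}

# Dummy catalog of a given size (distinct entropies, deterministic).
dummy_catalog <- function(n) {
  graded_catalog(seq(0.06, 0.94, length.out = n),
                 ids = sprintf("og%05d", seq_len(n)))
}

# One-gene exon table.
exons_for <- function(gene_id, og, contig, starts, ends) {
  data.frame(contig_id = contig, start = as.integer(starts),
             end = as.integer(ends), gene_id = gene_id,
             orthogroup_id = og, stringsAsFactors = FALSE)
}

# Alignment table from target spans on one contig.
aln_for <- function(contig, starts, ends, primary = TRUE) {
  n <- length(starts)
  if (n == 0L) {
    return(agmetric::parse_paf(character()))
  }
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)), read_length = 100L,
    read_start = 0L, read_end = as.integer(ends - starts), strand = "+",
    target_id = contig, target_length = 100000L,
    target_start = as.integer(starts), target_end = as.integer(ends),
    n_match = as.integer(ends - starts),
    aln_block_len = as.integer(ends - starts), mapq = 60L,
    is_primary = rep_len(primary, n), stringsAsFactors = FALSE
  )
}

# Brute-force per-base depth oracle: position-by-position recount.
brute_force_depths <- function(alignments, exons) {
  exn <- exons[order(exons$start), , drop = FALSE]
  # merge overlapping/abutting intervals by hand
  pos <- sort(unique(unlist(Map(function(s, e) seq.int(s, e - 1L),
                                exn$start, exn$end))))
  aln <- alignments[alignments$is_primary &
                      alignments$target_id == exons$contig_id[[1]], ]
  vapply(pos, function(p) {
    sum(aln$target_start <= p & p < aln$target_end)
  }, numeric(1))
}

# Orthogroup statuses + depths encoding given per-category gene counts,
# for worked-example AG arithmetic. TM orthogroups get full depth, FM half.
encode_category_counts <- function(n_genes_S, n_genes_TM, n_genes_FM,
                                   depth = 100) {
  genes <- list()
  classified <- data.frame(gene_id = character(),
                           orthogroup_id = character(),
                           status = character(), stringsAsFactors = FALSE)
  add <- function(og, gene_ids) {
    data.frame(gene_id = gene_ids, orthogroup_id = og, status = "complete",
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(n_genes_S)) {
    rows[[length(rows) + 1L]] <- add(sprintf("S%04d", i),
                                     sprintf("S%04d_g1", i))
  }
  # split multicopy genes into orthogroups of 2 (plus one of 3 if odd)
  split_into_ogs <- function(total, prefix) {
    out <- list()
    remaining <- total
    i <- 0L
    while (remaining > 0L) {
      i <- i + 1L
      size <- if (remaining %% 2L == 1L && remaining <= 3L) remaining else 2L
      out[[i]] <- sprintf("%s%04d_g%d", prefix, i, seq_len(size))
      names(out)[i] <- sprintf("%s%04d", prefix, i)
      remaining <- remaining - size
    }
    out
  }
  for (grp in list(list(split_into_ogs(n_genes_TM, "TM"), depth),
                   list(split_into_ogs(n_genes_FM, "FM"), depth / 2))) {
    for (og in names(grp[[1]])) {
      rows[[length(rows) + 1L]] <- add(og, grp[[1]][[og]])
    }
  }
  classified <- do.call(rbind, rows)
  statuses <- categorize_orthogroups(classified,
                                     unique(classified$orthogroup_id))
  depths <- data.frame(
    gene_id = classified$gene_id,
    median_exonic_depth = ifelse(startsWith(classified$gene_id, "FM"),
                                 depth / 2, depth),
    stringsAsFactors = FALSE)
  list(statuses = statuses, depths = depths)
}
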