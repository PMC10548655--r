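## Synthetic fixture generator: worlds with the statistical structure the
## AG metric assumes — single-copy genes and true paralogues at depth D,
## haplotypic duplicates at depth D/2 — emitted as exon models, alignment
## records and candidate tables, with a ground-truth label per gene.

#' Configuration for a synthetic fixture
#'
#' @param n_single Number of single-copy loci (one gene each, depth D).
#' @param n_paralog_pairs Number of true paralogue pairs (two genes each,
#'   both at depth D: true multicopy orthogroups).
#' @param n_false_duplication_loci Number of uncollapsed heterozygous loci
#'   (two gene copies each at depth D/2: false multicopy orthogroups).
#' @param depth Expected collapsed read depth D (reads per base).
#' @param gene_length Gene (contig) length in bases.
#' @param exons_per_gene Number of exon blocks per gene.
#' @param read_length Simulated read length in bases.
#' @param seed Integer seed; fixtures are byte-identical for equal seeds.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_single = 20L, n_paralog_pairs = 5L,
                             n_false_duplication_loci = 5L, depth = 30,
                             gene_length = 1000L, exons_per_gene = 3L,
                             read_length = 200L, seed = 1L) {
  counts <- c(n_single, n_paralog_pairs, n_false_duplication_loci)
  if (any(counts < 0) || depth <= 0 || gene_length < exons_per_gene) {
    agm_stop("invalid synthetic configuration", "agm_invalid_argument")
  }
  structure(list(n_single = as.integer(n_single),
                 n_paralog_pairs = as.integer(n_paralog_pairs),
                 n_false_duplication_loci =
                   as.integer(n_false_duplication_loci),
                 depth = depth, gene_length = as.integer(gene_length),
                 exons_per_gene = as.integer(exons_per_gene),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic fixture
#'
#' Emits, deterministically for a given seed, the tables the metric
#' pipeline consumes: exon intervals, alignment records (read origins are
#' known by construction, no aligner involved), gene candidates whose bit
#' scores and lengths pass the completeness cutoffs, the cutoff table, and
#' a truth table. Single-copy genes and true-paralogue genes get expected
#' exonic depth `depth`; both copies of a false duplication get
#' `depth / 2`. When `n_single` is 0 an anchor single-copy gene is added
#' so Cov(S) is always defined.
#'
#' @param config A [synthetic_config()].
#' @return List of class `ag_fixture` with `exons`, `alignments`,
#'   `candidates`, `cutoffs`, `truth`, `config`.
#' @export
generate_fixture <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    agm_stop("config must be a synthetic_config", "agm_invalid_argument")
  }
  set.seed(config$seed)
  genes <- list()
  add_gene <- function(gene_id, og, depth, class) {
    genes[[length(genes) + 1L]] <<- list(gene_id = gene_id,
                                         orthogroup_id = og,
                                         expected_depth = depth,
                                         true_class = class)
  }
  if (config$n_single == 0L) {
    add_gene("anchor_g1", "og_anchor", config$depth, "S")
  }
  for (i in seq_len(config$n_single)) {
    add_gene(sprintf("s%03d_g1", i), sprintf("og_s%03d", i), config$depth,
             "S")
  }
  for (i in seq_len(config$n_paralog_pairs)) {
    og <- sprintf("og_tm%03d", i)
    add_gene(sprintf("tm%03d_g1", i), og, config$depth, "TM-member")
    add_gene(sprintf("tm%03d_g2", i), og, config$depth, "TM-member")
  }
  for (i in seq_len(config$n_false_duplication_loci)) {
    og <- sprintf("og_fm%03d", i)
    add_gene(sprintf("fm%03d_g1", i), og, config$depth / 2, "FM-member")
    add_gene(sprintf("fm%03d_g2", i), og, config$depth / 2, "FM-member")
  }
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  og_ids <- vapply(genes, `[[`, character(1), "orthogroup_id")
  exons <- do.call(rbind, lapply(genes, function(g) {
    blk <- exon_blocks(config$gene_length, config$exons_per_gene)
    data.frame(contig_id = g$gene_id, start = blk$start, end = blk$end,
               gene_id = g$gene_id, orthogroup_id = g$orthogroup_id,
               stringsAsFactors = FALSE)
  }))
  alignments <- do.call(rbind, lapply(genes, function(g) {
    simulate_gene_alignments(g$gene_id, config$gene_length,
                             config$read_length, g$expected_depth)
  }))
  candidates <- data.frame(
    gene_id = gene_ids, orthogroup_id = og_ids,
    protein_length = MOCK_LENGTH_CUTOFF, bitscore = 2 * MOCK_SCORE_CUTOFF,
    contig = gene_ids, stringsAsFactors = FALSE
  )
  cutoffs <- data.frame(
    orthogroup_id = unique(og_ids), score_cutoff = MOCK_SCORE_CUTOFF,
    length_cutoff = MOCK_LENGTH_CUTOFF, length_sigma = MOCK_LENGTH_SIGMA,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = gene_ids, orthogroup_id = og_ids,
    true_class = vapply(genes, `[[`, character(1), "true_class"),
    true_depth = vapply(genes, `[[`, numeric(1), "expected_depth"),
    stringsAsFactors = FALSE
  )
  structure(list(exons = exons, alignments = alignments,
                 candidates = candidates, cutoffs = cutoffs, truth = truth,
                 config = config), class = "ag_fixture")
}

#' AG report of a fixture
#'
#' Convenience wrapper running the metric pipeline on a generated fixture.
#'
#' @param fixture An `ag_fixture` from [generate_fixture()].
#' @param tm_threshold Passed to [compute_ag()].
#' @return An `ag_report`.
#' @export
ag_from_fixture <- function(fixture, tm_threshold = 0.75) {
  ag_from_assembly(fixture$candidates, fixture$exons, fixture$alignments,
                   fixture$cutoffs, tm_threshold = tm_threshold)
}

#' Write a fixture to disk
#'
#' Serializes a fixture as the plain-text formats the command-line
#' workflows read: `exons.bed`, `alignments.paf`, `candidates.tsv`
#' (including the per-gene exon spans), `cutoffs.tsv` and `truth.tsv`.
#'
#' @param fixture An `ag_fixture`.
#' @param dir Output directory; created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    agm_stop(sprintf("cannot create directory %s", dir), "agm_io_error")
  }
  bed <- file.path(dir, "exons.bed")
  paf <- file.path(dir, "alignments.paf")
  cand <- file.path(dir, "candidates.tsv")
  cut <- file.path(dir, "cutoffs.tsv")
  tru <- file.path(dir, "truth.tsv")
  write_exon_bed(fixture$exons, bed)
  write_paf(fixture$alignments, paf)
  spans <- vapply(split(fixture$exons, fixture$exons$gene_id), function(g) {
    paste(sprintf("%d-%d", g$start, g$end), collapse = ",")
  }, character(1))
  cand_tbl <- fixture$candidates
  cand_tbl$exons <- spans[cand_tbl$gene_id]
  utils::write.table(cand_tbl, cand, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture$cutoffs, cut, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture$truth, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed, paf, cand, cut, tru))
}

#' Noise-free expected AG of a mock world
#'
#' Independent oracle for the optimizer: evaluates the mock assembler's
#' deterministic collapse/merge rules without sampling noise. A collapsed
#' single locus contributes 1 (an S gene); an uncollapsed one contributes
#' 0 (its copies form a false multicopy orthogroup). A merged paralogue
#' pair contributes 1 (one chimeric S gene); an unmerged pair contributes
#' 2 when its haplotypes collapse (a true multicopy orthogroup) and 0
#' otherwise.
#'
#' @param world A [mock_world()].
#' @param aggressiveness Collapse threshold in `[0, 1]`.
#' @return Expected AG (integer count).
#' @export
expected_ag <- function(world, aggressiveness) {
  total <- 0L
  for (i in seq_len(nrow(world$loci))) {
    loc <- world$loci[i, ]
    if (loc$kind == "single") {
      if (loc$haplotype_divergence <= aggressiveness) total <- total + 1L
    } else {
      if (loc$paralog_divergence <= aggressiveness) {
        total <- total + 1L
      } else if (loc$haplotype_divergence <= aggressiveness) {
        total <- total + 2L
      }
    }
  }
  total
}

#' Synthetic orthogroup catalog
#'
#' Builds a catalog of random profiles (Dirichlet-like emissions from
#' normalized gamma draws) with attached cutoffs and ancestral proteins.
#' Used for conservation-ranking and dataset-split workflows when no real
#' BUSCO dataset is at hand; it is synthetic and carries no biological
#' signal.
#'
#' @param n Number of orthogroups.
#' @param seed Integer seed.
#' @param profile_length Match states per profile.
#' @param concentration Gamma shape; small values give peaked (conserved-
#'   looking) emission distributions.
#' @return A [new_catalog()].
#' @export
synthetic_catalog <- function(n, seed = 1L, profile_length = 5L,
                              concentration = 0.5) {
  set.seed(seed)
  profiles <- lapply(seq_len(n), function(i) {
    g <- matrix(stats::rgamma(profile_length * 20L, shape = concentration),
                nrow = profile_length)
    orthogroup_profile(
      orthogroup_id = sprintf("og%05d", i),
      emissions = g / rowSums(g),
      ancestral_protein = paste(sample(AMINO_ACIDS, 50L, replace = TRUE),
                                collapse = ""),
      score_cutoff = MOCK_SCORE_CUTOFF,
      length_cutoff = MOCK_LENGTH_CUTOFF,
      length_sigma = MOCK_LENGTH_SIGMA)
  })
  new_catalog(profiles)
}

#' Write a catalog as a BUSCO-style dataset directory
#'
#' Inverse of [read_busco_dataset()]: writes `hmms/<id>.hmm`, `ancestral`,
#' `scores_cutoff` and `lengths_cutoff`.
#'
#' @param catalog A [new_catalog()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_busco_dataset <- function(catalog, dir) {
  hmm_dir <- file.path(dir, "hmms")
  if (!dir.exists(hmm_dir) && !dir.create(hmm_dir, recursive = TRUE)) {
    agm_stop(sprintf("cannot create directory %s", hmm_dir), "agm_io_error")
  }
  for (p in catalog$profiles) {
    write_hmm_profile(p, file.path(hmm_dir, paste0(p$orthogroup_id, ".hmm")))
  }
  ids <- names(catalog$profiles)
  anc <- vapply(catalog$profiles, function(p) {
    if (is.na(p$ancestral_protein)) strrep("A", 10L) else p$ancestral_protein
  }, character(1))
  writeLines(paste0(">", ids, "\n", anc), file.path(dir, "ancestral"))
  cut <- catalog_cutoffs(catalog)
  writeLines(sprintf("%s\t%s", cut$orthogroup_id, fmt_num(cut$score_cutoff)),
             file.path(dir, "scores_cutoff"))
  writeLines(sprintf("%s\t0\t%s\t%s", cut$orthogroup_id,
                     fmt_num(cut$length_sigma), fmt_num(cut$length_cutoff)),
             file.path(dir, "lengths_cutoff"))
  invisible(dir)
}
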