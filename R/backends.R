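## Assembler abstraction: pure command constructors for Hifiasm and Flye,
## BUSCO-read subsetting, and an in-process mock assembler that reproduces
## the failure modes the AG metric is designed to detect (uncollapsed
## haplotypes, merged paralogues), making the optimization loop testable
## without running an assembler.

#' Build a Hifiasm command line
#'
#' Constructs (never executes) the argument list for one Hifiasm run at a
#' given value of `-s`, the purge-aggressiveness parameter: the closer to
#' 0, the more aggressively similar sequences are removed. The output
#' prefix is fixed inside the work directory so that Hifiasm's
#' intermediate files are reused across parameter values.
#'
#' @param param Value for `-s`, in `[0, 1]`.
#' @param reads Path to the read file.
#' @param workdir Work directory for the run.
#' @return Character vector of command arguments.
#' @export
hifiasm_command <- function(param, reads, workdir) {
  if (!is.numeric(param) || length(param) != 1L || is.na(param) ||
      param < 0 || param > 1) {
    agm_stop("hifiasm -s must lie in [0, 1]", "agm_invalid_argument")
  }
  prefix <- file.path(workdir, "hifiasm", "asm")
  c("hifiasm", "-o", prefix, "-s", fmt_num(param), reads)
}

#' Build a Flye command line
#'
#' Constructs (never executes) the argument list for one Flye run at a
#' given `max_divergence`. The two divergence settings are coupled
#' (`assemble_ovlp_divergence = repeat_graph_ovlp_divergence = param`,
#' with `assemble_divergence_relative = 0`) and `--no-alt-contigs` is
#' always set. During optimization (`final = FALSE`) the BUSCO-read subset
#' is assembled (a gene-only objective assembly); the final assembly uses
#' all reads. The key=value overrides are a configuration template
#' (`extra_params_flag`) since Flye versions differ in how they accept
#' them.
#'
#' @param param `max_divergence`, in `[0.0001, 0.5]`.
#' @param reads_all Path to the full read set.
#' @param reads_busco Path to the BUSCO-read subset.
#' @param workdir Work directory for the run.
#' @param final If `FALSE`, assemble `reads_busco`; if `TRUE`, `reads_all`.
#' @param read_type Flye input flag, e.g. `"--nano-raw"`.
#' @param extra_params_flag Flag used to pass key=value overrides.
#' @return Character vector of command arguments.
#' @export
flye_command <- function(param, reads_all, reads_busco, workdir,
                         final = FALSE, read_type = "--nano-raw",
                         extra_params_flag = "--extra-params") {
  if (!is.numeric(param) || length(param) != 1L || is.na(param) ||
      param < 0.0001 || param > 0.5) {
    agm_stop("max_divergence must lie in [0.0001, 0.5]",
             "agm_invalid_argument")
  }
  overrides <- paste0("assemble_ovlp_divergence=", fmt_num(param),
                      ",assemble_divergence_relative=0",
                      ",repeat_graph_ovlp_divergence=", fmt_num(param))
  c("flye", read_type, if (final) reads_all else reads_busco,
    "--out-dir", file.path(workdir, "flye"),
    "--no-alt-contigs", extra_params_flag, overrides)
}

#' Select BUSCO reads from protein hits
#'
#' BUSCO reads are reads with at least one translated-alignment hit to an
#' ancestral BUSCO protein at or below the e-value ceiling; they are a
#' fast proxy subset for gene-level coverage and gene-only assemblies.
#'
#' @param hits Data frame from [parse_blasttab()].
#' @param read_ids Character vector of candidate read ids.
#' @param evalue_max E-value ceiling; default 1e-5.
#' @return The subset of `read_ids` with a qualifying hit, order
#'   preserved, no duplicates.
#' @export
select_busco_reads <- function(hits, read_ids, evalue_max = 1e-5) {
  keep <- unique(hits$read_id[hits$evalue <= evalue_max])
  unique(read_ids[read_ids %in% keep])
}

#' Define a mock diploid world
#'
#' A world is a set of loci on a diploid genome: `single` loci (one gene,
#' possibly heterozygous) and `paralog_pair` loci (two genes of one
#' orthogroup). Each locus carries a haplotype divergence (how different
#' its two alleles are) and, for paralogue pairs, a paralogue divergence
#' (how different the two paralogues are, always larger).
#'
#' @param loci Data frame with `locus_id`, `kind` in
#'   `{"single", "paralog_pair"}`, `haplotype_divergence` in `[0, 1]`,
#'   `paralog_divergence` in `[0, 1]` or `NA` for singles.
#' @param depth Expected read depth of a collapsed locus (reads per base).
#' @param seed Integer seed driving the sampling model.
#' @param gene_length Gene (contig) length in bases.
#' @param read_length Simulated read length in bases.
#' @param exons_per_gene Number of exon blocks per gene.
#' @return An object of class `mock_world`.
#' @export
mock_world <- function(loci, depth = 30, seed = 1L, gene_length = 500L,
                       read_length = 150L, exons_per_gene = 2L) {
  div <- c(loci$haplotype_divergence,
           loci$paralog_divergence[!is.na(loci$paralog_divergence)])
  if (any(div < 0) || any(div > 1)) {
    agm_stop("divergences must lie in [0, 1]", "agm_invalid_argument")
  }
  pairs <- loci[loci$kind == "paralog_pair", , drop = FALSE]
  if (nrow(pairs) > 0L &&
      (anyNA(pairs$paralog_divergence) ||
       any(pairs$paralog_divergence <= pairs$haplotype_divergence))) {
    agm_stop("paralog_divergence must exceed haplotype_divergence",
             "agm_invalid_argument")
  }
  if (!all(loci$kind %in% c("single", "paralog_pair"))) {
    agm_stop("locus kind must be 'single' or 'paralog_pair'",
             "agm_invalid_argument")
  }
  structure(list(loci = loci, depth = depth, seed = as.integer(seed),
                 gene_length = as.integer(gene_length),
                 read_length = as.integer(read_length),
                 exons_per_gene = as.integer(exons_per_gene)),
            class = "mock_world")
}

#' Random gapped mock world
#'
#' Draws a world whose haplotype divergences and paralogue divergences are
#' separated by a gap, so an aggressiveness value inside the gap collapses
#' every haplotype and merges no paralogue pair (the truth-optimal
#' plateau). The first single locus is homozygous (divergence 0), so a
#' single-copy gene — and hence Cov(S) — exists at any aggressiveness.
#'
#' @param n_single Number of single loci.
#' @param n_paralog_pairs Number of paralogue pairs.
#' @param depth Collapsed-locus read depth.
#' @param hap_range Range of haplotype divergences.
#' @param par_range Range of paralogue divergences.
#' @param seed Integer seed.
#' @param ... Passed to [mock_world()].
#' @return A `mock_world`.
#' @export
random_mock_world <- function(n_single = 8L, n_paralog_pairs = 4L,
                              depth = 30, hap_range = c(0.05, 0.3),
                              par_range = c(0.6, 0.95), seed = 1L, ...) {
  set.seed(seed)
  hs <- stats::runif(n_single, hap_range[1L], hap_range[2L])
  hs[1L] <- 0  # homozygous anchor locus
  hp <- stats::runif(n_paralog_pairs, hap_range[1L], hap_range[2L])
  pp <- stats::runif(n_paralog_pairs, par_range[1L], par_range[2L])
  loci <- data.frame(
    locus_id = c(sprintf("single%03d", seq_len(n_single)),
                 sprintf("pair%03d", seq_len(n_paralog_pairs))),
    kind = c(rep("single", n_single), rep("paralog_pair", n_paralog_pairs)),
    haplotype_divergence = c(hs, hp),
    paralog_divergence = c(rep(NA_real_, n_single), pp),
    stringsAsFactors = FALSE
  )
  mock_world(loci, depth = depth, seed = seed, ...)
}

## Exon layout used by the mock assembler and fixture generator: k blocks
## of length floor(L/(2k)) evenly spaced along a gene of length L.
exon_blocks <- function(gene_length, k) {
  blk <- max(1L, gene_length %/% (2L * k))
  starts <- (seq_len(k) - 1L) * (gene_length %/% k)
  data.frame(start = starts, end = pmin(starts + blk, gene_length))
}

## Alignment records for one gene: Poisson read starts along the contig
## (with overhang, so expected depth is uniform), clipped to the contig.
simulate_gene_alignments <- function(gene_id, gene_length, read_length,
                                     depth) {
  span <- gene_length + read_length - 1L
  n <- stats::rpois(1L, depth * span / read_length)
  if (n == 0L) {
    return(data.frame(read_id = character(), read_length = integer(),
                      read_start = integer(), read_end = integer(),
                      strand = character(), target_id = character(),
                      target_length = integer(), target_start = integer(),
                      target_end = integer(), n_match = integer(),
                      aln_block_len = integer(), mapq = integer(),
                      is_primary = logical(), stringsAsFactors = FALSE))
  }
  starts <- sample.int(span, n, replace = TRUE) - read_length
  ts <- pmax(starts, 0L)
  te <- pmin(starts + read_length, gene_length)
  keep <- ts < te
  ts <- ts[keep]
  te <- te[keep]
  n <- length(ts)
  data.frame(
    read_id = sprintf("%s_r%05d", gene_id, seq_len(n)),
    read_length = as.integer(read_length),
    read_start = 0L, read_end = as.integer(te - ts),
    strand = "+", target_id = gene_id,
    target_length = as.integer(gene_length),
    target_start = as.integer(ts), target_end = as.integer(te),
    n_match = as.integer(te - ts), aln_block_len = as.integer(te - ts),
    mapq = 60L, is_primary = TRUE, stringsAsFactors = FALSE
  )
}

## Default completeness cutoffs used by mock/synthetic candidates.
MOCK_SCORE_CUTOFF <- 50
MOCK_LENGTH_CUTOFF <- 300
MOCK_LENGTH_SIGMA <- 30

#' Mock assembly of a world at a given aggressiveness
#'
#' Deterministic given `(world, aggressiveness)`. A heterozygous locus is
#' collapsed into one gene at full depth iff its haplotype divergence is
#' at most the aggressiveness; otherwise both alleles are emitted, each at
#' half depth (a haplotypic duplication). A paralogue pair is merged into
#' one chimeric gene at double depth iff its paralogue divergence is at
#' most the aggressiveness; otherwise the two paralogues are emitted, each
#' behaving like a single locus of the pair's haplotype divergence.
#' Per-base depths follow a Poisson sampling model seeded by `world$seed`.
#'
#' @param world A [mock_world()].
#' @param aggressiveness Collapse threshold in `[0, 1]`: loci whose
#'   divergence does not exceed it are merged.
#' @return List with `candidates`, `exons`, `alignments`, `cutoffs`
#'   (directly consumable by [classify_candidates()], [gene_depths()] and
#'   [compute_ag()]) plus a `truth` table of per-gene labels.
#' @export
mock_assemble <- function(world, aggressiveness) {
  if (!is.numeric(aggressiveness) || length(aggressiveness) != 1L ||
      is.na(aggressiveness) || aggressiveness < 0 || aggressiveness > 1) {
    agm_stop("aggressiveness must lie in [0, 1]", "agm_invalid_argument")
  }
  set.seed(world$seed)
  genes <- list()  # rows: gene_id, orthogroup_id, expected_depth, truth
  for (i in seq_len(nrow(world$loci))) {
    loc <- world$loci[i, ]
    og <- loc$locus_id
    emit_het <- function(suffix_base) {
      if (loc$haplotype_divergence <= aggressiveness) {
        list(list(gene_id = paste0(og, suffix_base, "1"), orthogroup_id = og,
                  expected_depth = world$depth, truth = "collapsed"))
      } else {
        lapply(1:2, function(k) list(
          gene_id = paste0(og, suffix_base, k), orthogroup_id = og,
          expected_depth = world$depth / 2, truth = "haplotypic_duplicate"))
      }
    }
    if (loc$kind == "single") {
      genes <- c(genes, emit_het("_g"))
    } else {
      if (loc$paralog_divergence <= aggressiveness) {
        genes <- c(genes, list(list(
          gene_id = paste0(og, "_chimera"), orthogroup_id = og,
          expected_depth = 2 * world$depth, truth = "merged_paralogs")))
      } else {
        genes <- c(genes, emit_het("_a"), emit_het("_b"))
      }
    }
  }
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  exons <- do.call(rbind, lapply(genes, function(g) {
    blk <- exon_blocks(world$gene_length, world$exons_per_gene)
    data.frame(contig_id = g$gene_id, start = blk$start, end = blk$end,
               gene_id = g$gene_id, orthogroup_id = g$orthogroup_id,
               stringsAsFactors = FALSE)
  }))
  alignments <- do.call(rbind, lapply(genes, function(g) {
    simulate_gene_alignments(g$gene_id, world$gene_length,
                             world$read_length, g$expected_depth)
  }))
  candidates <- data.frame(
    gene_id = gene_ids,
    orthogroup_id = vapply(genes, `[[`, character(1), "orthogroup_id"),
    protein_length = MOCK_LENGTH_CUTOFF,
    bitscore = 2 * MOCK_SCORE_CUTOFF,
    contig = gene_ids, stringsAsFactors = FALSE
  )
  cutoffs <- data.frame(
    orthogroup_id = unique(world$loci$locus_id),
    score_cutoff = MOCK_SCORE_CUTOFF,
    length_cutoff = MOCK_LENGTH_CUTOFF,
    length_sigma = MOCK_LENGTH_SIGMA, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = gene_ids,
    orthogroup_id = candidates$orthogroup_id,
    true_class = vapply(genes, `[[`, character(1), "truth"),
    true_depth = vapply(genes, `[[`, numeric(1), "expected_depth"),
    stringsAsFactors = FALSE
  )
  list(candidates = candidates, exons = exons, alignments = alignments,
       cutoffs = cutoffs, truth = truth)
}

#' AG from assembly-level tables
#'
#' The full metric pipeline on in-memory tables: classify candidates
#' against cutoffs, categorize orthogroups, compute per-gene median exonic
#' depths, and produce the AG report.
#'
#' @param candidates Candidate table (see [classify_candidates()]).
#' @param exons Exon table (see [read_exon_bed()]).
#' @param alignments Alignment table (see [parse_paf()]).
#' @param cutoffs Cutoff table (see [read_cutoff_tables()]).
#' @param all_orthogroup_ids Orthogroups assessed; defaults to those
#'   present in `cutoffs`.
#' @param tm_threshold Passed to [compute_ag()].
#' @return An `ag_report`.
#' @export
ag_from_assembly <- function(candidates, exons, alignments, cutoffs,
                             all_orthogroup_ids = cutoffs$orthogroup_id,
                             tm_threshold = 0.75) {
  classified <- classify_candidates(candidates, cutoffs)
  statuses <- categorize_orthogroups(classified, all_orthogroup_ids)
  depths <- gene_depths(alignments, exons)
  compute_ag(statuses, depths, tm_threshold = tm_threshold)
}

#' Mock assembler backend for the optimizer
#'
#' Wraps [mock_assemble()] and the AG pipeline as a backend object for
#' [optimize_assembly()]: the search space is the identity unit interval
#' (the aggressiveness axis), the objective assembles the world at a
#' parameter value and scores it, and the final assembly re-runs the mock
#' at the best parameter.
#'
#' @param world A [mock_world()].
#' @param tm_threshold Passed to [ag_from_assembly()].
#' @return A backend list with `name`, `space`, `objective`,
#'   `assemble_final`.
#' @export
mock_backend <- function(world, tm_threshold = 0.75) {
  objective <- function(param) {
    asm <- mock_assemble(world, param)
    report <- ag_from_assembly(asm$candidates, asm$exons, asm$alignments,
                               asm$cutoffs, tm_threshold = tm_threshold)
    list(ag = report$ag, artifact = list(assembly = asm, report = report))
  }
  list(name = "mock", space = search_space(0, 1, "identity"),
       objective = objective,
       assemble_final = function(param) mock_assemble(world, param))
}
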