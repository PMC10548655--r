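## Orthogroup dataset model: profiles, conservation ranking by mean
## positional relative entropy, selection of the most conserved subset,
## and the assembly/testing split used to avoid circular reasoning.

#' Construct an orthogroup profile
#'
#' Bundles one BUSCO orthogroup's profile HMM match emissions with its
#' ancestral protein and the completeness cutoffs used for gene
#' classification.
#'
#' @param orthogroup_id Orthogroup identifier.
#' @param emissions Numeric matrix, one row per match state, 20 columns in
#'   HMMER amino-acid order; each row must sum to 1 within 1e-6.
#' @param ancestral_protein Amino-acid sequence (single string) or `NA`.
#' @param score_cutoff Bit-score cutoff for criterion (a), or `NA`.
#' @param length_cutoff Mean reference protein length (residues), or `NA`.
#' @param length_sigma Standard deviation of reference lengths, or `NA`.
#' @param compo Optional average composition parsed from the profile.
#' @return An object of class `orthogroup_profile`.
#' @export
orthogroup_profile <- function(orthogroup_id, emissions,
                               ancestral_protein = NA_character_,
                               score_cutoff = NA_real_,
                               length_cutoff = NA_real_,
                               length_sigma = NA_real_,
                               compo = NULL) {
  emissions <- as.matrix(emissions)
  if (ncol(emissions) != 20L || nrow(emissions) < 1L) {
    agm_stop("emissions must be an L x 20 matrix with L >= 1",
             "agm_invalid_argument")
  }
  if (any(abs(rowSums(emissions) - 1) > 1e-6) || any(emissions < 0)) {
    agm_stop("each emission row must be a probability distribution",
             "agm_malformed_profile")
  }
  if (!is.na(score_cutoff) && score_cutoff < 0) {
    agm_stop("score_cutoff must be >= 0", "agm_invalid_argument")
  }
  colnames(emissions) <- AMINO_ACIDS
  structure(list(
    orthogroup_id = orthogroup_id,
    length = nrow(emissions),
    emissions = emissions,
    ancestral_protein = ancestral_protein,
    score_cutoff = score_cutoff,
    length_cutoff = length_cutoff,
    length_sigma = length_sigma,
    compo = compo
  ), class = "orthogroup_profile")
}

#' @export
print.orthogroup_profile <- function(x, ...) {
  cat(sprintf("<orthogroup_profile %s: %d match states%s>\n",
              x$orthogroup_id, x$length,
              if (is.na(x$score_cutoff)) ""
              else sprintf(", score cutoff %.1f bits", x$score_cutoff)))
  invisible(x)
}

#' Construct an orthogroup catalog
#'
#' @param profiles List of [orthogroup_profile()] objects with unique ids.
#' @param background Probability distribution over the 20 amino acids used
#'   as the null model for relative entropy; default uniform.
#' @return An object of class `catalog`.
#' @export
new_catalog <- function(profiles, background = rep(1 / 20, 20L)) {
  ids <- vapply(profiles, function(p) p$orthogroup_id, character(1))
  if (anyDuplicated(ids)) {
    agm_stop("catalog profiles must have unique orthogroup ids",
             "agm_invalid_argument")
  }
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-6 ||
      any(background < 0)) {
    agm_stop("background must be a probability distribution over 20 residues",
             "agm_invalid_argument")
  }
  names(profiles) <- ids
  structure(list(profiles = profiles, background = background),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf("<catalog: %d orthogroup profiles>\n", length(x$profiles)))
  invisible(x)
}

#' @export
length.catalog <- function(x) length(x$profiles)

#' Mean positional relative entropy of a profile
#'
#' Conservation statistic used to rank orthogroups: the mean over match
#' states of the Kullback-Leibler divergence (in bits) between the
#' position's emission distribution and a background distribution,
#' `(1/L) * sum_i sum_a p_ia * log2(p_ia / q_a)`, with `0 * log(0/q) = 0`.
#' Highly conserved profiles concentrate probability and score high;
#' profiles at background score 0.
#'
#' @param profile An [orthogroup_profile()].
#' @param background Probability distribution over the 20 amino acids.
#' @return Mean relative entropy in bits per position (non-negative).
#' @export
mean_positional_relative_entropy <- function(profile,
                                             background = rep(1 / 20, 20L)) {
  E <- profile$emissions
  q <- as.numeric(background)
  bad <- which(q == 0)
  if (length(bad) > 0L && any(E[, bad, drop = FALSE] > 0)) {
    agm_stop("emission positive where background is zero: entropy undefined",
             "agm_undefined_entropy")
  }
  ratio <- sweep(E, 2L, q, "/")
  term <- ifelse(E > 0, E * log2(ratio), 0)
  mean(rowSums(term))
}

## Entropy of every profile in a catalog, in catalog order.
catalog_entropies <- function(catalog) {
  vapply(catalog$profiles, mean_positional_relative_entropy,
         numeric(1), background = catalog$background)
}

#' Select the most conserved orthogroups
#'
#' Ranks orthogroups by ascending mean positional relative entropy (most
#' conserved first is the convention used when restricting an analysis to
#' well-conserved gene families), ties broken lexicographically by id, and
#' returns the first `min(n, |catalog|)` ids. When the catalog holds fewer
#' than `n` orthogroups the full catalog is returned in ranked order.
#'
#' @param catalog A [new_catalog()] object.
#' @param n Number of orthogroups requested (default 1000).
#' @return Character vector of orthogroup ids in rank order.
#' @export
select_conserved <- function(catalog, n = 1000L) {
  if (!is_count(n) || n < 1) {
    agm_stop("n must be a positive integer", "agm_invalid_argument")
  }
  ent <- catalog_entropies(catalog)
  ids <- names(catalog$profiles)
  ord <- order(ent, ids, method = "radix")
  utils::head(ids[ord], min(n, length(ids)))
}

#' Split a catalog into assembly and testing parts
#'
#' Partitions a catalog so that one part can drive assembly-time
#' optimization while the disjoint remainder scores the final assembly,
#' avoiding evaluation on the same orthogroups that were optimized
#' against. The assembly part is the `n_assembly` most conserved
#' orthogroups; the testing part is everything else.
#'
#' @param catalog A [new_catalog()] object.
#' @param n_assembly Number of orthogroups for the assembly part; must be
#'   at least 1 and strictly less than the catalog size.
#' @return List with character vectors `assembly` and `testing`.
#' @export
split_dataset <- function(catalog, n_assembly) {
  n_total <- length(catalog$profiles)
  if (!is_count(n_assembly) || n_assembly < 1) {
    agm_stop("n_assembly must be a positive integer", "agm_invalid_argument")
  }
  if (n_assembly >= n_total) {
    agm_stop(sprintf(
      "n_assembly (%d) must be < catalog size (%d) so a testing set remains",
      n_assembly, n_total), "agm_invalid_split")
  }
  ranked <- select_conserved(catalog, n_total)
  list(assembly = ranked[seq_len(n_assembly)],
       testing = ranked[(n_assembly + 1L):n_total])
}

#' Read a BUSCO-style dataset directory into a catalog
#'
#' Expected layout: `hmms/<id>.hmm` (HMMER3 text profiles), `ancestral`
#' (protein FASTA, one record per orthogroup), `scores_cutoff` and
#' `lengths_cutoff` tables (see [read_cutoff_tables()]).
#'
#' @param dir Dataset directory.
#' @param background Background distribution for the catalog.
#' @return A [new_catalog()] object with cutoffs and ancestral proteins
#'   attached to each profile.
#' @export
read_busco_dataset <- function(dir, background = rep(1 / 20, 20L)) {
  hmm_dir <- file.path(dir, "hmms")
  if (!dir.exists(hmm_dir)) {
    agm_stop(sprintf("dataset directory %s lacks an hmms/ subdirectory", dir),
             "agm_inconsistent_dataset")
  }
  files <- list.files(hmm_dir, pattern = "\\.hmm$", full.names = TRUE)
  profiles <- lapply(files, parse_hmm_profile)
  cut <- read_cutoff_tables(file.path(dir, "scores_cutoff"),
                            file.path(dir, "lengths_cutoff"))
  anc <- Biostrings::readAAStringSet(file.path(dir, "ancestral"))
  anc_map <- stats::setNames(as.character(anc),
                             vapply(strsplit(names(anc), "\\s+"), `[[`,
                                    character(1), 1L))
  profiles <- lapply(profiles, function(p) {
    row <- cut[cut$orthogroup_id == p$orthogroup_id, , drop = FALSE]
    if (nrow(row) == 0L) {
      agm_stop(sprintf("no cutoffs for orthogroup %s", p$orthogroup_id),
               "agm_inconsistent_dataset")
    }
    p$score_cutoff <- row$score_cutoff
    p$length_cutoff <- row$length_cutoff
    p$length_sigma <- row$length_sigma
    if (p$orthogroup_id %in% names(anc_map)) {
      p$ancestral_protein <- anc_map[[p$orthogroup_id]]
    }
    p
  })
  new_catalog(profiles, background)
}

## Cutoff table (one row per orthogroup) from a catalog's profiles.
catalog_cutoffs <- function(catalog) {
  data.frame(
    orthogroup_id = names(catalog$profiles),
    score_cutoff = vapply(catalog$profiles, `[[`, numeric(1), "score_cutoff"),
    length_cutoff = vapply(catalog$profiles, `[[`, numeric(1),
                           "length_cutoff"),
    length_sigma = vapply(catalog$profiles, `[[`, numeric(1), "length_sigma"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
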