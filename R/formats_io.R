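## Readers and writers for the external formats the tool touches. All
## coordinates are 0-based half-open internally (PAF and BED native).

#' Parse PAF alignments
#'
#' Reads the 12 mandatory tab-separated PAF columns into a data frame of
#' alignment records. The `tp:A:` tag is honoured when present: records
#' tagged `tp:A:S` (or any value other than `P`) are flagged as
#' non-primary; untagged lines default to primary.
#'
#' @param x Path to a PAF file, or a character vector of PAF lines.
#' @return A data frame with one row per alignment: `read_id`,
#'   `read_length`, `read_start`, `read_end`, `strand`, `target_id`,
#'   `target_length`, `target_start`, `target_end` (0-based half-open),
#'   `n_match`, `aln_block_len`, `mapq`, `is_primary`.
#' @examples
#' parse_paf("r1\t100\t0\t100\t+\tctg1\t1000\t200\t300\t95\t100\t60")
#' @export
parse_paf <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      agm_stop(sprintf("PAF line %d has %d columns; 12 required",
                       i, length(f)), "agm_malformed_input")
    }
    ints <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
    if (anyNA(ints)) {
      agm_stop(sprintf("PAF line %d: non-integer coordinate field", i),
               "agm_malformed_input")
    }
    if (!f[5L] %in% c("+", "-")) {
      agm_stop(sprintf("PAF line %d: strand must be '+' or '-'", i),
               "agm_malformed_input")
    }
    if (!nzchar(f[1L])) {
      agm_stop(sprintf("PAF line %d: empty read id", i),
               "agm_malformed_input")
    }
    if (!(ints[5L] >= 0L && ints[5L] < ints[6L] && ints[6L] <= ints[4L])) {
      agm_stop(sprintf(
        "PAF line %d: need 0 <= target_start < target_end <= target_length",
        i), "agm_malformed_input")
    }
    is_primary <- TRUE
    if (length(f) > 12L) {
      tp <- grep("^tp:A:", f[13:length(f)], value = TRUE)
      if (length(tp) > 0L) is_primary <- sub("^tp:A:", "", tp[[1L]]) == "P"
    }
    out[[i]] <- list(
      read_id = f[1L], read_length = ints[1L], read_start = ints[2L],
      read_end = ints[3L], strand = f[5L], target_id = f[6L],
      target_length = ints[4L], target_start = ints[5L],
      target_end = ints[6L], n_match = ints[7L], aln_block_len = ints[8L],
      mapq = ints[9L], is_primary = is_primary
    )
  }
  empty <- data.frame(
    read_id = character(), read_length = integer(), read_start = integer(),
    read_end = integer(), strand = character(), target_id = character(),
    target_length = integer(), target_start = integer(),
    target_end = integer(), n_match = integer(), aln_block_len = integer(),
    mapq = integer(), is_primary = logical(), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)
  do.call(rbind, c(list(empty), lapply(out, as.data.frame)))
}

#' Write alignment records as PAF
#'
#' Inverse of [parse_paf()]; the primary/secondary flag is serialized as a
#' `tp:A:` tag so that a parse/write round trip is lossless.
#'
#' @param alignments Data frame as returned by [parse_paf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path) {
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    paste(a$read_id, a$read_length, a$read_start, a$read_end, a$strand,
          a$target_id, a$target_length, a$target_start, a$target_end,
          a$n_match, a$aln_block_len, a$mapq,
          if (a$is_primary) "tp:A:P" else "tp:A:S", sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a HMMER3 text profile
#'
#' Reads a profile HMM in HMMER3 flat-file format and recovers the
#' per-position match-state emission distributions. Stored values are
#' negative natural-log probabilities; `*` denotes probability zero. The
#' `COMPO` line, when present, is parsed into the `compo` field (the
#' model's average composition) but is not used as a background
#' distribution.
#'
#' @param x Path to a `.hmm` file, or a character vector of lines.
#' @return An [orthogroup_profile()] with `emissions` (length x 20 matrix,
#'   rows summing to 1), `length`, and `orthogroup_id` taken from `NAME`.
#' @export
parse_hmm_profile <- function(x) {
  lines <- read_input_lines(x)
  if (length(lines) == 0L || !grepl("^HMMER3", lines[[1L]])) {
    agm_stop("not a HMMER3 text profile (missing HMMER3 header)",
             "agm_malformed_profile")
  }
  name <- NA_character_
  leng <- NA_integer_
  hmm_at <- NA_integer_
  for (i in seq_along(lines)) {
    if (grepl("^NAME\\s", lines[[i]])) {
      name <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]][2L]
    } else if (grepl("^LENG\\s", lines[[i]])) {
      leng <- as.integer(strsplit(trimws(lines[[i]]), "\\s+")[[1L]][2L])
    } else if (grepl("^HMM\\s", lines[[i]])) {
      hmm_at <- i
      break
    }
  }
  if (is.na(hmm_at) || is.na(leng)) {
    agm_stop("profile lacks an HMM section or LENG header",
             "agm_malformed_profile")
  }
  decode <- function(tokens) {
    vapply(tokens, function(t) if (t == "*") 0 else exp(-as.numeric(t)),
           numeric(1), USE.NAMES = FALSE)
  }
  i <- hmm_at + 2L  # skip alphabet header and transition-name line
  compo <- NULL
  emissions <- matrix(NA_real_, nrow = 0L, ncol = 20L)
  expected <- 1L
  state <- "node0"
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(tok) == 0L) { i <- i + 1L; next }
    if (tok[[1L]] == "//") break
    if (tok[[1L]] == "COMPO") {
      compo <- decode(tok[2:21])
      i <- i + 1L
      next
    }
    if (state == "node0") {
      i <- i + 2L  # node-0 insert emissions + transitions
      state <- "match"
      next
    }
    if (suppressWarnings(!is.na(as.integer(tok[[1L]]))) &&
        as.integer(tok[[1L]]) == expected && length(tok) >= 21L) {
      emissions <- rbind(emissions, decode(tok[2:21]))
      expected <- expected + 1L
      i <- i + 3L  # skip insert-emission and transition lines
    } else {
      agm_stop(sprintf("unexpected line %d in HMM model section", i),
               "agm_malformed_profile")
    }
  }
  if (nrow(emissions) != leng) {
    agm_stop(sprintf("LENG is %d but %d match-emission lines parsed",
                     leng, nrow(emissions)), "agm_malformed_profile")
  }
  sums <- rowSums(emissions)
  if (any(abs(sums - 1) > 1e-3)) {
    agm_stop("match emissions do not sum to 1 (beyond storage precision)",
             "agm_malformed_profile")
  }
  # stored values are rounded; renormalize to exact distributions
  emissions <- emissions / sums
  colnames(emissions) <- AMINO_ACIDS
  orthogroup_profile(orthogroup_id = name, emissions = emissions,
                     compo = compo)
}

#' Write a profile as HMMER3-flavoured text
#'
#' Emits the minimal HMMER3/f structure that [parse_hmm_profile()] reads
#' back (header, `COMPO`, node-0 lines, per-node match/insert/transition
#' lines). Insert emissions and transitions are written as placeholders;
#' only match emissions carry information.
#'
#' @param profile An [orthogroup_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hmm_profile <- function(profile, path) {
  enc <- function(p) {
    vapply(p, function(v) if (v <= 0) "*" else sprintf("%.9f", -log(v)),
           character(1))
  }
  L <- profile$length
  zeros20 <- paste(rep("0.69315", 20L), collapse = "  ")
  trans <- paste(rep("0.69315", 7L), collapse = "  ")
  compo <- colMeans(profile$emissions)
  lines <- c(
    "HMMER3/f [agmetric writer]",
    paste0("NAME  ", profile$orthogroup_id),
    paste0("LENG  ", L),
    "ALPH  amino",
    paste0("HMM          ", paste(AMINO_ACIDS, collapse = "        ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("  COMPO   ", paste(enc(compo), collapse = "  ")),
    paste0("          ", zeros20),
    paste0("          ", trans)
  )
  for (k in seq_len(L)) {
    lines <- c(lines,
      paste0(sprintf("%7d   ", k),
             paste(enc(profile$emissions[k, ]), collapse = "  "),
             sprintf("  %d - - -", k)),
      paste0("          ", zeros20),
      paste0("          ", trans))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read exon intervals from BED
#'
#' BED is 0-based half-open. Column 4 must encode `gene_id|orthogroup_id`.
#' Overlapping or abutting intervals of the same gene are merged, so two
#' equivalent representations of the same exon set canonicalize to the
#' same records.
#'
#' @param x Path to a BED file, or a character vector of lines.
#' @return Data frame with `contig_id`, `start`, `end`, `gene_id`,
#'   `orthogroup_id`, sorted by gene then start.
#' @export
read_exon_bed <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) {
      agm_stop(sprintf("BED line %d has fewer than 4 columns", i),
               "agm_malformed_input")
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) {
      agm_stop(sprintf("BED line %d: non-integer coordinates", i),
               "agm_malformed_input")
    }
    if (s >= e) {
      agm_stop(sprintf("BED line %d: start (%d) must be < end (%d)",
                       i, s, e), "agm_malformed_interval")
    }
    ids <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
    if (length(ids) != 2L) {
      agm_stop(sprintf(
        "BED line %d: name column must be 'gene_id|orthogroup_id'", i),
        "agm_malformed_input")
    }
    data.frame(contig_id = f[1L], start = s, end = e, gene_id = ids[1L],
               orthogroup_id = ids[2L], stringsAsFactors = FALSE)
  })
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      orthogroup_id = character(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  bed <- do.call(rbind, rows)
  merge_gene_exons(bed)
}

## Merge overlapping/abutting exon intervals within each gene.
merge_gene_exons <- function(bed) {
  parts <- split(bed, paste(bed$gene_id, bed$contig_id, sep = "\r"))
  merged <- lapply(parts, function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L,
                                           end = g$end))
    data.frame(contig_id = g$contig_id[[1L]],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               gene_id = g$gene_id[[1L]],
               orthogroup_id = g$orthogroup_id[[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write exon intervals as BED
#'
#' @param exons Data frame as returned by [read_exon_bed()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exon_bed <- function(exons, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s", exons$contig_id, exons$start,
                   exons$end, exons$gene_id, exons$orthogroup_id)
  writeLines(lines, path)
  invisible(path)
}

#' Parse blast tabular hits (outfmt 6)
#'
#' Twelve-column blast tabular output as produced by translated searches
#' of reads against ancestral BUSCO proteins. Only the read (query),
#' protein (subject), e-value and bit score are retained.
#'
#' @param x Path to a tabular file, or a character vector of lines.
#' @return Data frame with `read_id`, `protein_id`, `evalue`, `bitscore`.
#' @export
parse_blasttab <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), protein_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      agm_stop(sprintf("blast tabular line %d has %d columns; 12 required",
                       i, length(f)), "agm_malformed_input")
    }
    ev <- suppressWarnings(as.numeric(f[11L]))
    bs <- suppressWarnings(as.numeric(f[12L]))
    if (is.na(ev) || is.na(bs) || ev < 0 || bs < 0) {
      agm_stop(sprintf("blast tabular line %d: bad evalue/bitscore", i),
               "agm_malformed_input")
    }
    data.frame(read_id = f[1L], protein_id = f[2L], evalue = ev,
               bitscore = bs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read BUSCO-style score and length cutoff tables
#'
#' The default dialect is the BUSCO dataset layout: the scores table has
#' columns `(orthogroup_id, score_cutoff)`; the lengths table has columns
#' `(orthogroup_id, ignored, length_sigma, mean_length)`. Column positions
#' are overridable for other dialects.
#'
#' @param scores Path or lines of the scores table.
#' @param lengths Path or lines of the lengths table.
#' @param length_cols Integer vector `c(sigma_col, mean_length_col)` in the
#'   lengths table; default `c(3, 4)`.
#' @return Data frame with `orthogroup_id`, `score_cutoff`,
#'   `length_cutoff` (mean reference length), `length_sigma`.
#' @export
read_cutoff_tables <- function(scores, lengths, length_cols = c(3L, 4L)) {
  sl <- read_input_lines(scores)
  ll <- read_input_lines(lengths)
  sl <- sl[nzchar(trimws(sl))]
  ll <- ll[nzchar(trimws(ll))]
  parse_tbl <- function(lines) lapply(lines, function(l)
    strsplit(trimws(l), "\\s+")[[1L]])
  st <- parse_tbl(sl)
  lt <- parse_tbl(ll)
  sid <- vapply(st, `[[`, character(1), 1L)
  lid <- vapply(lt, `[[`, character(1), 1L)
  only_s <- setdiff(sid, lid)
  only_l <- setdiff(lid, sid)
  if (length(only_s) > 0L || length(only_l) > 0L) {
    agm_stop(sprintf(
      "inconsistent dataset: ids in one cutoff table only (%s)",
      paste(utils::head(c(only_s, only_l), 5L), collapse = ", ")),
      "agm_inconsistent_dataset")
  }
  if (length(st) == 0L) {
    return(data.frame(orthogroup_id = character(), score_cutoff = numeric(),
                      length_cutoff = numeric(), length_sigma = numeric(),
                      stringsAsFactors = FALSE))
  }
  score <- vapply(st, function(f) as.numeric(f[[2L]]), numeric(1))
  lmap <- stats::setNames(lt, lid)
  sigma <- vapply(sid, function(id)
    as.numeric(lmap[[id]][[length_cols[[1L]]]]), numeric(1))
  mlen <- vapply(sid, function(id)
    as.numeric(lmap[[id]][[length_cols[[2L]]]]), numeric(1))
  if (anyNA(score) || anyNA(sigma) || anyNA(mlen)) {
    agm_stop("non-numeric value in cutoff tables", "agm_malformed_input")
  }
  data.frame(orthogroup_id = sid, score_cutoff = score,
             length_cutoff = mlen, length_sigma = sigma,
             stringsAsFactors = FALSE, row.names = NULL)
}
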