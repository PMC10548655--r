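cutoffs1 <- data.frame(orthogroup_id = "og1", score_cutoff = 85,
                       length_cutoff = 310, length_sigma = 30,
                       stringsAsFactors = FALSE)

test_that("candidate classification applies both completeness criteria", {
  prof <- flat_profile("og1", rep(1 / 20, 20))
  prof$score_cutoff <- 85
  prof$length_cutoff <- 310
  prof$length_sigma <- 30
  cand <- function(bs, len) list(orthogroup_id = "og1", bitscore = bs,
                                 protein_length = len)
  # both criteria pass: 90 >= 85 and 300 >= 310 - 2*30 = 250
  expect_equal(classify_candidate(cand(90, 300), prof)$status, "complete")
  # passes similarity (a) but fails minimum length (b)
  expect_equal(classify_candidate(cand(90, 200), prof)$status, "fragmented")
  # fails similarity: rejected regardless of length
  expect_equal(classify_candidate(cand(50, 400), prof)$status, "rejected")
  # orthogroup mismatch
  bad <- list(orthogroup_id = "og2", bitscore = 90, protein_length = 300)
  expect_error(classify_candidate(bad, prof), class = "agm_invalid_argument")
})

test_that("vectorized classification agrees with the scalar rule", {
  cands <- data.frame(
    gene_id = c("g1", "g2", "g3"), orthogroup_id = "og1",
    protein_length = c(300, 200, 400), bitscore = c(90, 90, 50),
    stringsAsFactors = FALSE)
  out <- classify_candidates(cands, cutoffs1)
  expect_equal(out$status, c("complete", "fragmented", "rejected"))
  expect_error(classify_candidates(
    data.frame(gene_id = "g", orthogroup_id = "nope", protein_length = 1,
               bitscore = 1), cutoffs1), class = "agm_invalid_argument")
})

make_classified <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], orthogroup_id = r[[2]], status = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("orthogroups are categorized into S/D/F/M from gene counts", {
  cl <- make_classified(
    list("a1", "ogS", "complete"),
    list("b1", "ogD", "complete"), list("b2", "ogD", "complete"),
    list("b3", "ogD", "fragmented"),
    list("c1", "ogF", "fragmented"), list("c2", "ogF", "rejected"),
    list("d1", "ogM", "rejected"))
  st <- categorize_orthogroups(cl, c("ogS", "ogD", "ogF", "ogM", "ogNone"))
  got <- stats::setNames(st$category, st$orthogroup_id)
  expect_equal(got[["ogS"]], "S")   # a single completely assembled gene
  expect_equal(got[["ogD"]], "D")   # more than one complete gene
  expect_equal(got[["ogF"]], "F")   # only fragmented genes pass (a)
  expect_equal(got[["ogM"]], "M")   # nothing passes (a)
  expect_equal(got[["ogNone"]], "M")  # no candidates at all
  expect_equal(st$n_complete[st$orthogroup_id == "ogD"], 2L)
  # every orthogroup gets a status; categories partition the set
  expect_equal(sum(table(st$category)), 5L)
  expect_error(categorize_orthogroups(cl, c("ogS")),
               class = "agm_invalid_argument")
})

test_that("N(C) = N(S) + N(D) and upgrades never demote a D orthogroup", {
  set.seed(21)
  for (rep in 1:20) {
    n_og <- sample(3:8, 1)
    ogs <- sprintf("og%02d", seq_len(n_og))
    n_genes <- sample(0:4, n_og, replace = TRUE)
    cl <- do.call(rbind, lapply(seq_len(n_og), function(i) {
      if (n_genes[i] == 0) return(NULL)
      data.frame(gene_id = sprintf("%s_g%d", ogs[i], seq_len(n_genes[i])),
                 orthogroup_id = ogs[i],
                 status = sample(c("complete", "fragmented", "rejected"),
                                 n_genes[i], replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cl)) cl <- make_classified(list("x", ogs[1], "rejected"))
    st <- categorize_orthogroups(cl, ogs)
    tab <- table(factor(st$category, levels = c("S", "D", "F", "M")))
    expect_equal(sum(tab), n_og)
    # N(C) = N(S) + N(D) by construction of the compound category
    expect_equal(sum(st$category %in% c("S", "D")), tab[["S"]] + tab[["D"]])
    # upgrading one fragmented gene to complete never leaves D for S/F/M
    frag_idx <- which(cl$status == "fragmented")
    if (length(frag_idx) > 0) {
      i <- frag_idx[[1]]
      og <- cl$orthogroup_id[[i]]
      before <- st$category[st$orthogroup_id == og]
      cl2 <- cl
      cl2$status[[i]] <- "complete"
      after <- categorize_orthogroups(cl2, ogs)
      after_cat <- after$category[after$orthogroup_id == og]
      if (before == "D") expect_equal(after_cat, "D")
    }
  }
})

test_that("candidate TSV reader recovers candidates and merged exons", {
  tsv <- c("gene_id\torthogroup_id\tprotein_length\tbitscore\tcontig\texons",
           "g1\tog1\t300\t90\tctg1\t0-100,100-200",
           "g2\tog1\t200\t90\tctg2\t50-150")
  parsed <- read_candidates_tsv(tsv)
  expect_equal(nrow(parsed$candidates), 2L)
  g1 <- parsed$exons[parsed$exons$gene_id == "g1", ]
  expect_equal(nrow(g1), 1L)  # abutting spans merged
  expect_equal(c(g1$start, g1$end), c(0L, 200L))
  expect_error(read_candidates_tsv(c(
    "gene_id\torthogroup_id\tprotein_length\tbitscore\tcontig\texons",
    "g1\tog1\t300\t90\tctg1\t100-50")), class = "agm_malformed_interval")
})

test_that("domtblout reader extracts gene, orthogroup and bit score", {
  lines <- c("# comment",
             paste("gene1 - 350 og1 - 120 1e-40 99.5 1 1 0 0 0 0 0 0 0 0 0",
                   "0 0 desc"),
             "gene2 - 300 og2 - 120 1e-10 45.0 1 1 0 0 0 0 0 0 0 0 0 0 0 x")
  hits <- parse_domtblout(lines)
  expect_equal(hits$gene_id, c("gene1", "gene2"))
  expect_equal(hits$orthogroup_id, c("og1", "og2"))
  expect_equal(hits$bitscore, c(99.5, 45.0))
})
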