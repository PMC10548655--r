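test_that("TM/FM classification splits at the threshold, boundary to FM", {
  expect_equal(classify_multicopy(100, 100), "TM")
  expect_equal(classify_multicopy(50, 100), "FM")   # halved coverage
  expect_equal(classify_multicopy(75, 100), "FM")   # boundary: not strict excess
  expect_equal(classify_multicopy(75 + 1e-9, 100), "TM")
  expect_equal(classify_multicopy(c(80, 70), 100), c("TM", "FM"))
  expect_error(classify_multicopy(50, 0), class = "agm_invalid_argument")
  # configurable threshold factor
  expect_equal(classify_multicopy(60, 100, tm_threshold = 0.5), "TM")
})

test_that("compute_ag counts genes, classifies D orthogroups, keeps invariants", {
  cl <- rbind(
    data.frame(gene_id = c("s1", "s2"), orthogroup_id = c("ogS1", "ogS2"),
               status = "complete", stringsAsFactors = FALSE),
    data.frame(gene_id = c("t1", "t2"), orthogroup_id = "ogTM",
               status = "complete", stringsAsFactors = FALSE),
    data.frame(gene_id = c("f1", "f2"), orthogroup_id = "ogFM",
               status = "complete", stringsAsFactors = FALSE),
    data.frame(gene_id = "fr1", orthogroup_id = "ogF",
               status = "fragmented", stringsAsFactors = FALSE))
  st <- categorize_orthogroups(cl, c("ogS1", "ogS2", "ogTM", "ogFM", "ogF",
                                     "ogM"))
  depths <- data.frame(
    gene_id = c("s1", "s2", "t1", "t2", "f1", "f2", "fr1"),
    median_exonic_depth = c(100, 100, 95, 105, 50, 52, 40),
    stringsAsFactors = FALSE)
  rep <- compute_ag(st, depths)
  expect_equal(rep$cov_s, 100)
  expect_equal(rep$n_genes_S, 2L)
  expect_equal(rep$n_genes_TM, 2L)
  expect_equal(rep$n_genes_FM, 2L)
  expect_equal(rep$ag, 4L)
  expect_equal(rep$ag, rep$n_genes_S + rep$n_genes_TM)
  n <- rep$n_orthogroups
  expect_equal(unname(n[c("S", "D", "F", "M")]), c(2L, 2L, 1L, 1L))
  expect_equal(n[["D"]], n[["TM"]] + n[["FM"]])
  # per-gene table covers S genes, D genes and fragmented genes
  expect_equal(nrow(rep$per_gene_table), 7L)
  # fragmented genes never enter AG
  expect_false("fr1" %in% rep$per_gene_table$gene_id[
    !is.na(rep$per_gene_table$multicopy_class)])

  # missing coverage for a counted gene is an error naming the gene
  expect_error(compute_ag(st, depths[depths$gene_id != "t2", ]),
               "t2", class = "agm_incomplete_coverage")
  # no single-copy genes but multicopy present: AG undefined
  st_d_only <- categorize_orthogroups(cl[cl$orthogroup_id == "ogTM", ],
                                      "ogTM")
  expect_error(compute_ag(st_d_only, depths),
               class = "agm_no_single_copy_genes")
})

test_that("empty input yields AG 0 with an empty report", {
  rep <- compute_ag(NULL, data.frame(gene_id = character(),
                                     median_exonic_depth = numeric()))
  expect_equal(rep$ag, 0L)
  expect_equal(nrow(rep$per_gene_table), 0L)
  expect_true(is.na(rep$cov_s))
})

test_that("AG is invariant under rescaling all depths by k > 0", {
  set.seed(13)
  for (rep_i in 1:10) {
    n_s <- sample(3:8, 1)
    n_d <- sample(1:4, 1)
    cl <- rbind(
      data.frame(gene_id = sprintf("s%d", seq_len(n_s)),
                 orthogroup_id = sprintf("ogS%d", seq_len(n_s)),
                 status = "complete", stringsAsFactors = FALSE),
      do.call(rbind, lapply(seq_len(n_d), function(i) {
        data.frame(gene_id = sprintf("d%d_g%d", i, 1:2),
                   orthogroup_id = sprintf("ogD%d", i),
                   status = "complete", stringsAsFactors = FALSE)
      })))
    st <- categorize_orthogroups(cl, unique(cl$orthogroup_id))
    depths <- data.frame(gene_id = cl$gene_id,
                         median_exonic_depth = stats::runif(nrow(cl), 20, 80),
                         stringsAsFactors = FALSE)
    base <- compute_ag(st, depths)
    for (k in c(0.1, 3, 42)) {
      scaled <- depths
      scaled$median_exonic_depth <- scaled$median_exonic_depth * k
      res <- compute_ag(st, scaled)
      expect_equal(res$ag, base$ag)
      expect_equal(res$n_orthogroups[["TM"]], base$n_orthogroups[["TM"]])
      expect_equal(res$per_gene_table$multicopy_class,
                   base$per_gene_table$multicopy_class)
    }
  }
})

test_that("moving one orthogroup TM->FM lowers AG by its gene count", {
  enc <- encode_category_counts(n_genes_S = 5, n_genes_TM = 4,
                                n_genes_FM = 0)
  base <- compute_ag(enc$statuses, enc$depths)
  expect_equal(base$ag, 9L)
  # push one TM orthogroup (2 genes) below the threshold
  og <- enc$statuses$orthogroup_id[enc$statuses$category == "D"][[1]]
  genes <- enc$statuses$complete_genes[[
    which(enc$statuses$orthogroup_id == og)]]
  depths2 <- enc$depths
  depths2$median_exonic_depth[depths2$gene_id %in% genes] <- 30
  after <- compute_ag(enc$statuses, depths2)
  expect_equal(after$ag, base$ag - length(genes))
})

test_that("summary string and report export follow the BUSCO layout", {
  enc <- encode_category_counts(n_genes_S = 9, n_genes_TM = 2,
                                n_genes_FM = 0)
  rep <- compute_ag(enc$statuses, enc$depths)  # 9 S + 1 D(TM) of 10 ogs
  s <- format_busco_summary(rep)
  expect_match(s, "^C:100\\.0%\\[S:90\\.0%,D:10\\.0%\\]", fixed = FALSE)
  expect_match(s, "AG:11")

  dir <- withr::local_tempdir()
  paths <- export_report(rep, dir)
  expect_true(all(file.exists(paths)))
  tbl <- utils::read.table(file.path(dir, "per_gene.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(tbl), 11L)
  expect_equal(readLines(file.path(dir, "summary.txt")), s)

  # empty report writes a header-only table
  empty <- compute_ag(NULL, data.frame(gene_id = character(),
                                       median_exonic_depth = numeric()))
  dir2 <- withr::local_tempdir()
  export_report(empty, dir2)
  tbl2 <- utils::read.table(file.path(dir2, "per_gene.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(tbl2), 0L)
})
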