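test_that("parse_paf maps fields, honours tp tags and rejects bad lines", {
  rec <- parse_paf("r1\t100\t0\t100\t+\tctg1\t1000\t200\t300\t95\t100\t60")
  expect_equal(rec$target_id, "ctg1")
  expect_equal(rec$target_start, 200L)
  expect_equal(rec$target_end, 300L)
  expect_equal(rec$strand, "+")
  expect_true(rec$is_primary)

  sec <- parse_paf(
    "r1\t100\t0\t100\t+\tctg1\t1000\t200\t300\t95\t100\t60\ttp:A:S")
  expect_false(sec$is_primary)

  expect_error(parse_paf("r1\t100\t0"), class = "agm_malformed_input")
  expect_error(parse_paf("r1\t100\t0\t100\t+\tctg1\t1000\t2e2\tX\t95\t100\t60"),
               class = "agm_malformed_input")
  expect_error(  # target_end beyond target_length
    parse_paf("r1\t100\t0\t100\t+\tctg1\t250\t200\t300\t95\t100\t60"),
    class = "agm_malformed_input")
  expect_equal(nrow(parse_paf(character())), 0L)
})

test_that("PAF records round-trip through write_paf on fuzzed inputs", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:30, 1L)
    tl <- sample(500:5000, n, replace = TRUE)
    ts <- vapply(tl, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
    te <- vapply(seq_len(n), function(i)
      ts[i] + sample.int(tl[i] - ts[i], 1L), integer(1))
    df <- data.frame(
      read_id = sprintf("read%02d", seq_len(n)),
      read_length = sample(100:1000, n, replace = TRUE),
      read_start = 0L, read_end = as.integer(te - ts),
      strand = sample(c("+", "-"), n, replace = TRUE),
      target_id = sample(c("c1", "c2"), n, replace = TRUE),
      target_length = as.integer(tl), target_start = as.integer(ts),
      target_end = as.integer(te), n_match = as.integer(te - ts),
      aln_block_len = as.integer(te - ts), mapq = 60L,
      is_primary = sample(c(TRUE, FALSE), n, replace = TRUE),
      stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".paf")
    write_paf(df, path)
    expect_equal(parse_paf(path), df)
  }
})

test_that("parse_hmm_profile reconstructs emissions from stored -ln p", {
  mk_lines <- function(leng, value_rows) {
    c("HMMER3/f [test]", "NAME  og_test", sprintf("LENG  %d", leng),
      "ALPH  amino",
      paste("HMM", paste(agmetric:::AMINO_ACIDS, collapse = " ")),
      "      m->m m->i m->d i->m i->i d->m d->d",
      paste("  COMPO", paste(rep("2.99573", 20), collapse = " ")),
      paste(" ", paste(rep("0.69315", 20), collapse = " ")),
      paste(" ", paste(rep("0.69315", 7), collapse = " ")),
      unlist(lapply(seq_along(value_rows), function(k) c(
        paste(k, paste(value_rows[[k]], collapse = " "), k, "- - -"),
        paste(" ", paste(rep("0.69315", 20), collapse = " ")),
        paste(" ", paste(rep("0.69315", 7), collapse = " "))))),
      "//")
  }
  # all 20 stored values = -ln(0.05): uniform emissions
  uniform <- rep(sprintf("%.5f", -log(0.05)), 20)
  p <- parse_hmm_profile(mk_lines(1L, list(uniform)))
  expect_equal(unname(p$emissions[1, ]), rep(0.05, 20), tolerance = 1e-5)
  expect_equal(p$orthogroup_id, "og_test")

  # "*" means probability zero
  conc <- c("0.00001", rep("*", 19))
  p2 <- parse_hmm_profile(mk_lines(1L, list(conc)))
  expect_equal(unname(p2$emissions[1, 2:20]), rep(0, 19))
  expect_equal(unname(p2$emissions[1, 1]), 1, tolerance = 1e-4)

  # LENG 5 but 4 emission rows -> error
  expect_error(parse_hmm_profile(mk_lines(5L, rep(list(uniform), 4))),
               class = "agm_malformed_profile")
  expect_error(parse_hmm_profile("not a profile"),
               class = "agm_malformed_profile")
})

test_that("hmm profiles round-trip through the writer and sum to 1", {
  set.seed(11)
  for (rep in 1:5) {
    L <- sample(1:8, 1L)
    E <- matrix(stats::rgamma(L * 20, 0.7), nrow = L)
    E <- E / rowSums(E)
    prof <- orthogroup_profile(sprintf("og%d", rep), E)
    path <- withr::local_tempfile(fileext = ".hmm")
    write_hmm_profile(prof, path)
    back <- parse_hmm_profile(path)
    expect_equal(back$length, L)
    expect_equal(unname(back$emissions), unname(E), tolerance = 1e-4)
    expect_true(all(abs(rowSums(back$emissions) - 1) <= 1e-6))
  }
})

test_that("read_exon_bed parses, merges within-gene intervals, validates", {
  bed <- read_exon_bed("ctg1\t10\t20\tg1|og1")
  expect_equal(bed$start, 10L)
  expect_equal(bed$end, 20L)
  expect_equal(bed$gene_id, "g1")
  expect_equal(bed$orthogroup_id, "og1")

  # abutting intervals canonicalize by merging
  two <- read_exon_bed(c("ctg1\t10\t20\tg1|og1", "ctg1\t20\t30\tg1|og1"))
  expect_equal(nrow(two), 1L)
  expect_equal(c(two$start, two$end), c(10L, 30L))

  # different genes are kept apart
  sep <- read_exon_bed(c("ctg1\t10\t20\tg1|og1", "ctg1\t20\t30\tg2|og1"))
  expect_equal(nrow(sep), 2L)

  expect_error(read_exon_bed("ctg1\t20\t10\tg1|og1"),
               class = "agm_malformed_interval")
  expect_error(read_exon_bed("ctg1\t10\t20\tnopipe"),
               class = "agm_malformed_input")
})

test_that("BED records round-trip through write_exon_bed", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(1:15, 1L)
    s <- sample(0:1000, n)
    bed <- data.frame(contig_id = sprintf("g%02d", seq_len(n)),
                      start = as.integer(s), end = as.integer(s + 50L),
                      gene_id = sprintf("g%02d", seq_len(n)),
                      orthogroup_id = "og1", stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".bed")
    write_exon_bed(bed, path)
    back <- read_exon_bed(path)
    expect_equal(back[order(back$gene_id), ]$start, bed$start)
    expect_equal(back[order(back$gene_id), ]$end, bed$end)
  }
})

test_that("parse_blasttab reads 12-column rows and rejects bad input", {
  row <- paste("read1", "prot1", "90.0", "100", "5", "0", "1", "100", "1",
               "100", "1e-30", "120", sep = "\t")
  hits <- parse_blasttab(row)
  expect_equal(hits$read_id, "read1")
  expect_equal(hits$protein_id, "prot1")
  expect_equal(hits$bitscore, 120)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(nrow(parse_blasttab(character())), 0L)
  expect_error(parse_blasttab(paste(rep("x", 11), collapse = "\t")),
               class = "agm_malformed_input")
  bad <- paste(c(rep("x", 10), "oops", "120"), collapse = "\t")
  expect_error(parse_blasttab(bad), class = "agm_malformed_input")
})

test_that("read_cutoff_tables merges the BUSCO dialect and checks ids", {
  cut <- read_cutoff_tables("og1 85.0", "og1 0 30.0 310")
  expect_equal(cut$score_cutoff, 85)
  expect_equal(cut$length_cutoff, 310)
  expect_equal(cut$length_sigma, 30)

  expect_error(read_cutoff_tables(c("og1 85.0", "og2 60.0"), "og1 0 30 310"),
               class = "agm_inconsistent_dataset")
  empty <- read_cutoff_tables(character(), character())
  expect_equal(nrow(empty), 0L)
})

test_that("a dataset directory round-trips through writer and reader", {
  cat <- synthetic_catalog(6, seed = 2, profile_length = 3)
  dir <- withr::local_tempdir()
  write_busco_dataset(cat, dir)
  back <- read_busco_dataset(dir)
  expect_equal(sort(names(back$profiles)), sort(names(cat$profiles)))
  p <- back$profiles[["og00003"]]
  expect_equal(p$score_cutoff, 50)
  expect_equal(p$length_cutoff, 300)
  expect_equal(unname(p$emissions),
               unname(cat$profiles[["og00003"]]$emissions),
               tolerance = 1e-4)
  expect_equal(p$ancestral_protein, cat$profiles[["og00003"]]$ancestral_protein)
})
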