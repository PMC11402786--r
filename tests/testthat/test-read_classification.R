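test_that("pair merging reproduces the amplicon geometry", {
  withr::local_seed(11)
  # 450 nt amplicon, 300 nt mates: perfect 150 nt overlap
  amp <- random_dna_str(450)
  res <- merge_read_pair(substr(amp, 1, 300), revcomp_str(substr(amp, 151, 450)))
  expect_true(res$merged)
  expect_equal(nchar(res$sequence), 450)
  expect_equal(res$sequence, amp)
  expect_equal(res$overlap_len, 150L)
  expect_equal(res$mismatches_in_overlap, 0L)

  # 700 nt amplicon: mates cannot overlap at all
  amp2 <- random_dna_str(700)
  res2 <- merge_read_pair(substr(amp2, 1, 300),
                          revcomp_str(substr(amp2, 401, 700)))
  expect_false(res2$merged)
  expect_true(is.na(res2$sequence))
})

test_that("overlaps above the mismatch tolerance are rejected", {
  withr::local_seed(12)
  amp <- random_dna_str(450)
  fwd <- substr(amp, 1, 300)
  rev_seq <- substr(amp, 151, 450)
  # corrupt 30 of the 150 overlap bases of the reverse mate
  ov <- strsplit(substr(rev_seq, 1, 150), "")[[1]]
  pos <- sample(150, 30)
  ov[pos] <- vapply(ov[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  rev_bad <- paste0(paste(ov, collapse = ""), substr(rev_seq, 151, 300))
  res <- merge_read_pair(fwd, revcomp_str(rev_bad), max_mismatch_frac = 0.1)
  # 30/150 = 0.2 > 0.1 at the true overlap; no other acceptable overlap
  expect_false(res$merged)
  res_loose <- merge_read_pair(fwd, revcomp_str(rev_bad),
                               max_mismatch_frac = 0.25)
  expect_true(res_loose$merged)
  expect_equal(res_loose$overlap_len, 150L)
})

test_that("merged length is fwd + rev - overlap for random geometries", {
  withr::local_seed(13)
  for (amp_len in c(320, 405, 500, 589, 590)) {
    amp <- random_dna_str(amp_len)
    fwd <- substr(amp, 1, min(300, amp_len))
    rev_seq <- substr(amp, max(1, amp_len - 299), amp_len)
    res <- merge_read_pair(fwd, revcomp_str(rev_seq))
    expect_true(res$merged)
    expect_equal(nchar(res$sequence),
                 nchar(fwd) + nchar(rev_seq) - res$overlap_len)
    expect_equal(res$sequence, amp)
  }
})

test_that("merging validates its inputs", {
  expect_error(merge_read_pair("", "ACGT"), "non-empty")
  expect_error(merge_read_pairs(tibble::tibble(read_id = "r", fwd = "ACGT",
                                               rev = "ACGT"),
                                max_mismatch_frac = 0.6),
               "0.5")
  expect_error(merge_read_pairs(tibble::tibble(read_id = "r", fwd = "ACGT",
                                               rev = "ACGT"),
                                min_overlap = 0),
               "at least 1")
})

test_that("exact reference reads classify to their isoform at distance 0", {
  gm <- default_gene_model()
  refs <- setNames(chartr("U", "T", gm$isoforms$sequence),
                   gm$isoforms$isoform)
  cl <- classify_reads(unname(refs), gm)
  expect_equal(cl$label, names(refs))
  expect_equal(cl$best_distance, rep(0L, length(refs)))
})

test_that("ties and sub-margin wins are unclassified, never random", {
  subst_at <- function(s, pos, repl) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- repl
    paste(ch, collapse = "")
  }
  ref1 <- strrep("ACGT", 10)                       # 40 nt
  ref2 <- subst_at(ref1, c(1, 11, 21, 31), c("C", "G", "T", "A"))
  cat2 <- build_isoform_catalog(
    tibble::tibble(exon_id = c("A", "B"), sequence = c(ref1, ref2)),
    list(iso1 = "A", iso2 = "B"), merge_limit_nt = 600)
  # a read carrying 2 of the 4 distinguishing substitutions lies at
  # distance 2 from both references: tie -> unclassified
  tie_read <- subst_at(ref1, c(1, 11), c("C", "G"))
  expect_equal(classify_merged_read(tie_read, cat2), "unclassified")
  # a read 1 edit from ref1 wins with a wide margin
  near <- subst_at(ref1, 5, "T")
  expect_equal(classify_merged_read(near, cat2), "iso1")
  # references only 1 edit apart can never satisfy min_margin = 2
  cat_close <- build_isoform_catalog(
    tibble::tibble(exon_id = c("A", "B"),
                   sequence = c(ref1, subst_at(ref1, 1, "C"))),
    list(iso1 = "A", iso2 = "B"), merge_limit_nt = 600)
  expect_equal(classify_merged_read(ref1, cat_close, min_margin = 2),
               "unclassified")
})

test_that("classification agrees with the full-matrix adist oracle", {
  gm <- default_gene_model()
  withr::local_seed(21)
  sim <- simulate_cell_reads(gm, n_reads = 150, read_len = 700,
                             error_rate = 0.02, seed = 99, cell_id = "o")
  # read_len 700 > longest amplicon: every "read" is a full-length molecule
  seqs <- sim$reads$fwd
  got <- classify_reads(seqs, gm)$label
  want <- oracle_classify(seqs, gm)
  expect_identical(got, want)
  # and with the margin stressed
  got5 <- classify_reads(seqs, gm, min_margin = 5)$label
  want5 <- oracle_classify(seqs, gm, min_margin = 5)
  expect_identical(got5, want5)
})

test_that("unmerged pairs separate the two long isoforms by the extension signature", {
  gm <- default_gene_model()
  refs <- setNames(chartr("U", "T", gm$isoforms$sequence),
                   gm$isoforms$isoform)
  pair_from <- function(ref) {
    L <- nchar(ref)
    tibble::tibble(read_id = "p", fwd = substr(ref, 1, 300),
                   rev = revcomp_str(substr(ref, L - 299, L)))
  }
  expect_equal(classify_unmerged_pairs(pair_from(refs["noS"]), gm)$label,
               "noS")
  expect_equal(classify_unmerged_pairs(pair_from(refs["E3a"]), gm)$label,
               "E3a")
  # a pair matching neither long-isoform end is unclassified
  junk <- tibble::tibble(read_id = "j",
                         fwd = random_dna_str(300),
                         rev = random_dna_str(300))
  withr::local_seed(31)
  expect_equal(classify_unmerged_pairs(junk, gm)$label, "unclassified")
})

test_that("the unmerged route tolerates sequencing errors in the signature", {
  gm <- default_gene_model()
  ref <- chartr("U", "T",
                gm$isoforms$sequence[gm$isoforms$isoform == "E3a"])
  L <- nchar(ref)
  withr::local_seed(32)
  for (i in 1:20) {
    fwd <- substr(ref, 1, 300)
    rv <- substr(ref, L - 299, L)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }
    pr <- tibble::tibble(read_id = "e", fwd = mut(fwd, 3),
                         rev = revcomp_str(mut(rv, 3)))
    expect_equal(classify_unmerged_pairs(pr, gm)$label, "E3a")
  }
})

test_that("count_sample conserves reads and matches simulation truth", {
  gm <- default_gene_model()
  # empty input
  empty <- count_sample(tibble::tibble(read_id = character(),
                                       fwd = character(),
                                       rev = character()), gm)
  expect_true(all(empty$count == 0))
  # error-free reads: counts equal truth exactly
  sim <- simulate_cell_reads(gm, n_reads = 400, error_rate = 0,
                             seed = 5, cell_id = "exact")
  cnt <- count_sample(sim$reads, gm, sample_id = "exact")
  expect_equal(sum(cnt$count), 400)
  truth <- table(sim$truth$isoform)
  for (cat in names(truth)) {
    expect_equal(cnt$count[cnt$category == cat], unname(truth[cat]),
                 label = paste("count of", cat))
  }
  expect_equal(cnt$count[cnt$category == "unclassified"], 0L)
})

test_that("classification is invariant to read order", {
  gm <- default_gene_model()
  sim <- simulate_cell_reads(gm, n_reads = 120, error_rate = 0.01,
                             seed = 6, cell_id = "ord")
  fwdo <- count_sample(sim$reads, gm, sample_id = "s")
  revo <- count_sample(sim$reads[rev(seq_len(nrow(sim$reads))), ], gm,
                       sample_id = "s")
  expect_equal(fwdo$count, revo$count)
})

test_that("FASTQ pairs round-trip through files", {
  gm <- default_gene_model()
  sim <- simulate_cell_reads(gm, n_reads = 30, seed = 8, cell_id = "io")
  tmp <- withr::local_tempdir()
  write_fastq_pair(sim$reads, tmp, "io")
  back <- read_fastq_pairs(file.path(tmp, "io_R1.fastq"),
                           file.path(tmp, "io_R2.fastq"))
  expect_equal(back$fwd, sim$reads$fwd)
  expect_equal(back$rev, sim$reads$rev)
  expect_equal(back$read_id, sim$reads$read_id)
  # malformed FASTQ is reported as such
  bad <- file.path(tmp, "bad.fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(read_fastq_pairs(bad, bad), "Malformed FASTQ")
})
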