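# Helpers to fabricate read pairs over a known construct.
make_pair <- function(construct, read_len = 125L) {
  n <- nchar(construct)
  r1 <- substr(construct, 1, min(read_len, n))
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(construct, max(1, n - read_len + 1), n))))
  list(r1 = r1, q1 = strrep("F", nchar(r1)), r2 = r2, q2 = strrep("F", nchar(r2)))
}

mutate_at <- function(seq, pos, base = NULL) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), s[p])
    s[p] <- if (is.null(base)) alt[1] else base
  }
  paste(s, collapse = "")
}

test_that("overlap merging reconstructs the construct and prefers quality", {
  fl <- default_flanks()
  construct <- paste0(fl$flank5, "ATGGCTAAATTTGGGCCCAAATAG", fl$flank3)
  p <- make_pair(construct, read_len = 50L)
  m <- merge_read_pair(p$r1, p$q1, p$r2, p$q2)
  expect_equal(m$seq, construct)
  expect_equal(nchar(m$qual), nchar(construct))
  # disagreement in the overlap resolved toward the higher-quality base
  r1_bad <- mutate_at(p$r1, 40)
  q1_bad <- paste0(substr(p$q1, 1, 39), "0", substr(p$q1, 41, nchar(p$q1)))
  m2 <- merge_read_pair(r1_bad, q1_bad, p$r2, p$q2)
  expect_equal(m2$seq, construct)
  # irreconcilable pair is rejected with a reason
  junk <- paste(rep("A", 50), collapse = "")
  bad <- merge_read_pair(junk, strrep("F", 50), strrep("C", 50), strrep("F", 50))
  expect_true(is_reject(bad))
  expect_equal(reject_reason(bad), "unmergeable")
})

test_that("flank trimming applies the 20 percent mismatch budget per flank", {
  fl <- default_flanks()
  region <- "ATGGCTAAATTTGGGCCC"
  construct <- paste0(fl$flank5, region, fl$flank3)
  qual <- strrep("F", nchar(construct))
  tr <- trim_flanks(construct, qual, fl$flank5, fl$flank3)
  expect_equal(tr$seq, region)
  # 25-nt 5' flank: floor(0.2 * 25) = 5 mismatches accepted, 6 rejected
  c5 <- mutate_at(construct, 1:5)
  expect_equal(trim_flanks(c5, qual, fl$flank5, fl$flank3)$seq, region)
  c6 <- mutate_at(construct, 1:6)
  rej <- trim_flanks(c6, qual, fl$flank5, fl$flank3)
  expect_true(is_reject(rej))
  expect_equal(reject_reason(rej), "flank5_mismatch")
  # 21-nt 3' flank: floor(0.2 * 21) = 4 accepted, 5 rejected
  n <- nchar(construct)
  c4 <- mutate_at(construct, (n - 3):n)
  expect_equal(trim_flanks(c4, qual, fl$flank5, fl$flank3)$seq, region)
  c5b <- mutate_at(construct, (n - 4):n)
  expect_true(is_reject(trim_flanks(c5b, qual, fl$flank5, fl$flank3)))
})

test_that("the quality filter is a strict per-base Phred 30 threshold", {
  q37 <- strrep("F", 10)
  expect_true(quality_filter(q37))
  q29 <- paste0(substr(q37, 1, 5), rawToChar(as.raw(33 + 29)), substr(q37, 7, 10))
  expect_false(quality_filter(q29))
  q30 <- paste0(substr(q37, 1, 5), rawToChar(as.raw(33 + 30)), substr(q37, 7, 10))
  expect_true(quality_filter(q30))
})

test_that("variant counting matches exactly and tallies non-designed reads", {
  lib <- build_library(short_wt(), max_del_len = 9)
  fl <- default_flanks()
  wt_nt <- lib$variants$nt_seq[lib$variants$variant_id == "WT"]
  v2 <- lib$variants$nt_seq[5]
  off <- mutate_at(wt_nt, 2)  # one nt off every design
  stopifnot(!off %in% lib$variants$nt_seq)
  constructs <- paste0(fl$flank5, c(wt_nt, wt_nt, v2, off), fl$flank3)
  dir <- withr::local_tempdir()
  pairs <- lapply(constructs, make_pair)
  dimatlas:::write_fastq(sprintf("r%d", 1:4),
                         vapply(pairs, `[[`, "", "r1"),
                         vapply(pairs, `[[`, "", "q1"),
                         file.path(dir, "s_R1.fastq.gz"))
  dimatlas:::write_fastq(sprintf("r%d", 1:4),
                         vapply(pairs, `[[`, "", "r2"),
                         vapply(pairs, `[[`, "", "q2"),
                         file.path(dir, "s_R2.fastq.gz"))
  res <- count_reads(file.path(dir, "s_R1.fastq.gz"),
                     file.path(dir, "s_R2.fastq.gz"), lib)
  expect_equal(unname(res$counts["WT"]), 2L)
  expect_equal(unname(res$counts[lib$variants$variant_id[5]]), 1L)
  expect_equal(unname(res$qc["non_designed"]), 1L)
  expect_equal(unname(res$qc["designed"]), 3L)
  # translation-level matching accepts synonymous nucleotide sequences
  res_aa <- count_reads(file.path(dir, "s_R1.fastq.gz"),
                        file.path(dir, "s_R2.fastq.gz"), lib,
                        match_level = "aa")
  expect_gte(sum(res_aa$counts), 3L)
})

test_that("zero-error FASTQ emission round-trips to the simulated counts", {
  lib <- build_library(short_wt(), max_del_len = 9)
  cfg <- sim_config(n_bio = 2, n_tech = 1, depth = 1500, dead_prob = 0.02,
                    err_rate = 0, seed = 17)
  tr <- sample_true_scores(lib, cfg)
  ct <- simulate_counts(lib, tr, cfg)
  dir <- withr::local_tempdir()
  sheet <- emit_fastq(ct, lib, dir, cfg)
  q <- quantify_samples(sheet, lib)
  a <- ct[ct$count_in > 0 | ct$count_out > 0, ]
  a <- a[order(a$bio_rep, a$tech_rep, a$variant_id), ]
  b <- q$counts[order(q$counts$bio_rep, q$counts$tech_rep, q$counts$variant_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(b, a)
  # QC accounts for every read
  for (qc in q$qc) {
    expect_equal(qc$reads, qc$designed + qc$non_designed +
                   qc$unmergeable + qc$flank_reject + qc$quality_fail)
  }
})

test_that("input-read filters enforce the 10-read and 1000-read rules strictly", {
  lib <- build_library(short_wt())
  ids <- lib$variants$variant_id
  reserved <- c("WT", ids[ids != "WT"][1:2])
  single_nt <- setdiff(ids[is.finite(lib$variants$nt_min_changes) &
                             lib$variants$nt_min_changes == 1], reserved)[1]
  multi_nt <- setdiff(ids[is.finite(lib$variants$nt_min_changes) &
                            lib$variants$nt_min_changes >= 2], reserved)[1]
  counts <- data.frame(
    variant_id = rep(c("WT", "A", "B", single_nt, multi_nt), each = 3),
    bio_rep = rep(1:3, times = 5), tech_rep = 1L,
    count_in = c(5, 5, 5,          # WT: below threshold but never dropped
                 12, 9, 15,        # A: fewer than 10 in one replicate -> drop
                 10, 10, 10,       # B: boundary, retained
                 300, 300, 300,    # single-nt: 900 pooled < 1000 -> drop
                 300, 300, 300),   # multi-nt: same counts, retained
    count_out = 50)
  counts$variant_id[counts$variant_id == "A"] <- ids[ids != "WT"][1]
  counts$variant_id[counts$variant_id == "B"] <- ids[ids != "WT"][2]
  kept <- apply_read_filters(counts, lib)
  expect_true("WT" %in% kept$variant_id)
  expect_false(ids[ids != "WT"][1] %in% kept$variant_id)
  expect_true(ids[ids != "WT"][2] %in% kept$variant_id)
  expect_false(single_nt %in% kept$variant_id)
  expect_true(multi_nt %in% kept$variant_id)
  # idempotence
  again <- apply_read_filters(kept, lib)
  expect_equal(again$variant_id, kept$variant_id)
  expect_equal(again$count_in, kept$count_in)
})
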