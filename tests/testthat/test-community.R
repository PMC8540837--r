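test_that("quality-window filter implements the 50-nt mean-Phred-20 rule", {
  good <- amplicon_reads("a", paste(rep("A", 100), collapse = ""),
                         list(rep(30L, 100)))
  expect_identical(quality_window_filter(good)$kept$ids, "a")
  # one contiguous 50-nt stretch at Q15 sinks the read
  q <- rep(30L, 200); q[101:150] <- 15L
  bad <- amplicon_reads("b", paste(rep("A", 200), collapse = ""), list(q))
  res <- quality_window_filter(bad)
  expect_identical(res$rejected$id, "b")
  expect_identical(res$rejected$reason, "low_quality_window")
  # short reads are judged on their full length
  short <- amplicon_reads(c("s1", "s2"),
                          c(strrep("A", 30), strrep("A", 30)),
                          list(rep(19L, 30), rep(21L, 30)))
  expect_identical(quality_window_filter(short)$kept$ids, "s2")
})

test_that("quality-window decisions match the all-windows oracle on random reads", {
  reads <- random_reads(1000, seed = 123)
  res <- quality_window_filter(reads)
  expected_fail <- vapply(reads$qualities, oracle_window_fails, logical(1))
  expect_setequal(res$rejected$id, reads$ids[expected_fail])
  expect_setequal(res$kept$ids, reads$ids[!expected_fail])
})

test_that("a batch with a known number of planted failures is split exactly", {
  set.seed(9)
  n <- 100
  fail_idx <- sort(sample(n, 17))
  quals <- lapply(seq_len(n), function(i) {
    q <- rep(32L, 120)
    if (i %in% fail_idx) q[31:80] <- 12L
    q
  })
  reads <- amplicon_reads(paste0("r", 1:n),
                          replicate(n, strrep("A", 120)), quals)
  res <- quality_window_filter(reads)
  expect_length(res$kept$ids, 83)
  expect_setequal(res$rejected$id, paste0("r", fail_idx))
})

test_that("reads with mismatched quality vectors are rejected with a reason", {
  reads <- amplicon_reads(c("ok", "bad"), c("ACGTAC", "ACGTAC"),
                          list(rep(30L, 6), rep(30L, 5)))
  res <- quality_window_filter(reads)
  expect_identical(res$rejected$id, "bad")
  expect_identical(res$rejected$reason, "length_mismatch")
})

test_that("frame/stop filter catches framing errors and in-frame stops", {
  orf <- gen_reference_orfs(1, 465, seed = 3)[[1]]
  expect_true(frame_stop_filter(orf)$pass)
  r466 <- paste0(orf, "A")
  expect_false(frame_stop_filter(r466)$pass)
  expect_identical(frame_stop_filter(r466)$reason, "framing")
  stopped <- orf
  substr(stopped, 58, 60) <- "TAA"  # codon 20
  expect_false(frame_stop_filter(stopped)$pass)
  expect_identical(frame_stop_filter(stopped)$reason, "stop_codon")
  expect_error(frame_stop_filter("ACGXGG"), "non-IUPAC")
})

test_that("frame/stop filter agrees with translation under the bacterial code", {
  orfs <- gen_reference_orfs(20, 465, seed = 21)
  for (s in orfs) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_identical(frame_stop_filter(s)$pass, !grepl("*", aa, fixed = TRUE))
  }
  # and on sequences with a planted stop
  s <- orfs[[1]]
  substr(s, 301, 303) <- "TGA"
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_true(grepl("*", aa, fixed = TRUE))
  expect_false(frame_stop_filter(s)$pass)
})

test_that("length windows are inclusive and primer-set specific", {
  expect_true(length_window_filter(465, "mb661R"))
  expect_true(length_window_filter(474, "mb661R"))
  expect_false(length_window_filter(464, "mb661R"))
  expect_false(length_window_filter(475, "mb661R"))
  expect_true(length_window_filter(492, "A682R"))
  expect_true(length_window_filter(495, "A682R"))
  expect_false(length_window_filter(496, "A682R"))
  expect_true(length_window_filter(strrep("A", 470), "mb661R"))
  expect_error(length_window_filter(465, "nifH"))
})

test_that("taxonomy is assigned by best global alignment with tie flagging", {
  set.seed(31)
  seqs <- vapply(1:3, function(i)
    paste0(sample(c("A", "C", "G", "T"), 452, replace = TRUE), collapse = ""),
    character(1))
  db <- reference_db(paste0("Methylobacter;sp", 1:3), seqs, "mb661R")
  hit <- assign_taxonomy(seqs[2], db)
  expect_identical(hit$taxonomy, "Methylobacter;sp2")
  expect_equal(hit$percent_identity, 100)
  expect_false(hit$tie)
  # one substitution over a 452-column alignment
  q <- seqs[2]
  old <- substr(q, 100, 100)
  substr(q, 100, 100) <- setdiff(c("A", "C", "G", "T"), old)[1]
  hit1 <- assign_taxonomy(q, db)
  expect_identical(hit1$taxonomy, "Methylobacter;sp2")
  expect_equal(hit1$percent_identity, 451 / 452 * 100, tolerance = 1e-9)
  # a duplicated entry ties; first in database order wins, flagged
  db_dup <- reference_db(c("first;copy", "second;copy"), rep(seqs[1], 2))
  hit_dup <- assign_taxonomy(seqs[1], db_dup)
  expect_identical(hit_dup$taxonomy, "first;copy")
  expect_true(hit_dup$tie)
  expect_error(reference_db(character(), character()), "empty")
})

test_that("relative abundance normalises rows and flags empty samples", {
  x <- rbind(a = c(10, 30, 60), b = c(0, 0, 0), c = c(5, 5, 0))
  expect_warning(rel <- to_relative_abundance(x), "empty")
  expect_equal(rel["a", ], c(0.1, 0.3, 0.6), ignore_attr = TRUE)
  expect_equal(unname(rowSums(rel)), c(1, 0, 1))
  expect_identical(attr(rel, "empty_samples"), "b")
  expect_error(to_relative_abundance(rbind(c(-1, 2))), "non-negative")
})

test_that("denoising zeroes strictly-below-threshold entries and reports the read loss", {
  counts <- rbind(s1 = c(9, 9991), s2 = c(10, 9990))
  rel <- to_relative_abundance(counts)
  dn <- denoise(rel, counts)              # 9e-4 < 1e-3 goes; 1e-3 stays
  expect_identical(unname(dn$rel["s1", 1]), 0)
  expect_equal(unname(dn$rel["s1", 2]), 1)
  expect_equal(dn$rel["s2", ], rel["s2", ])
  expect_equal(dn$removed_fraction, 9 / 20000)
  expect_identical(dn$n_zeroed, 1L)
  expect_error(denoise(rel, counts, threshold = 0), "threshold")
})

test_that("a table built to lose 3% of reads loses exactly that, under 5%", {
  counts <- matrix(c(rep(9, 30), 9730), 1, 31)  # 270 of 10000 reads sub-threshold
  rownames(counts) <- "s1"
  rel <- to_relative_abundance(counts)
  dn <- denoise(rel, counts)
  expect_equal(dn$removed_fraction, 0.027)
  expect_lt(dn$removed_fraction, 0.05)
  expect_identical(dn$n_zeroed, 30L)
  # second pass on the renormalised table: nothing crosses, so idempotent
  dn2 <- denoise(dn$rel)
  expect_identical(dn2$n_zeroed, 0L)
  expect_equal(dn2$rel, dn$rel)
})

test_that("log normalisation maps 0 to 0 and x to log_b(x) + 1", {
  x <- rbind(c(0, 1, 8), c(2, 0, 1024))
  out <- log_normalize(x, base = 2)
  expect_equal(out, rbind(c(0, 1, 4), c(2, 0, 11)))
  expect_error(log_normalize(rbind(c(-1, 0))), "non-negative")
  expect_warning(log_normalize(rbind(c(0.5, 2))), "negative")
  # monotone on positives
  v <- sort(runif(20, 0.5, 100))
  expect_true(all(diff(as.vector(log_normalize(matrix(v, 1)))) > 0))
})
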