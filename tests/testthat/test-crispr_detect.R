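test_that("planted arrays are recovered with exact boundaries and match the brute-force oracle", {
  set.seed(101)
  for (case in list(list(m = 5L, deg = FALSE), list(m = 4L, deg = TRUE),
                    list(m = 8L, deg = TRUE))) {
    tb <- build_test_array(n_repeats = case$m, degenerate_last = case$deg,
                           pad = 1200L)
    det <- detect_arrays(tb$contig)
    expect_length(det, 1)
    expect_equal(det[[1]]$start, tb$start)
    expect_equal(det[[1]]$end, tb$end)
    expect_equal(nrow(det[[1]]$repeats), case$m)
    expect_equal(det[[1]]$repeats$start, tb$repeat_starts)
    expect_same_arrays(det, oracle_detect_arrays(tb$contig))
  }
})

test_that("random sequence yields no arrays, in agreement with the oracle", {
  set.seed(7)
  contig <- crispratlas:::random_seq(10000)
  expect_length(detect_arrays(contig), 0)
  expect_length(oracle_detect_arrays(contig), 0)
})

test_that("two planted arrays on one contig are both found, non-overlapping", {
  set.seed(55)
  t1 <- build_test_array(n_repeats = 5L, pad = 800L)
  t2 <- build_test_array(n_repeats = 4L,
                         repeat_seq = crispr_repeat2(), pad = 800L)
  contig <- paste0(t1$contig, t2$contig)
  det <- detect_arrays(contig)
  expect_length(det, 2)
  expect_equal(det[[1]]$start, t1$start)
  expect_equal(det[[2]]$start, nchar(t1$contig) + t2$start)
  expect_true(det[[1]]$end <= det[[2]]$start)
  expect_same_arrays(det, oracle_detect_arrays(contig))
})

test_that("detection is reverse-complement equivariant", {
  set.seed(77)
  tb <- build_test_array(n_repeats = 6L, pad = 900L)
  fwd <- detect_arrays(tb$contig)
  rev <- detect_arrays(revcomp(tb$contig))
  expect_length(rev, length(fwd))
  n <- nchar(tb$contig)
  expect_equal(rev[[1]]$start, n - fwd[[1]]$end)
  expect_equal(rev[[1]]$end, n - fwd[[1]]$start)
  expect_equal(rev[[1]]$consensus$seq, revcomp(fwd[[1]]$consensus$seq))
})

test_that("a planted printed-consensus array gives a 29 bp consensus", {
  set.seed(3)
  tb <- build_test_array(n_repeats = 5L)
  det <- detect_arrays(tb$contig)
  expect_equal(det[[1]]$consensus$length, 29L)
  expect_equal(det[[1]]$consensus$seq, gsub("W", "A", crispr_repeat1()))
})

test_that("consensus_of takes the modal sequence with deterministic ties", {
  r <- gsub("W", "A", crispr_repeat1())
  expect_equal(consensus_of(rep(r, 7))$seq, r)
  expect_equal(consensus_of(rep(r, 7))$exact_fraction, 1.0)
  x <- "AAAA"; y <- "CCCC"
  expect_equal(consensus_of(c(rep(x, 6), rep(y, 4)))$seq, x)
  # tie -> lexicographically smaller
  expect_equal(consensus_of(c(rep(y, 5), rep(x, 5)))$seq, x)
  # permutation invariance
  set.seed(9)
  seqs <- c(rep(x, 6), rep(y, 4))
  for (i in 1:5)
    expect_equal(consensus_of(sample(seqs))$seq, consensus_of(seqs)$seq)
  expect_error(consensus_of(c("AA", "AAA")), "equal length")
  # exact_fraction excludes terminal repeats on request
  seqs2 <- c("AATT", rep("AAAA", 3), "AACC")
  expect_equal(consensus_of(seqs2, exclude_terminals = TRUE)$exact_fraction, 1)
  expect_lt(consensus_of(seqs2)$exact_fraction, 1)
})

test_that("fuzzy_find honours the 60% same-length identity rule", {
  set.seed(13)
  cons <- gsub("W", "A", crispr_repeat1())
  contig <- paste0(crispratlas:::random_seq(400), cons,
                   crispratlas:::random_seq(400))
  u <- fuzzy_find(contig, cons, min_identity = 0.6)
  expect_equal(nrow(u), 1)
  expect_equal(u$identity, 1.0)
  expect_equal(u$start, 400)
  # 12 of 29 mutated -> identity 0.586, below threshold
  worse <- crispratlas:::substitute_at(cons, sample(29, 12))
  contig2 <- paste0(crispratlas:::random_seq(400), worse,
                    crispratlas:::random_seq(400))
  u2 <- fuzzy_find(contig2, cons, min_identity = 0.6)
  expect_false(any(u2$start == 400))
  # the printed W position matches either A or T
  for (b in c("A", "T")) {
    c3 <- paste0(crispratlas:::random_seq(200),
                 gsub("W", b, crispr_repeat1()),
                 crispratlas:::random_seq(200))
    u3 <- fuzzy_find(c3, crispr_repeat1(), min_identity = 0.95)
    expect_true(any(u3$start == 200 & u3$identity == 1.0))
  }
  expect_error(fuzzy_find(contig, cons, region = c(-5, 100)), "bounds")
})

test_that("rescued units across a transposase gap give a disrupted array", {
  set.seed(21)
  cons <- gsub("W", "A", crispr_repeat1())
  gap_is <- crispratlas:::random_seq(900)     # IS-sized insert
  contig <- paste0(crispratlas:::random_seq(300),
                   cons, crispratlas:::random_seq(30), cons,
                   crispratlas:::random_seq(15), gap_is,
                   crispratlas:::random_seq(15),
                   cons, crispratlas:::random_seq(30), cons,
                   crispratlas:::random_seq(300))
  u <- fuzzy_find(contig, cons, min_identity = 0.9)
  expect_equal(nrow(u), 4)
  arrs <- assemble_rescued(u, contig, contig_id = "c")
  expect_length(arrs, 1)
  expect_true(arrs[[1]]$flags$is_disrupted)
  # a lone unit is a single-repeat array
  c1 <- paste0(crispratlas:::random_seq(300), cons,
               crispratlas:::random_seq(300))
  a1 <- assemble_rescued(fuzzy_find(c1, cons, min_identity = 0.9), c1)
  expect_length(a1, 1)
  expect_true(a1[[1]]$flags$single_repeat)
})

test_that("extract_spacers reassembles the array span exactly", {
  set.seed(31)
  tb <- build_test_array(n_repeats = 5L)
  a <- detect_arrays(tb$contig)[[1]]
  a <- extract_spacers(a, tb$contig)
  expect_equal(nrow(a$spacers), 4)
  expect_equal(a$spacers$seq, tb$spacers)
  # round trip: repeats + spacers reassemble the span
  parts <- character(0)
  for (i in seq_len(nrow(a$repeats))) {
    parts <- c(parts, a$repeats$seq[i])
    if (i <= nrow(a$spacers)) parts <- c(parts, a$spacers$seq[i])
  }
  expect_equal(paste(parts, collapse = ""),
               substr(tb$contig, a$start + 1, a$end))
  expect_equal(a$spacers$index_from_leader, 0:3)
  a$orientation <- "leader_right"
  a2 <- extract_spacers(a, tb$contig)
  expect_equal(a2$spacers$index_from_leader, 3:0)
})

test_that("single-repeat arrays have no spacers; oversized gaps are logged, not emitted", {
  cons <- gsub("W", "A", crispr_repeat1())
  set.seed(87)
  contig <- paste0(crispratlas:::random_seq(100), cons,
                   crispratlas:::random_seq(600),  # > spacer max: IS-like
                   cons, crispratlas:::random_seq(32), cons,
                   crispratlas:::random_seq(100))
  u <- fuzzy_find(contig, cons, min_identity = 0.95)
  a <- assemble_rescued(u, contig)[[1]]
  a <- extract_spacers(a, contig)
  expect_equal(nrow(a$spacers), 1)
  expect_equal(nrow(a$insertions), 1)
  expect_true(a$flags$is_disrupted)
  single <- assemble_rescued(u[1, , drop = FALSE], contig)[[1]]
  single <- extract_spacers(single, contig)
  expect_equal(nrow(single$spacers), 0)
  # overlapping repeats are an invariant violation
  bad <- a
  bad$repeats$start[2] <- bad$repeats$start[1] + 3
  bad$repeats$end[2] <- bad$repeats$start[2] + 29
  bad$repeats <- bad$repeats[order(bad$repeats$start), ]
  expect_error(extract_spacers(bad, contig), "overlap")
})

test_that("terminal degeneracy is flagged in transcription orientation", {
  set.seed(91)
  exact <- build_test_array(n_repeats = 5L)
  a <- detect_arrays(exact$contig)[[1]]
  expect_equal(unname(flag_terminal_degeneracy(a)), c(FALSE, FALSE))
  deg <- build_test_array(n_repeats = 5L, degenerate_last = TRUE)
  a2 <- detect_arrays(deg$contig)[[1]]
  expect_equal(flag_terminal_degeneracy(a2),
               c(five_prime = FALSE, three_prime = TRUE))
  # mirrored case: first repeat degenerate, leader on the right
  rc <- detect_arrays(revcomp(deg$contig))[[1]]
  rc$orientation <- "leader_right"
  expect_equal(flag_terminal_degeneracy(rc),
               c(five_prime = FALSE, three_prime = TRUE))
})

test_that("pfm columns are base frequencies summing to one", {
  m <- pfm_of("ACGT")
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(colSums(m)), rep(1, 4))
  expect_equal(unname(m["A", 1]), 1)
  m2 <- pfm_of(c("ACGT", "ACGA"))
  expect_equal(unname(m2["T", 4]), 0.5)
  expect_equal(unname(m2["A", 4]), 0.5)
  expect_error(pfm_of(c("AC", "ACG")), "equal length")
  # majority oracle: modal base per column of 390 lightly mutated repeats
  set.seed(17)
  base <- gsub("W", "A", crispr_repeat1())
  variants <- vapply(1:390, function(i)
    crispratlas:::mutate_seq(base, 0.01)$seq, "")
  M <- pfm_of(variants)
  modal <- rownames(M)[apply(M, 2, which.max)]
  expect_equal(paste(modal, collapse = ""), base)
})

test_that("palindromicity matches the exhaustive pairing oracle", {
  expect_equal(palindromicity("AAAAAAAAAA"), 0)
  expect_equal(palindromicity("GGGGGAAAACCCCC"), 5 / 7)
  expect_error(palindromicity("ACGTACG"), "shorter")
  set.seed(19)
  for (i in 1:8) {
    s <- crispratlas:::random_seq(sample(10:14, 1))
    expect_equal(palindromicity(s),
                 oracle_max_pairs(s) / (nchar(s) %/% 2),
                 info = s)
    expect_equal(palindromicity(s), palindromicity(revcomp(s)), info = s)
  }
  # the two printed repeats are partially palindromic
  expect_gt(palindromicity(gsub("W", "A", crispr_repeat1())), 0.4)
  expect_gt(palindromicity(crispr_repeat2()), 0.4)
})
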