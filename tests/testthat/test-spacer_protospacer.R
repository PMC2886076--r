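mk_spacers <- function(seqs, genomes, loci = "CRISPR1",
                       arrays = paste0(genomes, ".a1"),
                       idx = seq_along(seqs) - 1L) {
  out <- data.frame(spacer_id = character(0), genome_id = character(0),
                    locus = character(0), array_id = character(0),
                    index_from_leader = integer(0), seq = character(0),
                    stringsAsFactors = FALSE)
  if (!length(seqs)) return(out)
  data.frame(spacer_id = paste0("sp", seq_along(seqs)),
             genome_id = as.character(genomes),
             locus = rep_len(as.character(loci), length(seqs)),
             array_id = as.character(arrays),
             index_from_leader = idx,
             seq = as.character(seqs), stringsAsFactors = FALSE)
}

test_that("clustering is strand-normalised, exact, and group-deduplicated", {
  set.seed(111)
  s1 <- crispratlas:::random_seq(32)
  s2 <- crispratlas:::random_seq(32)
  # all unique -> all singleton
  cl <- cluster_spacers(mk_spacers(c(s1, s2), c("gA", "gB")))
  expect_true(all(cl$clusters$is_singleton))
  # one spacer in 3 genomes of 3 groups -> one non-singleton cluster
  cl2 <- cluster_spacers(mk_spacers(rep(s1, 3), c("gA", "gB", "gC")))
  expect_equal(nrow(cl2$clusters), 1)
  expect_false(cl2$clusters$is_singleton)
  # reverse complement collapses into the same cluster
  cl3 <- cluster_spacers(mk_spacers(c(s1, revcomp(s1)), c("gA", "gB")))
  expect_equal(nrow(cl3$clusters), 1)
  # two genomes in one close group sharing spacers stay singleton
  groups <- data.frame(genome_id = c("gA", "gB"), group_id = c(1L, 1L))
  cl4 <- cluster_spacers(mk_spacers(rep(s1, 2), c("gA", "gB")), groups)
  expect_true(cl4$clusters$is_singleton)
})

test_that("atlas statistics agree with independent truth-ledger bookkeeping", {
  w <- small_world()
  sp <- small_spacer_table()
  cl <- cluster_spacers(sp, w$truth$groups)
  atlas <- atlas_stats(cl)
  # independent bookkeeping from the truth ledger (representative genomes;
  # the IS-split spacer is not part of the atlas)
  tr <- w$truth$spacers
  tr <- tr[tr$genome_id != "g06" & !tr$split_by_is, ]
  key <- ifelse(tr$seq <= vapply(tr$seq, revcomp, ""), tr$seq,
                vapply(tr$seq, revcomp, ""))
  for (locus in unique(tr$locus)) {
    sel <- tr$locus == locus
    row <- atlas[atlas$locus == locus, ]
    expect_equal(row$n_spacers, sum(sel), info = locus)
    expect_equal(row$n_distinct, length(unique(key[sel])), info = locus)
    occ <- table(key)[unique(key[sel])]
    expect_equal(row$n_singleton, sum(occ == 1), info = locus)
  }
  tot <- atlas[atlas$locus == "Total", ]
  expect_equal(tot$n_spacers, nrow(tr))
  expect_equal(tot$singleton_pct,
               pct_int(sum(table(key) == 1), length(unique(key))))
  # zero spacers -> empty atlas
  empty <- cluster_spacers(mk_spacers(character(0), character(0)))
  expect_equal(nrow(atlas_stats(empty)), 1)    # Total row only
  expect_equal(atlas_stats(empty)$n_spacers, 0)
})

test_that("leader-end acquisition gives a negative polarity statistic; uniform does not", {
  w <- small_world()
  cl <- cluster_spacers(small_spacer_table(), w$truth$groups)
  pol <- polarity_profile(cl, n_perm = 499, seed = 5)
  expect_lt(pol$stat, 0)
  expect_lt(pol$stat, pol$null_lo)
  # single-genome world: every spacer is a singleton, statistic undefined
  one <- cluster_spacers(mk_spacers(
    vapply(1:4, function(i) crispratlas:::random_seq(32), ""), "gA",
    idx = 0:3))
  expect_true(is.na(polarity_profile(one)$stat))
})

test_that("duplications are classified within and between arrays", {
  s <- crispratlas:::random_seq(32)
  m <- mk_spacers(c(s, s, crispratlas:::random_seq(32)),
                  genomes = c("gA", "gA", "gA"),
                  arrays = c("a1", "a1", "a2"), idx = c(0L, 3L, 0L))
  d <- detect_duplications(cluster_spacers(m))
  expect_equal(d$kind, "within_array")
  m2 <- mk_spacers(c(s, s), genomes = c("gA", "gA"),
                   loci = c("CRISPR1", "CRISPR2"), arrays = c("a1", "a2"))
  d2 <- detect_duplications(cluster_spacers(m2))
  expect_equal(d2$kind, "between_arrays")
  m3 <- mk_spacers(c(s, crispratlas:::random_seq(32)), c("gA", "gA"),
                   arrays = c("a1", "a1"))
  expect_equal(nrow(detect_duplications(cluster_spacers(m3))), 0)
})

test_that("proto-spacer search equals the exhaustive window oracle", {
  set.seed(121)
  el_seq <- crispratlas:::random_seq(5000)
  sp0 <- substr(el_seq, 1001, 1032)                      # verbatim
  sp1 <- crispratlas:::substitute_at(substr(el_seq, 2001, 2032), 10)
  sp2 <- crispratlas:::substitute_at(substr(el_seq, 3001, 3032), c(5, 20))
  sp_rc <- revcomp(substr(el_seq, 4001, 4032))           # minus strand
  spacers <- mk_spacers(c(sp0, sp1, sp2, sp_rc), "gA")
  el <- new_mobile_element("e1", el_seq, "phage")
  hits <- search_protospacers(spacers, list(el))
  # verbatim -> 0 mismatches at the planted site
  h0 <- hits[hits$spacer_id == "sp1", ]
  expect_true(any(h0$start == 1000 & h0$mismatches == 0))
  # 1 mismatch (31/32 = 0.969 > 0.95) -> hit
  expect_true(any(hits$spacer_id == "sp2" & hits$start == 2000 &
                    hits$mismatches == 1))
  # 2 mismatches (0.9375) -> never a hit
  expect_false(any(hits$spacer_id == "sp3"))
  # minus-strand hit recovered
  expect_true(any(hits$spacer_id == "sp4" & hits$strand == "-" &
                    hits$start == 4000))
  # full agreement with the exhaustive oracle, per spacer
  for (i in seq_len(nrow(spacers))) {
    oh <- oracle_protospacers(spacers$seq[i], el_seq)
    ih <- hits[hits$spacer_id == spacers$spacer_id[i], ]
    expect_equal(nrow(ih), nrow(oh), info = spacers$spacer_id[i])
    if (nrow(oh)) {
      expect_setequal(paste(ih$start, ih$strand, ih$mismatches),
                      paste(oh$start, oh$strand, oh$mismatches))
    }
  }
})

test_that("searching a reverse-complemented element mirrors the hits", {
  set.seed(122)
  el_seq <- crispratlas:::random_seq(3000)
  sp <- substr(el_seq, 501, 532)
  spacers <- mk_spacers(sp, "gA")
  h_f <- search_protospacers(spacers, list(new_mobile_element("e", el_seq,
                                                              "phage")))
  h_r <- search_protospacers(spacers,
                             list(new_mobile_element("e", revcomp(el_seq),
                                                     "phage")))
  expect_equal(nrow(h_f), nrow(h_r))
  expect_setequal(3000 - h_f$end, h_r$start)
  expect_true(all(h_r$strand != h_f$strand[match(3000 - h_f$end, h_r$start)]))
})

test_that("hits inside the querying arrays are excluded (self-array rule)", {
  set.seed(123)
  chrom <- crispratlas:::random_seq(4000)
  sp <- substr(chrom, 1001, 1032)
  spacers <- mk_spacers(sp, "gA")
  el <- new_mobile_element("gA.chr", chrom, "chromosome", owner_genome = "gA")
  free <- search_protospacers(spacers, list(el))
  expect_true(any(free$start == 1000))
  excl <- search_protospacers(spacers, list(el),
                              exclude_spans = data.frame(
                                element_id = "gA.chr", start = 900L,
                                end = 1100L))
  expect_false(any(excl$start == 1000))
})

test_that("hit classification uses element class, prophage and cas spans", {
  set.seed(124)
  hits <- data.frame(spacer_id = "s", genome_id = "gA",
                     element_id = c("ph1", "pl1", "chr", "chr", "chr"),
                     start = c(10L, 10L, 100L, 5000L, 9000L),
                     end = c(42L, 42L, 132L, 5032L, 9032L),
                     strand = "+", mismatches = 0L, identity = 1,
                     stringsAsFactors = FALSE)
  els <- list(new_mobile_element("ph1", crispratlas:::random_seq(100), "phage"),
              new_mobile_element("pl1", crispratlas:::random_seq(100), "plasmid"),
              new_mobile_element("chr", crispratlas:::random_seq(10000),
                                 "chromosome"))
  out <- classify_hits(hits, els,
                       prophage_spans = data.frame(element_id = "chr",
                                                   start = 4000L, end = 6000L),
                       cas_spans = data.frame(element_id = "chr",
                                              start = 8900L, end = 9500L))
  expect_equal(out$target_class,
               c("phage", "plasmid", "chromosome", "prophage", "cas"))
})

test_that("genic context and coding-strand fractions are computed per hit", {
  genes <- data.frame(gene_id = "g1", contig_id = "e1", start = 100L,
                      end = 200L, strand = "+", type = "CDS", product = "p",
                      protein = NA_character_, stringsAsFactors = FALSE)
  hits <- data.frame(spacer_id = c("a", "b", "c"), genome_id = "gA",
                     element_id = "e1", start = c(150L, 150L, 300L),
                     end = c(182L, 182L, 332L), strand = c("+", "-", "+"),
                     mismatches = 0L, identity = 1, stringsAsFactors = FALSE)
  ctx <- context_stats(hits, genes)
  expect_equal(ctx$hits$context, c("genic", "genic", "intergenic"))
  expect_equal(ctx$genic_fraction, 2 / 3)
  expect_equal(ctx$coding_strand_fraction, 1 / 2)
  # intergenic-only input
  ctx0 <- context_stats(hits[3, ], genes)
  expect_equal(ctx0$genic_fraction, 0)
})

test_that("hit spans measure the clustered extent on a target", {
  h1 <- data.frame(start = 100L, end = 132L)
  expect_equal(hit_span(h1), 32L)
  h2 <- data.frame(start = c(100L, 2900L), end = c(132L, 2932L))
  expect_equal(hit_span(h2), 2832L)
  expect_equal(hit_span(h2[2:1, ]), hit_span(h2))   # order invariance
  expect_error(hit_span(h2[0, ]), "no hits")
})

test_that("self-targeting hits are separated by element ownership", {
  hits <- data.frame(spacer_id = c("a", "b"), genome_id = c("gA", "gA"),
                     element_id = c("plA", "plB"), start = 0L, end = 32L,
                     strand = "+", mismatches = 0L, identity = 1,
                     stringsAsFactors = FALSE)
  own <- data.frame(element_id = c("plA", "plB"),
                    owner_genome = c("gA", "gB"), stringsAsFactors = FALSE)
  st <- self_targets(hits, own)
  expect_equal(st$spacer_id, "a")
  own2 <- data.frame(element_id = c("plA", "plB"),
                     owner_genome = c("gB", "gB"), stringsAsFactors = FALSE)
  expect_equal(nrow(self_targets(hits, own2)), 0)
})

test_that("planted self-targets are recovered in the synthetic world", {
  w <- small_world()
  sp <- w$truth$spacers
  # genome 2 carries a spacer drawn from the prophage donor element
  self_sp <- sp[sp$genome_id == "g02" & sp$source_kind == "element" &
                  sp$source_id == w$elements[[1]]$element_id, ]
  expect_gte(nrow(self_sp), 1)
  g2 <- w$genomes[[2]]
  expect_true(any(g2$element_spans$class == "prophage"))
})

test_that("anti-CRISPR flags require the cognate operon to be missing", {
  w <- small_world()
  ops <- do.call(rbind, lapply(c("g01", "g05"), function(id)
    data.frame(genome_id = id, subtype = c("Ecoli", "Ypest"),
               status = c("complete", if (id == "g05") "complete" else "absent"),
               stringsAsFactors = FALSE)))
  sp <- small_spacer_table()
  sp <- sp[sp$genome_id %in% c("g01", "g05"), ]
  flags <- detect_anti_crispr(sp, default_cas_refs(), ops)
  # g01 lacks Ypest -> flagged; g05 carries intact Ypest -> conflict, unflagged
  f1 <- flags[flags$genome_id == "g01" & flags$subtype == "Ypest", ]
  expect_true(nrow(f1) == 1 && f1$flagged)
  expect_equal(f1$locus, "CRISPR3")
  f5 <- flags[flags$genome_id == "g05", ]
  expect_true(all(!f5$flagged))
  # no cas-matching spacers anywhere -> empty
  none <- mk_spacers(crispratlas:::random_seq(32), "gX")
  expect_equal(nrow(detect_anti_crispr(none, default_cas_refs(),
                                       ops[ops$genome_id == "g01", ])), 0)
})
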