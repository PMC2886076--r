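# small hand-made genomes for orthology unit tests
make_protein_genome <- function(id, prots, contig_len = 4000L,
                                order = seq_along(prots)) {
  n <- length(prots)
  starts <- seq(100L, by = 300L, length.out = n)
  genes <- data.frame(
    gene_id = paste0(id, ".", names(prots)[order]),
    contig_id = "c1",
    start = starts, end = starts + 150L, strand = "+", type = "CDS",
    product = names(prots)[order], protein = unname(prots[order]),
    stringsAsFactors = FALSE)
  new_genome(id, c(c1 = crispratlas:::random_seq(contig_len)), genes = genes)
}

mutate_protein <- function(p, k) {
  aa <- strsplit(p, "")[[1]]
  pos <- sample(length(aa), k)
  for (i in pos) aa[i] <- sample(setdiff(crispratlas:::.AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

test_that("identical gene sets pair one-to-one at similarity 1", {
  set.seed(61)
  prots <- stats::setNames(vapply(1:5, function(i)
    paste(sample(crispratlas:::.AA20, 120, TRUE), collapse = ""),
    ""), paste0("p", 1:5))
  ga <- make_protein_genome("A", prots)
  gb <- make_protein_genome("B", prots)
  p <- rbh_orthologs(ga, gb)
  expect_equal(nrow(p), 5)
  expect_true(all(p$similarity == 1))
  expect_true(all(p$length_diff == 0))
  # symmetry: swapping arguments mirrors the pair set
  q <- rbh_orthologs(gb, ga)
  expect_setequal(paste(p$gene_a, p$gene_b), paste(q$gene_b, q$gene_a))
})

test_that("RBH pairs equal the exhaustive alignment oracle on a toy set", {
  set.seed(62)
  base <- stats::setNames(vapply(1:8, function(i)
    paste(sample(crispratlas:::.AA20, sample(100:200, 1), TRUE),
          collapse = ""), ""), paste0("p", 1:8))
  mut <- stats::setNames(vapply(base, function(p)
    mutate_protein(p, 6L), ""), names(base))
  ga <- make_protein_genome("A", base)
  gb <- make_protein_genome("B", mut, order = sample(8))
  pairs <- rbh_orthologs(ga, gb)
  # oracle: all-vs-all global alignment scores, reciprocal maxima
  S <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    S[i, j] <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ga$genes$protein[i]),
      Biostrings::AAString(gb$genes$protein[j]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
  expected <- list()
  for (i in 1:8) {
    j <- which.max(S[i, ])
    if (which.max(S[, j]) == i)
      expected[[length(expected) + 1]] <- paste(ga$genes$gene_id[i],
                                                gb$genes$gene_id[j])
  }
  expect_setequal(paste(pairs$gene_a, pairs$gene_b), unlist(expected))
})

test_that("pairs breaching the 20% length-difference rule are excluded", {
  set.seed(63)
  p <- paste(sample(crispratlas:::.AA20, 150, TRUE), collapse = "")
  long <- paste0(p, paste(sample(crispratlas:::.AA20, 50, TRUE), collapse = ""))
  ga <- make_protein_genome("A", c(x = p))
  gb <- make_protein_genome("B", c(x = long))
  expect_equal(nrow(rbh_orthologs(ga, gb)), 0)   # ld = 0.25
  gc_ <- make_protein_genome("C", c(x = mutate_protein(p, 5L)))
  expect_equal(nrow(rbh_orthologs(ga, gc_)), 1)
})

test_that("synteny refinement keeps collinear genomes and drops shuffled isolates", {
  set.seed(64)
  prots <- stats::setNames(vapply(1:10, function(i)
    paste(sample(crispratlas:::.AA20, 130, TRUE), collapse = ""), ""),
    paste0("p", 1:10))
  ga <- make_protein_genome("A", prots)
  gb <- make_protein_genome("B", vapply(prots, mutate_protein, "", k = 4L))
  p0 <- rbh_orthologs(ga, gb)
  expect_equal(nrow(synteny_refine(p0, ga, gb)), nrow(p0))
  # an isolated weak pair placed outside any conserved block
  weak <- paste(sample(crispratlas:::.AA20, 130, TRUE), collapse = "")
  weak_b <- mutate_protein(weak, 45L)   # low similarity, still reciprocal
  ga2 <- make_protein_genome("A2", c(prots[1:5], w = weak, prots[6:10][-5]))
  gb2 <- make_protein_genome("B2", c(w = weak_b, prots[c(6, 7, 8, 9)],
                                     prots[1:5]))
  gb2$genes$protein[1] <- weak_b
  p2 <- rbh_orthologs(ga2, gb2, min_similarity = 0.3)
  ref <- synteny_refine(p2, ga2, gb2)
  expect_true(all(paste(ref$gene_a, ref$gene_b) %in%
                    paste(p2$gene_a, p2$gene_b)))   # subset property
  expect_false(any(ref$gene_a == "A2.w"))
})

test_that("core families recover the planted core of a synthetic world", {
  w <- small_world()
  core <- cached("small_core", function() core_genome(w$genomes))
  per_family <- table(core$family_id)
  expect_true(all(per_family == length(w$genomes)))
  planted_core <- c("cysD", "cysJ", "ygcF", "clpS", "infA", "aat",
                    paste0("fill", 1:8))
  expect_setequal(unique(core$product), planted_core)
})

test_that("core size shrinks when a gene is deleted from one genome", {
  set.seed(65)
  prots <- stats::setNames(vapply(1:6, function(i)
    paste(sample(crispratlas:::.AA20, 110, TRUE), collapse = ""), ""),
    paste0("p", 1:6))
  gs <- lapply(c("A", "B", "C"), function(id)
    make_protein_genome(id, prots))
  core_full <- core_genome(gs)
  expect_equal(length(unique(core_full$family_id)), 6)
  gs2 <- gs
  gs2[[3]]$genes <- gs2[[3]]$genes[-2, ]           # delete p2 from genome C
  core_del <- core_genome(gs2)
  expect_equal(length(unique(core_del$family_id)), 5)
  expect_false(any(core_del$product == "p2"))
})

test_that("arrays anchor to the named loci by their flanking core genes", {
  w <- small_world()
  det <- small_detected()
  core <- cached("small_core", function() core_genome(w$genomes))
  tr <- w$truth$arrays
  for (i in seq_along(w$genomes)) {
    g <- w$genomes[[i]]
    ta <- tr[tr$genome_id == g$genome_id, ]
    for (a in det[[i]]) {
      hit <- ta[ta$start <= a$start & ta$end >= a$end, ]
      if (!nrow(hit)) next
      expect_equal(anchor_locus(a, g, core), hit$locus[1],
                   info = paste(g$genome_id, hit$locus[1]))
    }
  }
  # an array in a random intergenic region stays unanchored
  set.seed(66)
  tb <- build_test_array(n_repeats = 4L)
  g1 <- w$genomes[[1]]
  fake <- detect_arrays(tb$contig, contig_id = names(g1$contigs)[1])[[1]]
  fake$start <- 120000; fake$end <- 120300
  fake$contig_id <- names(g1$contigs)[1]
  expect_equal(anchor_locus(fake, g1, core), "unanchored")
})

test_that("anchoring is invariant under contig reverse-complementation", {
  w <- small_world()
  g <- w$genomes[[1]]
  core <- cached("small_core", function() core_genome(w$genomes))
  a <- small_detected()[[1]][[1]]
  lab <- anchor_locus(a, g, core)
  grc <- rc_genome(g)
  n <- nchar(g$contigs[[a$contig_id]])
  arc <- a
  arc$start <- n - a$end
  arc$end <- n - a$start
  expect_equal(anchor_locus(arc, grc, core), lab)
})

test_that("the conserved AT-rich flank is identified as the leader", {
  w <- small_world()
  det <- small_detected()
  core <- cached("small_core", function() core_genome(w$genomes))
  la <- list()
  for (i in seq_along(w$genomes)) {
    for (a in det[[i]]) {
      if (anchor_locus(a, w$genomes[[i]], core) == "CRISPR1")
        la[[length(la) + 1]] <- list(genome = w$genomes[[i]], array = a)
    }
  }
  expect_gte(length(la), 2)
  fl <- find_leader(la)
  expect_equal(fl$side, "left")
  expect_equal(fl$orientation, "leader_left")
  expect_true(fl$significant)
  # conservation across genomes exceeds the 70% identity floor
  expect_gte(unname(fl$conservation["left"]), 0.70)
  # reported AT fraction recovers the configured leader AT content
  expect_lt(abs(mean(fl$leaders$at_fraction) - 0.7), 0.05)
  # a single genome cannot reach significance
  f1 <- find_leader(la[1])
  expect_false(f1$significant)
  # independently random flanks on both sides give no significant leader
  set.seed(67)
  fake <- lapply(1:3, function(i) {
    tb <- build_test_array(n_repeats = 4L, pad = 500L)
    g <- new_genome(paste0("r", i), c(c1 = tb$contig))
    arr <- detect_arrays(tb$contig, contig_id = "c1")[[1]]
    list(genome = g, array = arr)
  })
  expect_false(find_leader(fake)$significant)
})
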