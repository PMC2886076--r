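test_that("same seed gives byte-identical worlds", {
  cfg <- world_config(n_genomes = 3L, genome_length = 130000L, seed = 5L,
                      pool = small_pool())
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  for (i in seq_along(w1$genomes)) {
    expect_identical(w1$genomes[[i]]$contigs, w2$genomes[[i]]$contigs)
    expect_identical(w1$genomes[[i]]$genes, w2$genomes[[i]]$genes)
  }
  expect_identical(w1$truth$spacers, w2$truth$spacers)
  expect_identical(lapply(w1$elements, `[[`, "seq"),
                   lapply(w2$elements, `[[`, "seq"))
})

test_that("planted spans reconstruct exactly from the truth ledger", {
  w <- small_world()
  tr <- w$truth$arrays
  sp <- w$truth$spacers
  for (r in seq_len(nrow(tr))) {
    g <- w$genomes[[match(tr$genome_id[r], vapply(w$genomes, `[[`, "",
                                                  "genome_id"))]]
    contig <- g$contigs[[tr$contig_id[r]]]
    L <- tr$repeat_len[r]
    rs <- tr$repeat_starts[[r]]
    expect_length(rs, tr$n_repeats[r])
    # every non-terminal repeat is an exact copy of the array's repeat base
    reps <- substring(contig, rs + 1, rs + L)
    expect_true(all(reps[-length(reps)] == tr$repeat_base[r]))
    if (!tr$degenerate_3p[r])
      expect_equal(reps[length(reps)], tr$repeat_base[r])
    # spacers in the ledger equal the genomic substrings (the spacer split
    # by an IS insertion spans the insert and is flagged instead)
    ss <- sp[sp$genome_id == tr$genome_id[r] & sp$locus == tr$locus[r], ]
    whole <- ss[!ss$split_by_is, ]
    expect_equal(substring(contig, whole$start + 1, whole$end), whole$seq)
    # repeats-vs-spacers bookkeeping: |spacers| = |repeats| - 1
    expect_equal(nrow(ss), tr$n_repeats[r] - 1L)
  }
})

test_that("spacer lengths concentrate near 32 bp and provenance is valid", {
  w <- small_world()
  sp <- w$truth$spacers
  expect_true(all(nchar(sp$seq) >= 28 & nchar(sp$seq) <= 36))
  expect_lt(abs(mean(nchar(sp$seq)) - 32), 1.5)
  prov <- sp[sp$source_kind == "element" & sp$n_mut == 0, ]
  expect_gt(nrow(prov), 0)
  pool <- stats::setNames(lapply(w$elements, `[[`, "seq"),
                          vapply(w$elements, `[[`, "", "element_id"))
  for (r in seq_len(nrow(prov))) {
    src <- substr(pool[[prov$source_id[r]]], prov$source_start[r] + 1,
                  prov$source_start[r] + nchar(prov$seq[r]))
    if (prov$source_strand[r] == "-") src <- revcomp(src)
    expect_equal(prov$seq[r], src)
  }
})

test_that("IS insertion splits an array and is recorded in the truth", {
  w <- small_world()
  tr <- w$truth$arrays
  dis <- tr[tr$is_disrupted, ]
  expect_equal(nrow(dis), 1)
  expect_equal(dis$locus, "CRISPR2")
  expect_false(is.na(dis$is_start))
  runs <- truth_runs(dis[1, ])
  expect_length(runs, 2)
  # the IS span is labelled in the genome's element spans
  g <- w$genomes[[match(dis$genome_id, vapply(w$genomes, `[[`, "",
                                              "genome_id"))]]
  es <- g$element_spans
  expect_true(any(es$class == "IS" & es$start == dis$is_start))
})

test_that("a bare world contains no detectable tandem-repeat structure", {
  bare <- replicate(2, list(loci = character(0)), simplify = FALSE)
  cfg <- world_config(n_genomes = 2L, genome_length = 60000L, seed = 9L,
                      pool = small_pool(), genome_specs = bare)
  w <- generate_world(cfg)
  expect_null(w$truth$arrays)
  for (g in w$genomes) expect_length(detect_genome_arrays(g), 0)
})

test_that("too small a genome raises a capacity error", {
  cfg <- world_config(n_genomes = 1L, genome_length = 20000L, seed = 2L,
                      pool = small_pool(),
                      genome_specs = list(list(
                        loci = c("CRISPR1", "CRISPR2", "CRISPR3"),
                        cas = list(subtype = "Ecoli", state = "intact"),
                        anti3 = FALSE)))
  expect_error(generate_world(cfg), "genome_length too small")
})

test_that("evolve_strain plants substitutions at the requested density", {
  set.seed(71)
  g <- new_genome("anc", c(chr = crispratlas:::random_seq(5000000)))
  expect_error(evolve_strain(g, 0.2), "out of")
  same <- evolve_strain(g, 0, seed = 4)
  expect_identical(same$contigs, g$contigs)
  ev <- evolve_strain(g, 2e-4, seed = 4)
  mism <- sum(strsplit(ev$contigs[[1]], "")[[1]] !=
                strsplit(g$contigs[[1]], "")[[1]])
  ci <- stats::qbinom(c(0.005, 0.995), 5000000, 2e-4)
  expect_gte(mism, ci[1])
  expect_lte(mism, ci[2])
  # excluded spans stay untouched
  ex <- data.frame(contig_id = "chr", start = 0L, end = 10000L)
  ev2 <- evolve_strain(g, 5e-3, seed = 6, exclude_spans = ex)
  expect_identical(substr(ev2$contigs[[1]], 1, 10000),
                   substr(g$contigs[[1]], 1, 10000))
})

test_that("pairs at 1e-4 group at the 0.02% threshold; pairs at 1e-3 do not", {
  set.seed(81)
  anc <- new_genome("anc", c(chr = crispratlas:::random_seq(1000000)))
  near <- evolve_strain(anc, 1e-4, seed = 10); near$genome_id <- "near"
  names(near$contigs) <- "chr"
  far <- evolve_strain(anc, 1e-3, seed = 11); far$genome_id <- "far"
  D <- distance_matrix(list(anc, near, far))
  gr <- group_close_strains(D, threshold = 2e-4)
  expect_equal(gr$group_id[gr$genome_id == "anc"],
               gr$group_id[gr$genome_id == "near"])
  expect_false(gr$group_id[gr$genome_id == "far"] ==
                 gr$group_id[gr$genome_id == "anc"])
})

test_that("the default world records clone groups and anti-CRISPR truth", {
  w <- small_world()
  gr <- w$truth$groups
  expect_equal(gr$group_id[gr$genome_id == "g06"],
               gr$group_id[gr$genome_id == "g01"])
  expect_equal(length(unique(gr$group_id)), 5)
  expect_equal(sort(w$truth$anti$genome_id[w$truth$anti$flagged]),
               c("g01", "g02", "g03", "g04", "g06"))
  # anti spacers point into Ypest cas coding sequences
  anti_sp <- w$truth$spacers[w$truth$spacers$source_kind == "cas", ]
  expect_gt(nrow(anti_sp), 0)
  expect_true(all(grepl("^Ypest\\|", anti_sp$source_id)))
  # clones carry identical arrays (mutations excluded there)
  sp <- w$truth$spacers
  expect_equal(sp$seq[sp$genome_id == "g06"], sp$seq[sp$genome_id == "g01"])
})

test_that("plant_anti_crispr converts spacers and removes the cognate operon", {
  cfg <- world_config(
    n_genomes = 1L, genome_length = 120000L, seed = 31L, pool = small_pool(),
    genome_specs = list(list(loci = c("CRISPR3", "CRISPR4"),
                             cas = list(subtype = "Ypest", state = "intact"),
                             anti3 = FALSE)))
  w <- generate_world(cfg)
  g <- w$genomes[[1]]
  expect_true(any(grepl("^Ypest ", g$genes$product)))
  g0 <- plant_anti_crispr(g, k = 0L, seed = 3L)
  expect_false(any(grepl("^Ypest ", g0$genes$product)))
  expect_lt(nchar(g0$contigs[[1]]), nchar(g$contigs[[1]]))
  g2 <- plant_anti_crispr(g, k = 2L, seed = 3L)
  tr <- attr(g2, "anti_truth")
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$gene_name %in% cas_subtype_genes("Ypest")))
  # end-to-end: the modified genome is flagged by detect_anti_crispr
  arrs <- detect_genome_arrays(g2)
  sp <- do.call(rbind, lapply(arrs, function(a) {
    a <- extract_spacers(a, g2$contigs[[a$contig_id]])
    if (!nrow(a$spacers)) return(NULL)
    data.frame(spacer_id = paste0(a$array_id, ".", seq_len(nrow(a$spacers))),
               genome_id = g2$genome_id, locus = anchor_locus(a, g2),
               seq = a$spacers$seq, stringsAsFactors = FALSE)
  }))
  ops <- data.frame(genome_id = g2$genome_id, subtype = c("Ecoli", "Ypest"),
                    status = "absent", stringsAsFactors = FALSE)
  flags <- detect_anti_crispr(sp, default_cas_refs(), ops)
  expect_true(any(flags$flagged & flags$genome_id == g2$genome_id))
  # a genome without a CRISPR3 array is a precondition error
  bare <- generate_world(world_config(
    n_genomes = 1L, genome_length = 60000L, seed = 32L, pool = small_pool(),
    genome_specs = list(list(loci = character(0)))))$genomes[[1]]
  expect_error(plant_anti_crispr(bare, k = 1L), "CRISPR3|anchors")
})
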