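# End-to-end orchestration: detect -> anchor -> leader -> cas -> atlas ->
# proto-spacer -> evolution statistics, with deterministic TSV outputs.

#' Pipeline configuration
#'
#' Exactly one of `world` (a [world_config()] for synthetic input) or
#' `input_dir` (a directory holding `*.fna` + `*.gff3` genomes,
#' `elements.fna` + `elements.tsv`) must be given.
#'
#' @param world a [world_config()] or NULL
#' @param input_dir input directory or NULL
#' @param out_dir optional output directory for [write_tables()]
#' @param seed integer seed
#' @param params [detector_params()]
#' @param cas_refs cas reference table
#' @param group_threshold closely-related grouping distance
#' @param flank_len leader flank length (bp)
#' @param allow_relic anti-CRISPR: treat relic operons as absent
#' @return configuration list
#' @export
pipeline_config <- function(world = NULL, input_dir = NULL, out_dir = NULL,
                            seed = 1L, params = detector_params(),
                            cas_refs = default_cas_refs(),
                            group_threshold = 2e-4, flank_len = 120L,
                            allow_relic = FALSE) {
  if (is.null(world) == is.null(input_dir))
    stop("pipeline_config: give exactly one of world / input_dir")
  list(world = world, input_dir = input_dir, out_dir = out_dir,
       seed = as.integer(seed), params = params, cas_refs = cas_refs,
       group_threshold = group_threshold, flank_len = as.integer(flank_len),
       allow_relic = allow_relic)
}

#' @keywords internal
load_input_dir <- function(dir) {
  fnas <- sort(list.files(dir, pattern = "\\.fna$", full.names = TRUE))
  fnas <- fnas[basename(fnas) != "elements.fna"]
  if (!length(fnas)) stop("input stage: no genome FASTA files in ", dir)
  genomes <- lapply(fnas, function(f) {
    gff <- sub("\\.fna$", ".gff3", f)
    load_genome(f, if (file.exists(gff)) gff else NULL)
  })
  efa <- file.path(dir, "elements.fna")
  elements <- if (file.exists(efa))
    load_elements(efa, file.path(dir, "elements.tsv")) else list()
  list(genomes = genomes, elements = elements, truth = NULL)
}

#' Run the full pipeline
#'
#' Stages: input (synthesis or loading), array detection, locus anchoring,
#' leader identification and orientation, cas annotation, strain grouping,
#' spacer atlas, proto-spacer search and classification, anti-CRISPR
#' detection, and divergence statistics.  With `out_dir` set in the
#' configuration, the report bundle is also written as TSV tables.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress per-stage log lines
#' @return report bundle (list); see [write_tables()] for the table set
#' @export
run_all <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[crispratlas] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  inp <- stage("input", {
    if (!is.null(config$world)) {
      w <- generate_world(config$world)
      list(genomes = w$genomes, elements = w$elements, truth = w$truth)
    } else load_input_dir(config$input_dir)
  })
  genomes <- inp$genomes
  ids <- vapply(genomes, `[[`, "", "genome_id")
  say("input: ", length(genomes), " genomes, ", length(inp$elements),
      " pool elements")

  arrays <- stage("detect", {
    a <- lapply(genomes, detect_genome_arrays, params = config$params)
    names(a) <- ids
    a
  })
  say("detect: ", sum(lengths(arrays)), " arrays")

  core <- stage("orthology", core_genome(genomes))

  arrays <- stage("anchor", {
    for (i in seq_along(genomes)) {
      for (j in seq_along(arrays[[i]])) {
        arrays[[i]][[j]]$locus <-
          anchor_locus(arrays[[i]][[j]], genomes[[i]], core)
      }
    }
    arrays
  })

  leaders <- stage("leader", {
    out <- list()
    for (locus in c("CRISPR1", "CRISPR2", "CRISPR3", "CRISPR4")) {
      la <- list()
      for (i in seq_along(genomes)) {
        for (j in seq_along(arrays[[i]])) {
          if (identical(arrays[[i]][[j]]$locus, locus))
            la[[length(la) + 1L]] <- list(genome = genomes[[i]],
                                          array = arrays[[i]][[j]],
                                          gi = i, ai = j)
        }
      }
      if (!length(la)) next
      fl <- find_leader(la, flank_len = config$flank_len)
      for (k in seq_along(la)) {
        arrays[[la[[k]]$gi]][[la[[k]]$ai]]$orientation <- fl$orientation
      }
      fl$leaders$locus <- locus
      out[[locus]] <- fl$leaders
    }
    out
  })
  leader_table <- if (length(leaders)) {
    lt <- do.call(rbind, leaders)
    lt[, c("genome_id", "locus", "side", "start", "end", "at_fraction",
           "conservation", "significant")]
  } else empty_leader_table()

  # spacers (post-orientation) and terminal degeneracy
  spacer_table <- stage("spacers", {
    rows <- list()
    for (i in seq_along(genomes)) {
      for (j in seq_along(arrays[[i]])) {
        a <- extract_spacers(arrays[[i]][[j]],
                             genomes[[i]]$contigs[[arrays[[i]][[j]]$contig_id]],
                             config$params)
        deg <- flag_terminal_degeneracy(a)
        a$flags$terminal_3prime_degenerate <- unname(deg["three_prime"])
        arrays[[i]][[j]] <- a
        if (nrow(a$spacers))
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = paste0(a$array_id, ".sp", seq_len(nrow(a$spacers))),
            genome_id = ids[i], locus = a$locus, array_id = a$array_id,
            index_from_leader = a$spacers$index_from_leader,
            contig_id = a$contig_id,
            start = a$spacers$start, end = a$spacers$end,
            seq = a$spacers$seq, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(spacer_id = character(0), genome_id = character(0),
                 locus = character(0), array_id = character(0),
                 index_from_leader = integer(0), contig_id = character(0),
                 start = integer(0), end = integer(0), seq = character(0),
                 stringsAsFactors = FALSE)
  })
  say("spacers: ", nrow(spacer_table))

  cas <- stage("cas", {
    calls <- list(); operons <- list()
    for (i in seq_along(genomes)) {
      an <- annotate_cas(genomes[[i]], arrays[[i]], config$cas_refs)
      if (nrow(an$calls)) {
        an$calls$genome_id <- ids[i]
        calls[[length(calls) + 1L]] <- an$calls
      }
      operons[[length(operons) + 1L]] <- an$operons
    }
    list(calls = if (length(calls)) do.call(rbind, calls) else
      cbind(empty_cas_calls(), genome_id = character(0)),
      operons = do.call(rbind, operons))
  })
  say("cas: ", nrow(cas$calls), " gene calls")

  evo <- stage("evolution", {
    D <- distance_matrix(genomes, method = "genome")
    groups <- group_close_strains(D, config$group_threshold)
    est <- data.frame(pair = character(0), d = numeric(0),
                      years_clock = numeric(0),
                      generations_neutral = numeric(0),
                      years_neutral = numeric(0), stringsAsFactors = FALSE)
    nearby <- which(D < 0.01 & upper.tri(D), arr.ind = TRUE)
    if (nrow(nearby)) {
      est <- do.call(rbind, lapply(seq_len(nrow(nearby)), function(r) {
        i <- nearby[r, 1]; j <- nearby[r, 2]
        ng <- neutral_generations(D[i, j])
        data.frame(pair = paste(ids[i], ids[j], sep = "-"), d = D[i, j],
                   years_clock = clock_years(D[i, j]),
                   generations_neutral = ng$generations,
                   years_neutral = ng$years, stringsAsFactors = FALSE)
      }))
    }
    corr <- NULL
    n1 <- n2 <- rep(NA_integer_, length(genomes))
    for (i in seq_along(genomes)) {
      for (a in arrays[[i]]) {
        if (a$locus == "CRISPR1") n1[i] <- nrow(a$repeats)
        if (a$locus == "CRISPR2") n2[i] <- nrow(a$repeats)
      }
    }
    both <- !is.na(n1) & !is.na(n2)
    if (sum(both) >= 3L && stats::sd(n1[both]) > 0 && stats::sd(n2[both]) > 0)
      corr <- repeat_correlation(n1[both], n2[both], n_perm = 2000L,
                                 seed = config$seed)
    list(D = D, groups = groups, estimates = est, correlation = corr,
         repeat_counts = data.frame(genome_id = ids, CRISPR1 = n1,
                                    CRISPR2 = n2, stringsAsFactors = FALSE))
  })
  say("evolution: ", length(unique(evo$groups$group_id)), " strain groups")

  atlas <- stage("atlas", {
    cl <- cluster_spacers(spacer_table, evo$groups)
    dup <- detect_duplications(cl)
    pol <- polarity_profile(cl, n_perm = 499L, seed = config$seed)
    list(cl = cl, duplications = dup, polarity = pol)
  })

  hits_out <- stage("protospacer", {
    # search targets: the pool plus every genome's own chromosomes
    chrom <- list()
    for (g in genomes) {
      for (cid in names(g$contigs))
        chrom[[length(chrom) + 1L]] <-
          new_mobile_element(cid, g$contigs[[cid]], "chromosome",
                             genes = g$genes[g$genes$contig_id == cid, ,
                                             drop = FALSE],
                             owner_genome = g$genome_id)
    }
    targets <- c(inp$elements, chrom)
    # exclude the querying arrays themselves
    excl <- do.call(rbind, lapply(seq_along(genomes), function(i) {
      if (!length(arrays[[i]])) return(NULL)
      data.frame(element_id = vapply(arrays[[i]], `[[`, "", "contig_id"),
                 start = vapply(arrays[[i]], `[[`, numeric(1), "start"),
                 end = vapply(arrays[[i]], `[[`, numeric(1), "end"),
                 stringsAsFactors = FALSE)
    }))
    hits <- search_protospacers(spacer_table, targets,
                                exclude_spans = excl)
    proph <- do.call(rbind, lapply(genomes, function(g) {
      es <- g$element_spans
      if (!nrow(es)) return(NULL)
      es <- es[es$class == "prophage", , drop = FALSE]
      if (!nrow(es)) return(NULL)
      data.frame(element_id = es$contig_id, start = es$start, end = es$end,
                 stringsAsFactors = FALSE)
    }))
    cas_spans <- if (nrow(cas$calls))
      data.frame(element_id = cas$calls$contig_id, start = cas$calls$start,
                 end = cas$calls$end, stringsAsFactors = FALSE)
    else NULL
    hits <- classify_hits(hits, targets, prophage_spans = proph,
                          cas_spans = cas_spans)
    genes_all <- do.call(rbind, c(lapply(targets, `[[`, "genes"),
                                  list(empty_genes())))
    ctx <- context_stats(hits, genes_all)
    hits <- ctx$hits
    ownership <- data.frame(
      element_id = vapply(targets, `[[`, "", "element_id"),
      owner_genome = vapply(targets, `[[`, "", "owner_genome"),
      stringsAsFactors = FALSE)
    st <- self_targets(hits, ownership)
    hits$self_target <- hits$element_id %in% st$element_id &
      paste(hits$spacer_id, hits$start) %in% paste(st$spacer_id, st$start)
    list(hits = hits, genic_fraction = ctx$genic_fraction,
         coding_strand_fraction = ctx$coding_strand_fraction,
         self_hits = st, ownership = ownership)
  })
  say("protospacer: ", nrow(hits_out$hits), " hits")

  anti <- stage("anti_crispr", {
    detect_anti_crispr(spacer_table, config$cas_refs, cas$operons,
                       allow_relic = config$allow_relic)
  })
  say("anti-CRISPR: ", sum(anti$flagged), " flagged")

  atlas_table <- atlas_stats(atlas$cl, hits_out$hits)

  array_table <- do.call(rbind, c(lapply(seq_along(genomes), function(i) {
    if (!length(arrays[[i]])) return(NULL)
    do.call(rbind, lapply(arrays[[i]], function(a) data.frame(
      genome_id = ids[i], contig_id = a$contig_id, locus = a$locus,
      start = a$start, end = a$end, n_repeats = nrow(a$repeats),
      repeat_len = a$consensus$length, consensus = a$consensus$seq,
      exact_fraction = a$consensus$exact_fraction,
      orientation = a$orientation,
      single_repeat = a$flags$single_repeat,
      is_disrupted = a$flags$is_disrupted,
      terminal_3prime_degenerate = isTRUE(a$flags$terminal_3prime_degenerate),
      stringsAsFactors = FALSE)))
  }), list(empty_array_table())))

  results <- list(
    genomes = genomes, elements = inp$elements, truth = inp$truth,
    arrays = arrays, array_table = array_table,
    spacer_table = spacer_table, clusters = atlas$cl,
    cluster_table = atlas$cl$clusters,
    duplications = atlas$duplications, polarity = atlas$polarity,
    atlas = atlas_table,
    hits = hits_out$hits, hit_table = hits_out$hits,
    genic_fraction = hits_out$genic_fraction,
    coding_strand_fraction = hits_out$coding_strand_fraction,
    self_hits = hits_out$self_hits,
    cas_calls = cas$calls, operons = cas$operons,
    cas_table = merge_cas_table(cas),
    leader_table = leader_table,
    anti = anti, anti_table = anti,
    distances = evo$D, groups = evo$groups, group_table = evo$groups,
    estimates = evo$estimates, estimate_table = evo$estimates,
    correlation = evo$correlation, repeat_counts = evo$repeat_counts,
    config = config)

  if (!is.null(config$out_dir)) {
    stage("write", write_tables(results, config$out_dir))
    say("written: ", config$out_dir)
  }
  results
}

#' @keywords internal
merge_cas_table <- function(cas) {
  if (!nrow(cas$calls)) return(empty_cas_table())
  op <- cas$operons
  key <- paste(op$genome_id, op$subtype)
  df <- data.frame(
    genome_id = cas$calls$genome_id, subtype = cas$calls$subtype,
    gene_name = cas$calls$gene_name, status = cas$calls$status,
    similarity = round(cas$calls$similarity, 4),
    evidence = cas$calls$evidence,
    operon_status = op$status[match(paste(cas$calls$genome_id,
                                          cas$calls$subtype), key)],
    adjacent_locus = op$adjacent_locus[match(paste(cas$calls$genome_id,
                                                   cas$calls$subtype), key)],
    stringsAsFactors = FALSE)
  df[order(df$genome_id, df$subtype, df$gene_name), , drop = FALSE]
}
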