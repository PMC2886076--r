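# Cross-genome spacer atlas and proto-spacer matching.
#
# Spacer clustering is exact-match after strand normalisation.  Singleton
# status is assessed after collapsing closely related strains (< 0.02%
# substitutions/site) to one representative per group.  Proto-spacers are
# substitution-only matches at identity strictly above 95% (a 32 bp spacer
# tolerates at most one mismatch); hits inside the querying CRISPR arrays
# are excluded.

#' @keywords internal
spacer_key <- function(seq) {
  rc <- vapply(seq, revcomp, "", USE.NAMES = FALSE)
  ifelse(seq <= rc, seq, rc)
}

#' Cluster spacers across genomes
#'
#' Exact-sequence clusters after strand normalisation (the lexicographically
#' smaller of a sequence and its reverse complement is the cluster key).
#' Occurrences are de-duplicated to one representative genome per strain
#' group before singleton status is assessed.
#'
#' @param spacers data frame with columns spacer_id, genome_id, locus,
#'   array_id, index_from_leader, seq
#' @param groups data frame (genome_id, group_id) from
#'   [group_close_strains()]; NULL treats every genome as its own group
#' @return list: `clusters` (cluster_id, representative, locus,
#'   n_occurrences, n_groups, is_singleton), `members` (input plus
#'   cluster_id, group_id, is_representative, is_singleton)
#' @export
cluster_spacers <- function(spacers, groups = NULL) {
  if (!nrow(spacers)) {
    members <- cbind(spacers,
                     data.frame(cluster_id = character(0),
                                group_id = integer(0),
                                is_representative = logical(0),
                                is_singleton = logical(0)))
    return(list(clusters = empty_cluster_table(), members = members))
  }
  if (is.null(groups))
    groups <- data.frame(genome_id = unique(spacers$genome_id),
                         group_id = seq_along(unique(spacers$genome_id)),
                         stringsAsFactors = FALSE)
  members <- spacers
  members$cluster_id <- spacer_key(members$seq)
  members$group_id <- groups$group_id[match(members$genome_id,
                                            groups$genome_id)]
  # representative genome of each group: lexicographically first
  reps <- stats::aggregate(genome_id ~ group_id, data = groups,
                           FUN = function(x) sort(x)[1])
  members$is_representative <-
    members$genome_id == reps$genome_id[match(members$group_id,
                                              reps$group_id)]
  dedup <- members[members$is_representative, , drop = FALSE]
  ng <- tapply(dedup$group_id, dedup$cluster_id,
               function(x) length(unique(x)))
  clusters <- data.frame(
    cluster_id = names(ng),
    n_groups = as.integer(ng),
    stringsAsFactors = FALSE, row.names = NULL)
  occ <- table(members$cluster_id)
  clusters$n_occurrences <- as.integer(occ[clusters$cluster_id])
  clusters$representative <- clusters$cluster_id
  first_loc <- tapply(members$locus, members$cluster_id, function(x) x[1])
  clusters$locus <- as.character(first_loc[clusters$cluster_id])
  clusters$is_singleton <- clusters$n_groups == 1L
  # clusters observed only in non-representative genomes keep their status
  missing <- setdiff(unique(members$cluster_id), clusters$cluster_id)
  if (length(missing)) {
    extra <- data.frame(cluster_id = missing, n_groups = 0L,
                        n_occurrences = as.integer(occ[missing]),
                        representative = missing,
                        locus = as.character(tapply(
                          members$locus, members$cluster_id,
                          function(x) x[1])[missing]),
                        is_singleton = NA, stringsAsFactors = FALSE)
    clusters <- rbind(clusters, extra)
  }
  members$is_singleton <-
    clusters$is_singleton[match(members$cluster_id, clusters$cluster_id)]
  clusters <- clusters[order(clusters$cluster_id),
                       c("cluster_id", "representative", "locus",
                         "n_occurrences", "n_groups", "is_singleton")]
  rownames(clusters) <- NULL
  list(clusters = clusters, members = members)
}

#' Per-locus spacer atlas statistics
#'
#' Counts spacers, distinct spacers and singletons per locus (plus a Total
#' row), over one representative genome per strain group; with hits given,
#' adds proto-spacer counts, genic and coding-strand statistics.
#' Percentages are integers rounded half-up, in the style of published
#' summary tables.
#'
#' @param cl result of [cluster_spacers()]
#' @param hits optional classified hit table from [search_protospacers()] /
#'   [context_stats()]
#' @return data frame, one row per locus plus `Total`
#' @export
atlas_stats <- function(cl, hits = NULL) {
  dedup <- cl$members[cl$members$is_representative, , drop = FALSE]
  loci <- sort(unique(dedup$locus))
  if (!is.null(hits) && nrow(hits))
    hits <- hits[hits$spacer_id %in% dedup$spacer_id, , drop = FALSE]
  one <- function(rows, label) {
    n_sp <- nrow(rows)
    keys <- unique(rows$cluster_id)
    n_di <- length(keys)
    singl <- cl$clusters$is_singleton[match(keys, cl$clusters$cluster_id)]
    n_si <- sum(singl, na.rm = TRUE)
    h <- if (!is.null(hits) && nrow(hits))
      hits[hits$spacer_id %in% rows$spacer_id, , drop = FALSE]
    else empty_hit_table()
    keys_with <- unique(rows$cluster_id[rows$spacer_id %in% h$spacer_id])
    n_hit_sp <- length(keys_with)
    n_ps <- nrow(h)
    n_genic <- if (nrow(h)) sum(h$context == "genic", na.rm = TRUE) else 0L
    n_cod <- if (nrow(h)) sum(h$context == "genic" & h$coding_strand,
                              na.rm = TRUE) else 0L
    data.frame(locus = label, n_spacers = n_sp, n_distinct = n_di,
               n_singleton = n_si,
               singleton_pct = if (n_di) pct_int(n_si, n_di) else 0L,
               n_with_protospacer = n_hit_sp,
               with_protospacer_pct = if (n_di) pct_int(n_hit_sp, n_di) else 0L,
               n_protospacers = n_ps,
               n_genic = n_genic,
               genic_pct = if (n_ps) pct_int(n_genic, n_ps) else 0L,
               n_coding_strand = n_cod,
               coding_strand_pct = if (n_genic) pct_int(n_cod, n_genic) else 0L,
               stringsAsFactors = FALSE)
  }
  per <- lapply(loci, function(l) one(dedup[dedup$locus == l, , drop = FALSE], l))
  tot <- one(dedup, "Total")
  out <- do.call(rbind, c(per, list(tot)))
  rownames(out) <- NULL
  out
}

#' Leader-polarity of singleton spacers
#'
#' Summary statistic: mean index-from-leader of singleton spacers minus
#' that of shared spacers (negative means singletons concentrate at the
#' leader end).  The null band comes from permuting spacer positions within
#' each array.
#'
#' @param cl result of [cluster_spacers()] on oriented arrays
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return list: stat, null_lo, null_hi (2.5%/97.5% permutation quantiles),
#'   p_value (two-sided, add-one smoothed), n_singleton, n_shared;
#'   stat is NA with a `reason` when undefined (no shared or no singleton
#'   spacers)
#' @export
polarity_profile <- function(cl, n_perm = 999L, seed = 1L) {
  d <- cl$members[cl$members$is_representative &
                    !is.na(cl$members$is_singleton), , drop = FALSE]
  ns <- sum(d$is_singleton)
  nh <- sum(!d$is_singleton)
  if (ns == 0L || nh == 0L)
    return(list(stat = NA_real_, reason = "all spacers singleton or all shared",
                n_singleton = ns, n_shared = nh))
  stat_fun <- function(x) mean(x$index_from_leader[x$is_singleton]) -
    mean(x$index_from_leader[!x$is_singleton])
  obs <- stat_fun(d)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      dd <- d
      for (a in unique(dd$array_id)) {
        w <- which(dd$array_id == a)
        dd$index_from_leader[w] <- sample(dd$index_from_leader[w])
      }
      stat_fun(dd)
    }, numeric(1))
  })
  qs <- stats::quantile(perm, c(0.025, 0.975), names = FALSE)
  list(stat = obs, null_lo = qs[1], null_hi = qs[2],
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
       n_singleton = ns, n_shared = nh)
}

#' Detect spacer duplications
#'
#' @param cl result of [cluster_spacers()]
#' @return data frame: cluster_id, genome_id, kind (within_array /
#'   between_arrays)
#' @export
detect_duplications <- function(cl) {
  m <- cl$members
  out <- list()
  for (g in unique(m$genome_id)) {
    mg <- m[m$genome_id == g, , drop = FALSE]
    for (k in unique(mg$cluster_id[duplicated(mg$cluster_id)])) {
      arrs <- mg$array_id[mg$cluster_id == k]
      if (any(duplicated(arrs)))
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = k, genome_id = g, kind = "within_array",
          stringsAsFactors = FALSE)
      if (length(unique(arrs)) > 1L)
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = k, genome_id = g, kind = "between_arrays",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = character(0), genome_id = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @keywords internal
max_mismatches <- function(L, min_identity) {
  # largest m with (L - m) / L > min_identity
  m <- as.integer(ceiling(L * (1 - min_identity))) - 1L
  max(m, 0L)
}

#' Search proto-spacers in a pool of target sequences
#'
#' Substitution-only search: every window of spacer length on either strand
#' of any element with identity strictly above `min_identity` is reported
#' (a 32 bp spacer at the default 0.95 tolerates at most one mismatch).
#' Hits overlapping `exclude_spans` (the querying CRISPR arrays on the
#' genomes' own chromosomes) are removed.
#'
#' @param spacers data frame (spacer_id, genome_id, seq, ...)
#' @param elements list of `mobile_element` objects
#' @param min_identity identity threshold, exceeded strictly (default 0.95)
#' @param exclude_spans optional data frame (element_id, start, end)
#' @return hit data frame: spacer_id, genome_id, element_id, start, end,
#'   strand, mismatches, identity
#' @export
search_protospacers <- function(spacers, elements, min_identity = 0.95,
                                exclude_spans = NULL) {
  out <- list()
  subjects <- lapply(elements, function(e) Biostrings::DNAString(e$seq))
  eids <- vapply(elements, `[[`, "", "element_id")
  uq <- spacers[!duplicated(spacers$spacer_id), , drop = FALSE]
  for (i in seq_len(nrow(uq))) {
    sp <- uq$seq[i]
    L <- nchar(sp)
    mm <- max_mismatches(L, min_identity)
    enc_f <- seq_ints(sp)
    enc_r <- seq_ints(revcomp(sp))
    for (j in seq_along(elements)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else revcomp(sp)
        enc_p <- if (strand == "+") enc_f else enc_r
        m <- Biostrings::matchPattern(pat, subjects[[j]], max.mismatch = mm)
        if (!length(m)) next
        st <- Biostrings::start(m) - 1L
        for (h in seq_along(st)) {
          w <- seq_ints(as.character(m[[h]]))
          nmm <- L - sum(!is.na(w) & !is.na(enc_p) & w == enc_p)
          if ((L - nmm) / L <= min_identity) next
          out[[length(out) + 1L]] <- data.frame(
            spacer_id = uq$spacer_id[i], genome_id = uq$genome_id[i],
            element_id = eids[j], start = st[h], end = st[h] + L,
            strand = strand, mismatches = nmm, identity = (L - nmm) / L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(spacer_id = character(0), genome_id = character(0),
               element_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               mismatches = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(exclude_spans) && nrow(hits) && nrow(exclude_spans)) {
    drop <- vapply(seq_len(nrow(hits)), function(i) {
      ex <- exclude_spans[exclude_spans$element_id == hits$element_id[i], ,
                          drop = FALSE]
      any(ex$start < hits$end[i] & ex$end > hits$start[i])
    }, logical(1))
    hits <- hits[!drop, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Classify proto-spacer hits by target class
#'
#' Phage and plasmid hits inherit the element class; chromosome hits are
#' subclassified `prophage` when inside a labelled prophage span, `cas`
#' when inside a cas gene call, `chromosome` otherwise.
#'
#' @param hits hit table from [search_protospacers()]
#' @param elements element list (classes)
#' @param prophage_spans optional data frame (element_id, start, end)
#' @param cas_spans optional data frame (element_id, start, end)
#' @return hits with a `target_class` column
#' @export
classify_hits <- function(hits, elements, prophage_spans = NULL,
                          cas_spans = NULL) {
  cls <- stats::setNames(vapply(elements, `[[`, "", "element_class"),
                         vapply(elements, `[[`, "", "element_id"))
  hits$target_class <- unname(cls[hits$element_id])
  overlap_any <- function(spans, i) {
    if (is.null(spans) || !nrow(spans)) return(FALSE)
    s <- spans[spans$element_id == hits$element_id[i], , drop = FALSE]
    any(s$start < hits$end[i] & s$end > hits$start[i])
  }
  for (i in seq_len(nrow(hits))) {
    if (!identical(hits$target_class[i], "chromosome")) next
    if (overlap_any(prophage_spans, i)) hits$target_class[i] <- "prophage"
    else if (overlap_any(cas_spans, i)) hits$target_class[i] <- "cas"
  }
  hits
}

#' Genic context of proto-spacer hits
#'
#' A hit is genic iff it overlaps an annotated gene by at least one base;
#' a genic hit is on the coding strand iff its strand equals the gene
#' strand.
#'
#' @param hits hit table
#' @param element_genes gene table across targets (contig_id = element_id)
#' @return list: `hits` (with context and coding_strand columns),
#'   `genic_fraction`, `coding_strand_fraction`
#' @export
context_stats <- function(hits, element_genes) {
  hits$context <- "intergenic"
  hits$coding_strand <- NA
  for (i in seq_len(nrow(hits))) {
    g <- element_genes[element_genes$contig_id == hits$element_id[i] &
                         element_genes$start < hits$end[i] &
                         element_genes$end > hits$start[i], , drop = FALSE]
    if (nrow(g)) {
      hits$context[i] <- "genic"
      hits$coding_strand[i] <- hits$strand[i] %in% g$strand
    }
  }
  n <- nrow(hits)
  ng <- sum(hits$context == "genic")
  list(hits = hits,
       genic_fraction = if (n) ng / n else NA_real_,
       coding_strand_fraction = if (ng) sum(hits$coding_strand,
                                            na.rm = TRUE) / ng else NA_real_)
}

#' Clustered hit span on one target
#'
#' @param hits hits of one (genome, target) pair
#' @return `max(end) - min(start)` in bp
#' @export
hit_span <- function(hits) {
  if (!nrow(hits)) stop("hit_span: no hits")
  max(hits$end) - min(hits$start)
}

#' Self-targeting hits
#'
#' Hits whose target element belongs to the querying genome (its own
#' chromosome, prophage or plasmid).
#'
#' @param hits hit table
#' @param ownership data frame (element_id, owner_genome)
#' @return subset of hits with a `self_target` column set to TRUE
#' @export
self_targets <- function(hits, ownership) {
  own <- stats::setNames(ownership$owner_genome, ownership$element_id)
  sel <- !is.na(own[hits$element_id]) &
    own[hits$element_id] == hits$genome_id
  st <- hits[sel, , drop = FALSE]
  if (nrow(st)) st$self_target <- TRUE
  st
}

#' Detect anti-CRISPR arrays
#'
#' An array is flagged when at least one of its spacers matches (identity
#' strictly above `min_identity`) a cas reference coding sequence of
#' subtype S while the genome's subtype-S operon is absent (optionally:
#' partial relics too).  Arrays whose spacers match cas genes of a subtype
#' the genome still carries are reported unflagged, as self-targeting
#' conflicts.
#'
#' @param spacers spacer table (spacer_id, genome_id, locus, seq)
#' @param cas_refs reference table with coding sequences
#' @param operon_table data frame (genome_id, subtype, status) from
#'   [annotate_cas()]
#' @param min_identity identity threshold (default 0.95, exceeded strictly)
#' @param allow_relic treat a partial (relic) operon as absent
#' @return data frame: genome_id, locus, matched_cas_genes, subtype,
#'   cognate_subtype_present, flagged
#' @export
detect_anti_crispr <- function(spacers, cas_refs, operon_table,
                               min_identity = 0.95, allow_relic = FALSE) {
  ref_elements <- lapply(seq_len(nrow(cas_refs)), function(i)
    new_mobile_element(paste0(cas_refs$subtype[i], "|", cas_refs$gene_name[i]),
                       cas_refs$cds[i], "chromosome"))
  hits <- search_protospacers(spacers, ref_elements, min_identity)
  out <- empty_anti_table()[, setdiff(names(empty_anti_table()), "flagged"),
                            drop = FALSE]
  rows <- list()
  if (nrow(hits)) {
    hits$subtype <- vapply(strsplit(hits$element_id, "|", fixed = TRUE),
                           `[[`, "", 1L)
    hits$gene <- vapply(strsplit(hits$element_id, "|", fixed = TRUE),
                        `[[`, "", 2L)
    key <- spacers[match(hits$spacer_id, spacers$spacer_id), ]
    hits$locus <- key$locus
    combs <- unique(data.frame(genome_id = hits$genome_id,
                               locus = hits$locus, subtype = hits$subtype,
                               stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combs))) {
      sel <- hits$genome_id == combs$genome_id[i] &
        hits$locus == combs$locus[i] & hits$subtype == combs$subtype[i]
      st <- operon_table$status[operon_table$genome_id == combs$genome_id[i] &
                                  operon_table$subtype == combs$subtype[i]]
      st <- if (length(st)) st[1] else "absent"
      present <- st %in% c("complete", if (!allow_relic) "partial")
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = combs$genome_id[i], locus = combs$locus[i],
        matched_cas_genes = paste(sort(unique(hits$gene[sel])),
                                  collapse = ","),
        subtype = combs$subtype[i],
        cognate_subtype_present = present,
        flagged = !present, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_anti_table()
}
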