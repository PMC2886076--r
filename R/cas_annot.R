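# cas gene and operon annotation.
#
# Intact genes are called from annotated CDS by best-hit similarity against
# the bundled subtype references (Ecoli: 8 genes, Ypest: 6 genes).
# Pseudogenes are recovered from raw sequence: reference coding sequences
# are probed across the genome, candidate loci are locally aligned, and a
# locus is pseudo when it shows a frameshift, an internal stop codon, or
# covers less than 80% of the reference length.  The same scan verifies
# that cas copies do not occur away from the CRISPR-associated regions.

#' Call cas genes within a genomic region
#'
#' Each annotated CDS in the region is assigned the best-matching reference
#' gene name when its protein similarity reaches `min_similarity`
#' (one gene name per CDS).
#'
#' @param genome a genome object
#' @param region 0-based half-open `c(start, end)` span, or NULL for the
#'   whole contig
#' @param refs reference table ([default_cas_refs()] or [load_cas_refs()])
#' @param min_similarity positives-fraction floor (default 0.35)
#' @param contig_id contig to scan (default: first contig)
#' @return data frame of calls: gene_name, subtype, start, end, strand,
#'   status, similarity, evidence
#' @export
call_cas <- function(genome, region = NULL, refs = default_cas_refs(),
                     min_similarity = 0.35, contig_id = NULL) {
  if (is.null(contig_id)) contig_id <- names(genome$contigs)[1]
  genes <- genome$genes
  genes <- genes[genes$contig_id == contig_id & genes$type == "CDS" &
                   !is.na(genes$protein), , drop = FALSE]
  if (!is.null(region))
    genes <- genes[genes$start >= region[1] & genes$end <= region[2], ,
                   drop = FALSE]
  out <- empty_cas_calls()
  if (!nrow(genes) || !nrow(refs)) return(out)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    plen <- nchar(genes$protein[i])
    # length prefilter: references outside a 2x length band cannot pass
    cand <- which(nchar(refs$protein) > plen / 2 & nchar(refs$protein) < plen * 2)
    if (!length(cand)) next
    # rank candidates by alignment score, evaluate similarity on the best
    scores <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(refs$protein[cand]),
      Biostrings::AAString(genes$protein[i]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
    b <- which.max(scores)
    sim <- protein_similarity(genes$protein[i], refs$protein[cand[b]])
    if (sim < min_similarity) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_name = refs$gene_name[cand[b]], subtype = refs$subtype[cand[b]],
      contig_id = contig_id, start = genes$start[i], end = genes$end[i],
      strand = genes$strand[i], status = "intact", similarity = sim,
      evidence = "cds_hit", stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' @keywords internal
empty_cas_calls <- function() {
  data.frame(gene_name = character(0), subtype = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), status = character(0),
             similarity = numeric(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

#' Find cas pseudogenes by translated-scan of raw sequence
#'
#' Probes every reference coding sequence across all contigs (both strands),
#' locally aligns candidate loci and calls a locus pseudo when the match
#' shows a frameshift (indel not a multiple of 3), an internal stop, or
#' covers less than `min_coverage` of the reference.  Loci matching an
#' intact annotated CDS are skipped.  Candidate matches shorter than
#' `min_hit_len` (e.g. cas-derived CRISPR spacers) are ignored.
#'
#' @param genome a genome object
#' @param refs reference table
#' @param min_identity nucleotide identity floor over the aligned region
#' @param min_coverage reference-length coverage below which a locus is a
#'   truncation pseudogene (default 0.8)
#' @param min_hit_len minimum aligned genome span (bp) for a credible locus
#' @return data frame of pseudo calls (same shape as [call_cas()], status
#'   "pseudo", evidence "translated_scan")
#' @export
find_pseudogenes <- function(genome, refs = default_cas_refs(),
                             min_identity = 0.8, min_coverage = 0.8,
                             min_hit_len = 120L) {
  out <- empty_cas_calls()
  rows <- list()
  for (cid in names(genome$contigs)) {
    contig <- genome$contigs[[cid]]
    subject <- Biostrings::DNAString(contig)
    cds_here <- genome$genes[genome$genes$contig_id == cid &
                               genome$genes$type == "CDS", , drop = FALSE]
    for (r in seq_len(nrow(refs))) {
      cds <- refs$cds[r]
      cand <- probe_candidates(cds, subject)
      for (ci in seq_len(nrow(cand))) {
        res <- align_candidate(contig, cds, cand$start[ci], cand$strand[ci])
        if (is.null(res)) next
        if (res$span_len < min_hit_len) next
        if (res$identity < min_identity) next
        # skip loci already annotated as an intact CDS
        ov <- cds_here$start < res$end & cds_here$end > res$start
        intactish <- res$coverage >= min_coverage && !res$frameshift &&
          !res$internal_stop
        if (intactish) next
        if (any(ov) && res$coverage >= min_coverage && !res$frameshift) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_name = refs$gene_name[r], subtype = refs$subtype[r],
          contig_id = cid, start = res$start, end = res$end,
          strand = cand$strand[ci], status = "pseudo",
          similarity = res$identity, evidence = "translated_scan",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    # merge duplicate calls of the same reference at overlapping spans
    out <- out[order(out$gene_name, out$subtype, out$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      j <- i - 1L
      if (keep[j] && out$gene_name[i] == out$gene_name[j] &&
          out$subtype[i] == out$subtype[j] &&
          out$start[i] < out$end[j]) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# probe a reference CDS across a contig; returns candidate anchor positions
#' @keywords internal
probe_candidates <- function(cds, subject, probe_len = 24L, step = 150L,
                             max_mm = 3L) {
  n <- nchar(cds)
  at <- seq(1L, max(1L, n - probe_len + 1L), by = step)
  anchors <- list()
  for (a in at) {
    probe <- substr(cds, a, a + probe_len - 1L)
    if (nchar(probe) < probe_len) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") probe else revcomp(probe)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm)
      if (length(m))
        anchors[[length(anchors) + 1L]] <- data.frame(
          pos = Biostrings::start(m) - 1L, offset = a - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(anchors))
    return(data.frame(start = integer(0), strand = character(0)))
  an <- do.call(rbind, anchors)
  # locus start implied by each anchor; cluster within a reference length
  an$locus <- ifelse(an$strand == "+", an$pos - an$offset,
                     an$pos + an$offset + probe_len - nchar(cds))
  an <- an[order(an$strand, an$locus), , drop = FALSE]
  keep <- !duplicated(paste(an$strand, round(an$locus / nchar(cds))))
  cl <- an[keep, , drop = FALSE]
  data.frame(start = pmax(0L, as.integer(cl$locus)), strand = cl$strand,
             stringsAsFactors = FALSE)
}

# local alignment of a reference CDS against a candidate window
#' @keywords internal
align_candidate <- function(contig, cds, approx_start, strand,
                            margin = 250L) {
  n <- nchar(contig)
  w1 <- max(1L, approx_start + 1L - margin)
  w2 <- min(n, approx_start + nchar(cds) + margin)
  win <- substr(contig, w1, w2)
  if (strand == "-") win <- revcomp(win)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(win),
    type = "local", substitutionMatrix =
      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
    gapOpening = 6, gapExtension = 2)
  pr <- pa@pattern@range
  sr <- pa@subject@range
  span_len <- IRanges::width(sr)
  if (span_len < 1L) return(NULL)
  px <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sx <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- px != "-" & sx != "-"
  identity <- if (any(both)) mean(px[both] == sx[both]) else 0
  ins_w <- unlist(IRanges::width(Biostrings::insertion(pa)))
  del_w <- unlist(IRanges::width(Biostrings::deletion(pa)))
  frameshift <- any(c(ins_w, del_w) %% 3L != 0L)
  # internal stop in the reference frame
  seg <- paste(sx[both], collapse = "")
  frame_off <- (3L - (IRanges::start(pr) - 1L) %% 3L) %% 3L
  internal_stop <- FALSE
  if (nchar(seg) - frame_off >= 6L) {
    s2 <- substr(seg, frame_off + 1L, nchar(seg))
    s2 <- substr(s2, 1L, nchar(s2) - nchar(s2) %% 3L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s2),
                                             if.fuzzy.codon = "X"))
    internal_stop <- grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)
  }
  # genome coordinates of the aligned span (0-based half-open)
  if (strand == "+") {
    g1 <- (w1 - 1L) + IRanges::start(sr) - 1L
    g2 <- g1 + span_len
  } else {
    g2 <- (w2) - (IRanges::start(sr) - 1L)
    g1 <- g2 - span_len
  }
  list(start = g1, end = g2, span_len = span_len, identity = identity,
       coverage = IRanges::width(pr) / nchar(cds),
       frameshift = frameshift, internal_stop = internal_stop)
}

#' Operon status from a set of cas gene calls
#'
#' `complete` iff every canonical gene of the subtype is called intact and
#' all calls are co-oriented; `partial` iff there is at least one call but
#' the operon is not complete (pseudogenes, missing genes, relics);
#' `absent` iff there are no calls.
#'
#' @param calls data frame of calls from [call_cas()] /
#'   [find_pseudogenes()] belonging to one genomic neighbourhood
#' @param subtype expected subtype; calls from a different subtype raise an
#'   ambiguity error
#' @return list: subtype, status, co_oriented, gene_calls
#' @export
operon_status <- function(calls, subtype = c("Ecoli", "Ypest")) {
  subtype <- match.arg(subtype)
  if (nrow(calls) && !all(calls$subtype == subtype))
    stop("operon_status: calls from mixed subtypes")
  canonical <- cas_subtype_genes(subtype)
  if (!nrow(calls))
    return(list(subtype = subtype, status = "absent", co_oriented = NA,
                gene_calls = calls))
  co <- length(unique(calls$strand)) == 1L
  intact <- calls$gene_name[calls$status == "intact"]
  complete <- all(canonical %in% intact) && co &&
    !any(calls$status == "pseudo")
  list(subtype = subtype,
       status = if (complete) "complete" else "partial",
       co_oriented = co, gene_calls = calls)
}

#' Annotate cas operons of a genome relative to its CRISPR arrays
#'
#' Scans a window around every anchored array for intact CDS calls, adds
#' genome-wide pseudogene calls, and summarises one operon status per
#' subtype.  An operon is linked to a locus when its span lies within
#' `adjacency` of an array boundary.
#'
#' @param genome genome object
#' @param arrays list of anchored `crispr_array`s of this genome
#' @param refs reference table
#' @param min_similarity CDS-call similarity floor
#' @param window region half-width around arrays scanned for CDS calls (bp)
#' @param adjacency maximum operon-to-array distance (bp) for locus linkage
#' @return list: `calls` (all gene calls), `operons` (one row per subtype:
#'   genome_id, subtype, status, co_oriented, adjacent_locus)
#' @export
annotate_cas <- function(genome, arrays, refs = default_cas_refs(),
                         min_similarity = 0.35, window = 15000L,
                         adjacency = 5000L) {
  calls <- empty_cas_calls()
  regions <- list()
  for (a in arrays) {
    n <- nchar(genome$contigs[[a$contig_id]])
    regions[[length(regions) + 1L]] <-
      list(contig_id = a$contig_id,
           span = c(max(0L, a$start - window), min(n, a$end + window)))
  }
  # merge overlapping windows so shared neighbourhoods are scanned once
  if (length(regions)) {
    regions <- regions[order(vapply(regions, `[[`, "", "contig_id"),
                             vapply(regions, function(r) r$span[1], numeric(1)))]
    merged <- list(regions[[1]])
    for (r in regions[-1]) {
      last <- merged[[length(merged)]]
      if (r$contig_id == last$contig_id && r$span[1] <= last$span[2])
        merged[[length(merged)]]$span[2] <- max(last$span[2], r$span[2])
      else merged[[length(merged) + 1L]] <- r
    }
    for (r in merged) {
      cc <- call_cas(genome, r$span, refs, min_similarity,
                     contig_id = r$contig_id)
      calls <- rbind(calls, cc)
    }
  }
  calls <- calls[!duplicated(calls[, c("gene_name", "subtype", "start")]), ,
                 drop = FALSE]
  pseudo <- find_pseudogenes(genome, refs)
  # drop pseudo calls that overlap an intact call of the same gene
  if (nrow(pseudo) && nrow(calls)) {
    drop <- vapply(seq_len(nrow(pseudo)), function(i) {
      any(calls$gene_name == pseudo$gene_name[i] &
            calls$subtype == pseudo$subtype[i] &
            calls$start < pseudo$end[i] & calls$end > pseudo$start[i])
    }, logical(1))
    pseudo <- pseudo[!drop, , drop = FALSE]
  }
  calls <- rbind(calls, pseudo)
  calls <- calls[order(calls$contig_id, calls$start), , drop = FALSE]
  ops <- list()
  for (st in c("Ecoli", "Ypest")) {
    sub <- calls[calls$subtype == st, , drop = FALSE]
    os <- operon_status(sub, st)
    loc <- NA_character_
    if (nrow(sub)) {
      span <- c(min(sub$start), max(sub$end))
      for (a in arrays) {
        if (a$contig_id %in% sub$contig_id &&
            span[1] < a$end + adjacency && span[2] > a$start - adjacency) {
          loc <- a$locus
          break
        }
      }
    }
    ops[[st]] <- data.frame(genome_id = genome$genome_id, subtype = st,
                            status = os$status,
                            co_oriented = isTRUE(os$co_oriented),
                            adjacent_locus = loc, stringsAsFactors = FALSE)
  }
  list(calls = calls, operons = do.call(rbind, ops))
}
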