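# Orthology, core genome, locus anchoring and leader identification.
#
# Orthologs are unique pairwise reciprocal best hits at >= 60% amino-acid
# similarity and < 20% protein length difference, refined by gene-order
# conservation.  CRISPR loci are named by their flanking core genes
# (CRISPR1: cysD-cysJ, CRISPR2: cysJ-ygcF, CRISPR3: clpS-tRNA-Ser,
# CRISPR4: tRNA-Ser-infA).  Leaders are recognised as the conserved,
# AT-rich flank of a locus, by contrast with the opposite flank.

.LOCUS_ANCHORS <- list(
  CRISPR1 = c("cysD", "cysJ"),
  CRISPR2 = c("cysJ", "ygcF"),
  CRISPR3 = c("clpS", "tRNA-Ser"),
  CRISPR4 = c("tRNA-Ser", "infA"))

#' Amino-acid similarity as positives fraction
#'
#' Global alignment under BLOSUM62 (gap open 10, extend 0.5); similarity is
#' the fraction of alignment columns whose substitution score is positive
#' (gap columns count as non-positive).
#'
#' @param a,b amino-acid strings
#' @return similarity in \[0, 1\]
#' @export
protein_similarity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) return(0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- x != "-" & y != "-"
  if (!any(ok)) return(0)
  B <- get_blosum62()
  pos <- sum(B[cbind(x[ok], y[ok])] > 0)
  pos / length(x)
}

#' @keywords internal
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' @keywords internal
protein_genes <- function(genome) {
  g <- genome$genes
  g[g$type == "CDS" & !is.na(g$protein) & nchar(g$protein) > 0, , drop = FALSE]
}

#' Reciprocal-best-hit orthologs between two genomes
#'
#' A pair (a, b) is reported iff b is a's best hit and a is b's best hit
#' under [protein_similarity()], similarity reaches `min_similarity`, and
#' the protein length difference is below `max_length_diff`.
#'
#' @param genome_a,genome_b genome objects with protein-bearing genes
#' @param min_similarity similarity floor (default 0.6)
#' @param max_length_diff length-difference ceiling (default 0.2, i.e.
#'   |la-lb|/max(la,lb) < 0.2)
#' @return data frame: gene_a, gene_b, similarity, length_diff
#' @export
rbh_orthologs <- function(genome_a, genome_b, min_similarity = 0.6,
                          max_length_diff = 0.2) {
  ga <- protein_genes(genome_a)
  gb <- protein_genes(genome_b)
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    similarity = numeric(0), length_diff = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nrow(ga) || !nrow(gb)) return(out)
  # hits ranked by global alignment score (vectorised); the similarity
  # measure itself is evaluated only on reciprocal candidates
  pa_set <- Biostrings::AAStringSet(ga$protein)
  S <- matrix(-Inf, nrow(ga), nrow(gb))
  for (j in seq_len(nrow(gb)))
    S[, j] <- Biostrings::pairwiseAlignment(
      pa_set, Biostrings::AAString(gb$protein[j]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
  best_a <- apply(S, 1L, which.max)
  best_b <- apply(S, 2L, which.max)
  rows <- list()
  for (i in seq_len(nrow(ga))) {
    j <- best_a[i]
    if (best_b[j] != i) next
    la <- nchar(ga$protein[i]); lb <- nchar(gb$protein[j])
    ld <- abs(la - lb) / max(la, lb)
    if (ld >= max_length_diff) next
    sim <- protein_similarity(ga$protein[i], gb$protein[j])
    if (sim >= min_similarity)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ga$gene_id[i], gene_b = gb$gene_id[j],
        similarity = sim, length_diff = ld, stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' @keywords internal
gene_order <- function(genome) {
  g <- genome$genes
  g <- g[order(g$contig_id, g$start), , drop = FALSE]
  g$order <- stats::ave(seq_len(nrow(g)), g$contig_id, FUN = seq_along)
  g[, c("gene_id", "contig_id", "order")]
}

#' Refine ortholog pairs by synteny
#'
#' A pair survives iff, on each side, at least one of its two nearest gene
#' neighbours also forms an RBH pair with a neighbour of the partner gene
#' (conserved neighbourhood), or its similarity exceeds the 95th percentile
#' of all pair similarities.  The output is always a subset of the input.
#'
#' @param pairs output of [rbh_orthologs()]
#' @param genome_a,genome_b the two genomes
#' @return filtered pair data frame
#' @export
synteny_refine <- function(pairs, genome_a, genome_b) {
  if (!nrow(pairs)) return(pairs)
  oa <- gene_order(genome_a)
  ob <- gene_order(genome_b)
  # neighbourhoods are taken over genes that have an RBH mapping, so genes
  # flanking a lineage-specific insertion/deletion are not penalised
  oa <- oa[oa$gene_id %in% pairs$gene_a, , drop = FALSE]
  ob <- ob[ob$gene_id %in% pairs$gene_b, , drop = FALSE]
  oa$order <- stats::ave(seq_len(nrow(oa)), oa$contig_id, FUN = seq_along)
  ob$order <- stats::ave(seq_len(nrow(ob)), ob$contig_id, FUN = seq_along)
  map_ab <- stats::setNames(pairs$gene_b, pairs$gene_a)
  hi <- stats::quantile(pairs$similarity, 0.95, names = FALSE, type = 7)
  neigh <- function(ord, gene_id, side) {
    r <- ord[ord$gene_id == gene_id, ]
    if (!nrow(r)) return(character(0))
    sel <- ord$contig_id == r$contig_id[1] &
      (if (side == "left") ord$order %in% (r$order[1] - (1:2))
       else ord$order %in% (r$order[1] + (1:2)))
    ord$gene_id[sel]
  }
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    nb <- c(neigh(ob, b, "left"), neigh(ob, b, "right"))
    side_ok <- vapply(c("left", "right"), function(s) {
      na <- neigh(oa, a, s)
      if (!length(na)) return(TRUE)          # contig end: nothing to test
      any(map_ab[na] %in% nb, na.rm = TRUE)
    }, logical(1))
    keep[i] <- all(side_ok) || pairs$similarity[i] > hi
  }
  pairs[keep, , drop = FALSE]
}

#' Core-genome families across genomes
#'
#' Families present exactly once per genome, built from pairwise RBH lists
#' against a reference genome (the first) and verified for all-pairs
#' transitive consistency; inconsistent families are dropped.
#'
#' @param genomes list of at least two genome objects
#' @param min_similarity,max_length_diff RBH thresholds
#' @param refine apply [synteny_refine()] to each pairwise list
#' @return data frame: family_id, genome_id, gene_id, product
#' @export
core_genome <- function(genomes, min_similarity = 0.6, max_length_diff = 0.2,
                        refine = TRUE) {
  n <- length(genomes)
  if (n < 2L) stop("core_genome: need at least two genomes")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  pair_list <- list()
  get_pairs <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(pair_list[[key]])) return(pair_list[[key]])
    p <- rbh_orthologs(genomes[[i]], genomes[[j]], min_similarity,
                       max_length_diff)
    if (refine) p <- synteny_refine(p, genomes[[i]], genomes[[j]])
    pair_list[[key]] <<- p
    p
  }
  ref_pairs <- lapply(2:n, function(j) get_pairs(1L, j))
  ref_genes <- protein_genes(genomes[[1]])
  fams <- list()
  for (g in ref_genes$gene_id) {
    members <- c(g, vapply(ref_pairs, function(p) {
      hit <- p$gene_b[p$gene_a == g]
      if (length(hit) == 1L) hit else NA_character_
    }, ""))
    if (anyNA(members)) next
    consistent <- TRUE
    if (n > 2L) {
      for (i in 2:(n - 1L)) {
        for (j in (i + 1L):n) {
          p <- get_pairs(i, j)
          if (!any(p$gene_a == members[i] & p$gene_b == members[j])) {
            consistent <- FALSE
            break
          }
        }
        if (!consistent) break
      }
    }
    if (!consistent) next
    prod <- ref_genes$product[ref_genes$gene_id == g]
    fams[[length(fams) + 1L]] <- data.frame(
      family_id = paste0("fam_", g), genome_id = ids, gene_id = members,
      product = prod, stringsAsFactors = FALSE)
  }
  if (!length(fams))
    return(data.frame(family_id = character(0), genome_id = character(0),
                      gene_id = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, fams)
}

#' Anchor an array to a named CRISPR locus
#'
#' The label is assigned from the unordered pair of nearest flanking core
#' anchors within `radius` (tRNA genes shared by name across genomes count
#' as anchors alongside core CDS families).
#'
#' @param array a `crispr_array`
#' @param genome the genome carrying it
#' @param core core-family table from [core_genome()] (may be NULL: anchor
#'   products are then taken directly from the genome annotation)
#' @param radius maximum anchor distance in bp (default 30 kb)
#' @return locus label: CRISPR1..CRISPR4 or "unanchored"
#' @export
anchor_locus <- function(array, genome, core = NULL, radius = 30000L) {
  genes <- genome$genes
  anchors <- unique(unlist(.LOCUS_ANCHORS))
  cand <- genes[genes$product %in% anchors, , drop = FALSE]
  if (!is.null(core)) {
    core_here <- core[core$genome_id == genome$genome_id, , drop = FALSE]
    keep <- cand$type == "tRNA" | cand$gene_id %in% core_here$gene_id
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[cand$contig_id == array$contig_id, , drop = FALSE]
  if (!nrow(cand)) return("unanchored")
  left <- cand[cand$end <= array$start &
                 array$start - cand$end <= radius, , drop = FALSE]
  right <- cand[cand$start >= array$end &
                  cand$start - array$end <= radius, , drop = FALSE]
  if (!nrow(left) || !nrow(right)) return("unanchored")
  lg <- left$product[which.max(left$end)]
  rg <- right$product[which.min(right$start)]
  for (locus in names(.LOCUS_ANCHORS)) {
    if (setequal(c(lg, rg), .LOCUS_ANCHORS[[locus]])) return(locus)
  }
  "unanchored"
}

#' @keywords internal
mean_pairwise_identity <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  encs <- lapply(seqs, seq_ints)
  tot <- 0; cnt <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    L <- min(length(encs[[i]]), length(encs[[j]]))
    if (L == 0L) next
    tot <- tot + ident_frac(encs[[i]][1:L], encs[[j]][1:L])
    cnt <- cnt + 1L
  }
  if (cnt == 0L) NA_real_ else tot / cnt
}

#' Identify the leader flank of a locus
#'
#' Compares the cross-genome conservation of the two fixed-length flanks of
#' the arrays sharing a locus.  The more conserved flank is called the
#' leader iff its mean identity exceeds the opposite flank's by `margin`
#' and reaches `floor`; the array orientation is then set so the
#' newest-spacer (5') end abuts the leader.
#'
#' @param locus_arrays list of `list(genome =, array =)` entries sharing a
#'   locus
#' @param flank_len flank window length in bp (default 120)
#' @param margin required conservation asymmetry (mean identity units)
#' @param floor conservation floor for significance (default 0.70)
#' @return list with `side` ("left"/"right"/"none"), `orientation`,
#'   `significant`, and a per-genome leader table
#' @export
find_leader <- function(locus_arrays, flank_len = 120L, margin = 0.15,
                        floor = 0.70) {
  flanks <- lapply(locus_arrays, function(ga) {
    contig <- ga$genome$contigs[[ga$array$contig_id]]
    n <- nchar(contig)
    ls <- max(0L, ga$array$start - flank_len)
    rs <- min(n, ga$array$end + flank_len)
    list(left = substr(contig, ls + 1L, ga$array$start),
         right = substr(contig, ga$array$end + 1L, rs),
         left_span = c(ls, ga$array$start),
         right_span = c(ga$array$end, rs))
  })
  id_left <- mean_pairwise_identity(vapply(flanks, `[[`, "", "left"))
  id_right <- mean_pairwise_identity(vapply(flanks, `[[`, "", "right"))
  single <- length(locus_arrays) < 2L
  side <- "none"; significant <- FALSE
  if (!single && !is.na(id_left) && !is.na(id_right)) {
    if (id_left >= id_right + margin && id_left >= floor) {
      side <- "left"; significant <- TRUE
    } else if (id_right >= id_left + margin && id_right >= floor) {
      side <- "right"; significant <- TRUE
    }
  }
  orientation <- switch(side, left = "leader_left", right = "leader_right",
                        "unknown")
  per_genome <- do.call(rbind, lapply(seq_along(locus_arrays), function(i) {
    ga <- locus_arrays[[i]]
    fl <- flanks[[i]]
    use <- if (side == "right") "right" else "left"
    span <- fl[[paste0(use, "_span")]]
    data.frame(genome_id = ga$genome$genome_id,
               contig_id = ga$array$contig_id,
               side = if (side == "none") NA_character_ else side,
               start = span[1], end = span[2],
               at_fraction = at_fraction(fl[[use]]),
               conservation = if (side == "right") id_right else id_left,
               significant = significant, stringsAsFactors = FALSE)
  }))
  list(side = side, orientation = orientation, significant = significant,
       conservation = c(left = id_left, right = id_right),
       leaders = per_genome)
}
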