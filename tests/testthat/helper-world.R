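# Shared synthetic worlds (memoised across test files) and small utilities.

.worlds <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.worlds[[key]])) .worlds[[key]] <- build()
  .worlds[[key]]
}

small_pool <- function() list(n_phage = 6L, n_plasmid = 4L, n_chromosome = 2L)

# 6 genomes x 150 kb, full default architecture
small_world <- function() cached("small", function()
  generate_world(world_config(n_genomes = 6L, genome_length = 150000L,
                              seed = 11L, pool = small_pool())))

# detection results for the small world
small_detected <- function() cached("small_det", function() {
  w <- small_world()
  d <- lapply(w$genomes, detect_genome_arrays)
  names(d) <- vapply(w$genomes, `[[`, "", "genome_id")
  d
})

# anchored + oriented spacer table built through the detection path
spacer_table_of <- function(w, det) {
  rows <- list()
  for (i in seq_along(w$genomes)) {
    g <- w$genomes[[i]]
    for (a in det[[i]]) {
      a$locus <- anchor_locus(a, g)
      a$orientation <- "leader_left"
      a <- extract_spacers(a, g$contigs[[a$contig_id]])
      if (!nrow(a$spacers)) next
      rows[[length(rows) + 1]] <- data.frame(
        spacer_id = paste0(a$array_id, ".sp", seq_len(nrow(a$spacers))),
        genome_id = g$genome_id, locus = a$locus, array_id = a$array_id,
        index_from_leader = a$spacers$index_from_leader,
        seq = a$spacers$seq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

small_spacer_table <- function() cached("small_spacers", function()
  spacer_table_of(small_world(), small_detected()))

genome_by_id <- function(w, id) {
  w$genomes[[match(id, vapply(w$genomes, `[[`, "", "genome_id"))]]
}

# cached per-genome cas annotation for the small world (anchored arrays)
small_cas <- function(id) {
  cached(paste0("cas_", id), function() {
    w <- small_world()
    i <- match(id, vapply(w$genomes, `[[`, "", "genome_id"))
    arrs <- small_detected()[[i]]
    for (j in seq_along(arrs))
      arrs[[j]]$locus <- anchor_locus(arrs[[j]], w$genomes[[i]])
    annotate_cas(w$genomes[[i]], arrs)
  })
}

# uniform-placement world (polarity null model)
uniform_world <- function() cached("uniform", function()
  generate_world(world_config(n_genomes = 6L, genome_length = 150000L,
                              seed = 23L, polarity = "uniform",
                              pool = small_pool())))

# reverse-complement a whole genome (contigs, genes, spans mirrored)
rc_genome <- function(genome) {
  out <- genome
  for (cid in names(out$contigs)) {
    n <- nchar(out$contigs[[cid]])
    out$contigs[[cid]] <- revcomp(out$contigs[[cid]])
    sel <- out$genes$contig_id == cid
    if (any(sel)) {
      s <- out$genes$start[sel]; e <- out$genes$end[sel]
      out$genes$start[sel] <- n - e
      out$genes$end[sel] <- n - s
      out$genes$strand[sel] <- ifelse(out$genes$strand[sel] == "+", "-", "+")
    }
    sel <- out$element_spans$contig_id == cid
    if (any(sel)) {
      s <- out$element_spans$start[sel]; e <- out$element_spans$end[sel]
      out$element_spans$start[sel] <- n - e
      out$element_spans$end[sel] <- n - s
    }
  }
  out
}

# expected detection runs (spans) of a planted array, split at an IS insert
truth_runs <- function(truth_row) {
  rs <- truth_row$repeat_starts[[1]]
  L <- truth_row$repeat_len
  if (!truth_row$is_disrupted) return(list(c(truth_row$start, truth_row$end)))
  gaps <- diff(rs)
  brk <- which(gaps > 48 + L)
  out <- list()
  prev <- 1
  for (b in c(brk, length(rs))) {
    out[[length(out) + 1]] <- c(rs[prev], rs[b] + L)
    prev <- b + 1
  }
  out
}

# hand-built array contig with boundary-contrast junctions, for detector
# unit tests: returns contig plus truth coordinates
build_test_array <- function(n_repeats = 5L, repeat_seq = NULL,
                             spacer_len = 32L, pad = 2000L,
                             degenerate_last = FALSE) {
  if (is.null(repeat_seq)) repeat_seq <- gsub("W", "A", crispr_repeat1())
  bases <- c("A", "C", "G", "T")
  sps <- character(n_repeats - 1L)
  pf <- NULL; pl <- "X"
  for (i in seq_len(n_repeats - 1L)) {
    s <- paste(sample(bases, spacer_len, replace = TRUE), collapse = "")
    if (!is.null(pf) && substr(s, 1, 1) == pf)
      substr(s, 1, 1) <- sample(setdiff(bases, pf), 1)
    if (substr(s, spacer_len, spacer_len) == pl)
      substr(s, spacer_len, spacer_len) <- sample(setdiff(bases, pl), 1)
    sps[i] <- s
    pf <- substr(s, 1, 1); pl <- substr(s, spacer_len, spacer_len)
  }
  reps <- rep(repeat_seq, n_repeats)
  if (degenerate_last) {
    L <- nchar(repeat_seq)
    last <- reps[n_repeats]
    for (p in (L - 4):L)
      substr(last, p, p) <- sample(setdiff(bases, substr(last, p, p)), 1)
    reps[n_repeats] <- last
  }
  body <- reps[1]
  for (i in seq_len(n_repeats - 1L)) body <- paste0(body, sps[i], reps[i + 1L])
  left <- paste(sample(bases, pad, replace = TRUE), collapse = "")
  # left junction: the character before the first repeat must differ from
  # the spacers' trailing characters pattern start
  if (substr(left, pad, pad) == substr(sps[1], spacer_len, spacer_len))
    substr(left, pad, pad) <- sample(setdiff(bases, substr(left, pad, pad)), 1)
  right <- paste(sample(bases, pad, replace = TRUE), collapse = "")
  if (substr(right, 1, 1) == pf)
    substr(right, 1, 1) <- sample(setdiff(bases, pf), 1)
  list(contig = paste0(left, body, right),
       start = pad, end = pad + nchar(body),
       repeat_starts = pad + c(0L, cumsum(rep(nchar(repeat_seq) +
                                                spacer_len, n_repeats - 1L))),
       repeats = reps, spacers = sps)
}
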