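# De novo CRISPR array detection.
#
# The detector is seed-and-chain, in the style of repeat-finding tools for
# microbial genomes: exact k-mer matches recurring at array-like periods seed
# candidate runs, repeat boundaries are refined by column-wise conservation
# across consecutive repeat copies, and runs are validated against repeat-
# and spacer-length constraints.  Degenerate terminal repeats (which often
# lose the seed word) are recovered by consensus-guided end extension.
# A separate fuzzy scanner (fuzzy_find) rescues single or strongly degenerate
# repeats at 60% identity with identical length.

#' Detector parameters
#'
#' Defaults mirror the published defaults of the CRISPR Recognition Tool:
#' 8 bp search seed, at least 3 repeats, repeat length 19-38 bp and spacer
#' length 19-48 bp.  `rescue_min_identity` is the identity floor of the
#' fuzzy rescue scan (degenerate repeats of identical length), and
#' `min_chain_identity` is the identity floor between repeat copies inside
#' one detected array.
#'
#' @param seed_word seed k-mer length (bp)
#' @param min_repeats minimum repeats per reported array
#' @param repeat_len length-2 integer vector, repeat length range (bp)
#' @param spacer_len length-2 integer vector, spacer length range (bp)
#' @param rescue_min_identity identity floor for [fuzzy_find()]
#' @param max_gap_spacers maximum number of oversized inter-repeat gaps
#'   (IS insertion / missing spacer) tolerated when joining rescued units
#' @param min_chain_identity identity floor between repeat copies in one array
#' @return a named list of validated parameters
#' @export
detector_params <- function(seed_word = 8L, min_repeats = 3L,
                            repeat_len = c(19L, 38L), spacer_len = c(19L, 48L),
                            rescue_min_identity = 0.6, max_gap_spacers = 1L,
                            min_chain_identity = 0.75) {
  stopifnot(seed_word >= 4L, min_repeats >= 2L,
            length(repeat_len) == 2L, repeat_len[1] <= repeat_len[2],
            length(spacer_len) == 2L, spacer_len[1] <= spacer_len[2],
            rescue_min_identity > 0, rescue_min_identity <= 1,
            min_chain_identity > 0, min_chain_identity <= 1)
  list(seed_word = as.integer(seed_word), min_repeats = as.integer(min_repeats),
       repeat_len = as.integer(repeat_len), spacer_len = as.integer(spacer_len),
       rescue_min_identity = rescue_min_identity,
       max_gap_spacers = as.integer(max_gap_spacers),
       min_chain_identity = min_chain_identity)
}

# --- internal helpers -------------------------------------------------------

# column-modal consensus encoding over repeat windows starting at `starts`
#' @keywords internal
modal_consensus <- function(enc, starts, L) {
  vapply(seq_len(L) - 1L, function(t) {
    col <- enc[starts + t]
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_integer_)
    tab <- tabulate(col + 1L, nbins = 4L)
    which.max(tab) - 1L          # ties resolved to the smaller code
  }, integer(1))
}

#' @keywords internal
ident_to <- function(enc, start, cons) {
  w <- enc[start:(start + length(cons) - 1L)]
  sum(!is.na(w) & !is.na(cons) & w == cons) / length(cons)
}

# Refine the repeat window around a run of seed positions `q`.
# A column belongs to the repeat while at most one consecutive pair of copies
# disagrees in it (no disagreement allowed for 3-copy runs); this keeps the
# 3'-degenerate terminal repeat from truncating the unit.
#' @keywords internal
refine_run <- function(enc, q, k, params) {
  m <- length(q)
  allow <- if (m >= 4L) 1L else 0L
  n <- length(enc)
  rep_max <- params$repeat_len[2]
  dis <- function(t) {
    a <- enc[q[-m] + t]
    b <- enc[q[-1] + t]
    sum(is.na(a) | is.na(b) | a != b)
  }
  tl <- 0L
  while (q[1] + tl - 1L >= 1L && (k - (tl - 1L)) <= rep_max &&
         dis(tl - 1L) <= allow) tl <- tl - 1L
  tr <- k
  while (q[m] + tr <= n && (tr + 1L - tl) <= rep_max &&
         dis(tr) <= allow) tr <- tr + 1L
  L <- tr - tl
  # structural cap: repeats must leave room for a minimal spacer
  Lcap <- min(rep_max, min(diff(q)) - params$spacer_len[1])
  if (L > Lcap) { tr <- tr - (L - Lcap); L <- Lcap }
  if (L < params$repeat_len[1]) return(NULL)
  list(starts = q + tl, L = L)
}

# Greedy consensus-guided extension of a run at both ends; rescues terminal
# repeats whose seed word was destroyed by 3' degeneracy, and makes runs
# maximal (not extendable by another qualifying repeat copy).
#' @keywords internal
extend_run <- function(enc, starts, L, params) {
  n <- length(enc)
  spr <- params$spacer_len
  thr <- params$min_chain_identity
  repeat {
    cons <- modal_consensus(enc, starts, L)
    cand <- starts[1] - L - (spr[1]:spr[2])
    cand <- cand[cand >= 1L]
    if (!length(cand)) break
    ids <- vapply(cand, function(p) ident_to(enc, p, cons), numeric(1))
    ok <- which(ids >= thr)
    if (!length(ok)) break
    best <- ok[order(-ids[ok], -cand[ok])][1]  # best identity, nearest
    starts <- c(cand[best], starts)
  }
  repeat {
    cons <- modal_consensus(enc, starts, L)
    last_end <- starts[length(starts)] + L
    cand <- last_end + (spr[1]:spr[2])
    cand <- cand[cand + L - 1L <= n]
    if (!length(cand)) break
    ids <- vapply(cand, function(p) ident_to(enc, p, cons), numeric(1))
    ok <- which(ids >= thr)
    if (!length(ok)) break
    best <- ok[order(-ids[ok], cand[ok])][1]
    starts <- c(starts, cand[best])
  }
  # trim non-qualifying end members (chance seed hits at array-like period)
  repeat {
    m <- length(starts)
    if (m < 2L) break
    cons <- modal_consensus(enc, starts, L)
    if (ident_to(enc, starts[1], cons) < thr) { starts <- starts[-1]; next }
    if (ident_to(enc, starts[m], cons) < thr) { starts <- starts[-m]; next }
    break
  }
  starts
}

#' @keywords internal
new_crispr_array <- function(contig, contig_id, starts, L, array_id = NA_character_) {
  seqs <- substring(contig, starts, starts + L - 1L)
  cons <- consensus_of(seqs, exclude_terminals = length(seqs) >= 3L)
  reps <- data.frame(start = starts - 1L, end = starts + L - 1L, seq = seqs,
                     identity = vapply(seqs, function(s)
                       ident_frac_str(s, cons$seq), numeric(1), USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)
  structure(list(array_id = array_id, contig_id = contig_id,
                 start = reps$start[1], end = reps$end[nrow(reps)],
                 repeats = reps, spacers = NULL,
                 orientation = "unknown", consensus = cons,
                 locus = "unanchored",
                 flags = list(terminal_3prime_degenerate = FALSE,
                              is_disrupted = FALSE,
                              single_repeat = nrow(reps) == 1L),
                 insertions = data.frame(start = integer(0), end = integer(0))),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("<crispr_array>", x$array_id, x$locus, "-", nrow(x$repeats), "repeats x",
      x$consensus$length, "bp,", x$start, "-", x$end, "\n")
  invisible(x)
}

#' Detect CRISPR arrays on a contig
#'
#' Finds maximal runs of at least `min_repeats` equal-length repeat copies
#' separated by spacers within the configured length ranges.  Repeat copies
#' within one array must share an exact seed k-mer at the same offset
#' (degenerate terminal copies are recovered by consensus extension at
#' `min_chain_identity`).  Returned arrays are non-overlapping and ordered
#' by position.
#'
#' @param contig nucleotide string
#' @param params a [detector_params()] list
#' @param contig_id label stored on the returned arrays
#' @return list of `crispr_array` objects (empty list when nothing is found)
#' @export
detect_arrays <- function(contig, params = detector_params(),
                          contig_id = "contig") {
  n <- nchar(contig)
  k <- params$seed_word
  min_span <- params$repeat_len[1] * params$min_repeats +
    params$spacer_len[1] * (params$min_repeats - 1L)
  if (n < min_span) return(list())
  enc <- seq_ints(contig)
  kc <- kmer_codes(enc, k)
  pmin_ <- params$repeat_len[1] + params$spacer_len[1]
  pmax_ <- params$repeat_len[2] + params$spacer_len[2]

  # maximal runs of a recurring seed k-mer with consecutive occurrence gaps
  # in the array period range; a stable sort groups equal codes with
  # positions ascending, so adjacent entries are consecutive occurrences
  ord <- order(kc, na.last = NA, method = "radix")
  if (length(ord) < params$min_repeats) return(list())
  sc <- kc[ord]
  gap <- diff(ord)
  link <- diff(sc) == 0 & gap >= pmin_ & gap <= pmax_
  r <- rle(link)
  ends <- cumsum(r$lengths)
  runs <- list()
  for (j in which(r$values & r$lengths >= params$min_repeats - 1L)) {
    i1 <- ends[j] - r$lengths[j] + 1L
    runs[[length(runs) + 1L]] <- ord[i1:(ends[j] + 1L)]
  }
  if (!length(runs)) return(list())

  # cluster runs that describe the same genomic region; keep the longest
  rng <- t(vapply(runs, function(q) c(q[1], q[length(q)]), numeric(2)))
  ord <- order(rng[, 1])
  chosen <- list()
  cur <- NULL; cur_end <- -Inf
  pick <- function(idx) {
    sizes <- lengths(runs[idx])
    cand <- idx[sizes == max(sizes)]
    cand[which.min(rng[cand, 1])]
  }
  for (i in ord) {
    if (rng[i, 1] <= cur_end) {
      cur <- c(cur, i); cur_end <- max(cur_end, rng[i, 2])
    } else {
      if (!is.null(cur)) chosen[[length(chosen) + 1L]] <- pick(cur)
      cur <- i; cur_end <- rng[i, 2]
    }
  }
  if (!is.null(cur)) chosen[[length(chosen) + 1L]] <- pick(cur)

  # refine, validate, extend; boundary refinement is iterated on the final
  # membership because a chance seed match at array-like distance can join
  # the first pass and truncate the repeat before it is trimmed away
  arrays <- list()
  for (ri in chosen) {
    q <- runs[[ri]]
    ref <- refine_run(enc, q, k, params)
    if (is.null(ref)) next
    L <- ref$L
    gaps <- diff(ref$starts) - L
    ok_link <- gaps >= params$spacer_len[1] & gaps <= params$spacer_len[2]
    brk <- c(0L, which(!ok_link), length(ref$starts))
    for (s in seq_len(length(brk) - 1L)) {
      seg <- ref$starts[(brk[s] + 1L):brk[s + 1L]]
      if (!length(seg)) next
      seg <- extend_run(enc, seg, L, params)
      if (length(seg) < params$min_repeats) next
      for (it in 1:3) {
        ref2 <- refine_run(enc, seg, L, params)
        if (is.null(ref2)) break
        seg2 <- extend_run(enc, ref2$starts, ref2$L, params)
        if (ref2$L == L && identical(seg2, seg)) break
        seg <- seg2
        L <- ref2$L
      }
      if (length(seg) < params$min_repeats) next
      arrays[[length(arrays) + 1L]] <- new_crispr_array(contig, contig_id, seg, L)
    }
  }
  if (!length(arrays)) return(list())

  # greedy non-overlapping selection: more repeats first, then leftmost
  nrep <- vapply(arrays, function(a) nrow(a$repeats), integer(1))
  st <- vapply(arrays, `[[`, numeric(1), "start")
  en <- vapply(arrays, `[[`, numeric(1), "end")
  keep <- logical(length(arrays))
  for (i in order(-nrep, st)) {
    clash <- any(keep & st < en[i] & en > st[i])
    if (!clash) keep[i] <- TRUE
  }
  arrays <- arrays[keep]
  arrays <- arrays[order(vapply(arrays, `[[`, numeric(1), "start"))]
  for (i in seq_along(arrays)) arrays[[i]]$array_id <-
    paste0(contig_id, ".arr", i)
  arrays
}

#' Detect arrays across all contigs of a genome
#'
#' @param genome a genome object
#' @param params [detector_params()]
#' @return list of `crispr_array` objects with genome-scoped array ids
#' @export
detect_genome_arrays <- function(genome, params = detector_params()) {
  out <- list()
  for (cid in names(genome$contigs)) {
    arrs <- detect_arrays(genome$contigs[[cid]], params, contig_id = cid)
    out <- c(out, arrs)
  }
  for (i in seq_along(out)) out[[i]]$array_id <-
    paste0(genome$genome_id, ".arr", i)
  out
}

#' Consensus repeat of an array
#'
#' The consensus is the modal full-length sequence (ties broken towards the
#' lexicographically smaller sequence).  `exact_fraction` is the fraction of
#' repeats identical to the consensus, computed over internal repeats when
#' `exclude_terminals` is set (terminal repeats are frequently degenerate).
#'
#' @param repeat_seqs character vector of equal-length repeat sequences
#' @param exclude_terminals drop the first and last sequence from the
#'   `exact_fraction` computation (requires at least 3 repeats)
#' @return list with `seq`, `length`, `support`, `exact_fraction`
#' @export
consensus_of <- function(repeat_seqs, exclude_terminals = FALSE) {
  if (!length(repeat_seqs)) stop("consensus_of: empty input")
  if (length(unique(nchar(repeat_seqs))) != 1L)
    stop("consensus_of: repeat sequences must have equal length")
  tab <- table(repeat_seqs)
  modal <- sort(names(tab)[tab == max(tab)])[1]
  internal <- repeat_seqs
  if (exclude_terminals && length(repeat_seqs) >= 3L)
    internal <- repeat_seqs[-c(1L, length(repeat_seqs))]
  list(seq = modal, length = nchar(modal), support = length(repeat_seqs),
       exact_fraction = mean(internal == modal))
}

#' Position frequency matrix of aligned repeats
#'
#' @param repeat_seqs character vector of equal-length sequences
#' @return 4 x L matrix of relative base frequencies (rows A, C, G, T);
#'   each column sums to 1
#' @export
pfm_of <- function(repeat_seqs) {
  if (!length(repeat_seqs)) stop("pfm_of: empty input")
  L <- unique(nchar(repeat_seqs))
  if (length(L) != 1L) stop("pfm_of: sequences must have equal length")
  M <- matrix(0, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
  encs <- lapply(repeat_seqs, seq_ints)
  for (j in seq_len(L)) {
    col <- vapply(encs, `[[`, integer(1), j)
    col <- col[!is.na(col)]
    if (!length(col)) stop("pfm_of: column ", j, " has no unambiguous bases")
    M[, j] <- tabulate(col + 1L, nbins = 4L) / length(col)
  }
  M
}

#' Fuzzy consensus scan for degenerate or isolated repeats
#'
#' Reports every window of consensus length (either strand) whose identity to
#' the consensus reaches `min_identity`, greedily made non-overlapping in
#' best-identity-first order.  IUPAC W in the consensus matches A or T.
#'
#' @param contig nucleotide string
#' @param consensus consensus repeat string or a [consensus_of()] result
#' @param region 0-based half-open `c(start, end)` window to scan
#'   (defaults to the whole contig)
#' @param min_identity identity floor (degenerate repeats: 0.6, same length)
#' @return data frame of repeat units: start, end (0-based half-open), seq,
#'   identity, strand
#' @export
fuzzy_find <- function(contig, consensus, region = NULL, min_identity = 0.6) {
  if (is.list(consensus)) consensus <- consensus$seq
  n <- nchar(contig)
  if (is.null(region)) region <- c(0L, n)
  if (region[1] < 0L || region[2] > n || region[1] >= region[2])
    stop("fuzzy_find: region out of contig bounds")
  if (min_identity <= 0 || min_identity > 1)
    stop("fuzzy_find: min_identity must be in (0, 1]")
  L <- nchar(consensus)
  sub <- substr(contig, region[1] + 1L, region[2])
  enc <- seq_ints(sub)
  allowed <- function(cons) {
    ch <- strsplit(cons, "", fixed = TRUE)[[1]]
    lapply(ch, function(b) switch(b, A = 0L, C = 1L, G = 2L, T = 3L,
                                  W = c(0L, 3L), integer(0)))
  }
  scan1 <- function(cons) {
    al <- allowed(cons)
    m <- length(enc) - L + 1L
    if (m < 1L) return(numeric(0))
    acc <- numeric(m)
    for (j in seq_len(L)) {
      x <- enc[j:(j + m - 1L)]
      acc <- acc + as.numeric(x %in% al[[j]])
    }
    acc / L
  }
  fwd <- scan1(consensus)
  rev_ <- scan1(revcomp(consensus))
  mk <- function(scores, strand) {
    idx <- which(scores >= min_identity)
    if (!length(idx)) return(NULL)
    data.frame(p = idx, identity = scores[idx], strand = strand,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(mk(fwd, "+"), mk(rev_, "-"))
  if (is.null(hits) || !nrow(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), identity = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  hits <- hits[order(-hits$identity, hits$p, hits$strand), , drop = FALSE]
  taken <- rep(FALSE, nchar(sub))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- hits$p[i]:(hits$p[i] + L - 1L)
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$p), , drop = FALSE]
  start0 <- region[1] + hits$p - 1L
  data.frame(start = start0, end = start0 + L,
             seq = substring(contig, start0 + 1L, start0 + L),
             identity = hits$identity, strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Assemble fuzzy-found repeat units into arrays
#'
#' Units separated by a spacer-sized gap form one contiguous run; an
#' oversized gap (IS insertion or missing spacer) joins runs into a single
#' array flagged `is_disrupted` as long as at most `max_gap_spacers`
#' oversized gaps occur.  A lone unit yields a `single_repeat` array.
#'
#' @param units data frame from [fuzzy_find()]
#' @param contig nucleotide string the units were found on
#' @param params [detector_params()]
#' @param contig_id label
#' @return list of `crispr_array` objects
#' @export
assemble_rescued <- function(units, contig, params = detector_params(),
                             contig_id = "contig") {
  if (!nrow(units)) return(list())
  L <- units$end[1] - units$start[1]
  gaps <- if (nrow(units) > 1L) units$start[-1] - units$end[-nrow(units)] else integer(0)
  oversized <- gaps > params$spacer_len[2]
  too_far <- gaps > params$spacer_len[2] + 2500L   # beyond an IS-sized insert
  n_over <- 0L
  grp <- integer(nrow(units)); grp[1] <- 1L
  for (i in seq_along(gaps)) {
    new_grp <- too_far[i] ||
      (oversized[i] && n_over >= params$max_gap_spacers)
    if (oversized[i] && !new_grp) n_over <- n_over + 1L
    if (new_grp) n_over <- 0L
    grp[i + 1L] <- grp[i] + as.integer(new_grp)
  }
  out <- list()
  for (g in unique(grp)) {
    u <- units[grp == g, , drop = FALSE]
    arr <- new_crispr_array(contig, contig_id, u$start + 1L, L)
    gg <- if (nrow(u) > 1L) u$start[-1] - u$end[-nrow(u)] else integer(0)
    arr$flags$is_disrupted <- any(gg > params$spacer_len[2])
    out[[length(out) + 1L]] <- arr
  }
  out
}

#' Extract spacers from an array
#'
#' Spacer i is the sequence between repeat i and repeat i+1.  Inter-repeat
#' segments longer than the spacer maximum (IS insertions, missing spacers)
#' are recorded in the array's `insertions` and excluded from the spacer
#' list, and the array is flagged `is_disrupted`.  Concatenating repeats and
#' inter-repeat segments in order reproduces the contig substring exactly.
#'
#' @param array a `crispr_array`
#' @param contig the contig string the array lies on
#' @param params [detector_params()] (spacer length bounds)
#' @return the array, with `$spacers` (data frame: start, end, seq,
#'   index_from_leader) and flags updated
#' @export
extract_spacers <- function(array, contig, params = detector_params()) {
  reps <- array$repeats
  if (nrow(reps) > 1L) {
    if (any(reps$start[-1] < reps$end[-nrow(reps)]))
      stop("extract_spacers: overlapping repeats")
  }
  m <- nrow(reps)
  if (m < 2L) {
    array$spacers <- data.frame(start = integer(0), end = integer(0),
                                seq = character(0),
                                index_from_leader = integer(0),
                                stringsAsFactors = FALSE)
    return(array)
  }
  st <- reps$end[-m]
  en <- reps$start[-1]
  len <- en - st
  is_sp <- len <= params$spacer_len[2]
  sp <- data.frame(start = st[is_sp], end = en[is_sp],
                   seq = substring(contig, st[is_sp] + 1L, en[is_sp]),
                   stringsAsFactors = FALSE)
  # index 0 = newest spacer, adjacent to the leader
  idx <- seq_len(nrow(sp)) - 1L
  if (identical(array$orientation, "leader_right")) idx <- rev(idx)
  sp$index_from_leader <- idx
  array$spacers <- sp
  if (any(!is_sp)) {
    array$insertions <- data.frame(start = st[!is_sp], end = en[!is_sp])
    array$flags$is_disrupted <- TRUE
  }
  array
}

#' Flag terminal-repeat degeneracy
#'
#' A terminal repeat is degenerate when it differs from the consensus by at
#' least two positions within its distal third while internal repeats remain
#' near-exact.  Flags are reported in transcription orientation: the 3'
#' terminal repeat is the one distal to the leader.
#'
#' @param array a `crispr_array` (orientation used if assigned; the contig
#'   forward strand is assumed otherwise)
#' @param min_internal_identity identity floor for internal repeats
#' @return named logical vector `c(five_prime=, three_prime=)`
#' @export
flag_terminal_degeneracy <- function(array, min_internal_identity = 0.9) {
  reps <- array$repeats
  cons <- array$consensus$seq
  L <- nchar(cons)
  m <- nrow(reps)
  if (m < 3L) return(c(five_prime = FALSE, three_prime = FALSE))
  internal_ok <- mean(reps$identity[-c(1L, m)]) >= min_internal_identity
  third <- ceiling(L / 3)
  mism <- function(s) which(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
  left_deg <- internal_ok && sum(mism(reps$seq[1]) <= third) >= 2L
  right_deg <- internal_ok && sum(mism(reps$seq[m]) > L - third) >= 2L
  if (identical(array$orientation, "leader_right"))
    c(five_prime = right_deg, three_prime = left_deg)
  else
    c(five_prime = left_deg, three_prime = right_deg)
}

#' Palindromicity score of a repeat
#'
#' Fraction of the maximum possible base pairs that can form a nested
#' secondary structure: maximum number of Watson-Crick pairs in a nested
#' (pseudoknot-free) pairing with a minimum hairpin loop of 3, divided by
#' floor(n/2).  Watson-Crick pairing keeps the score invariant under
#' reverse complementation.  This is a structural-propensity stand-in; it
#' is not a folding free energy.
#'
#' @param seq nucleotide string, at least 8 bases
#' @return score in \[0, 1\]
#' @export
palindromicity <- function(seq) {
  n <- nchar(seq)
  if (n < 8L) stop("palindromicity: sequence shorter than 8")
  b <- strsplit(toupper(seq), "")[[1]]
  can_pair <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "G" && y == "C") || (x == "C" && y == "G")
  }
  M <- matrix(0L, n, n)
  for (span in 4L:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(M[i + 1L, j], M[i, j - 1L])
      if (can_pair(b[i], b[j])) best <- max(best, M[i + 1L, j - 1L] + 1L)
      if (j - i >= 2L) {
        for (kk in i:(j - 1L)) {
          v <- M[i, kk] + M[kk + 1L, j]
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  M[1L, n] / (n %/% 2L)
}
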