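# Independent brute-force oracles, written with naive character-level loops.

# Brute-force tandem-repeat array enumeration under the detector's published
# definition (seed runs, conserved-column boundary refinement, gap
# validation, consensus end extension, greedy non-overlapping selection).
oracle_detect_arrays <- function(contig, params = detector_params()) {
  k <- params$seed_word
  n <- nchar(contig)
  rep_rng <- params$repeat_len
  sp_rng <- params$spacer_len
  pmin <- rep_rng[1] + sp_rng[1]
  pmax <- rep_rng[2] + sp_rng[2]
  if (n < rep_rng[1] * params$min_repeats + sp_rng[1] * (params$min_repeats - 1))
    return(list())
  ch <- strsplit(contig, "", fixed = TRUE)[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  nk <- n - k + 1
  kmers <- substring(contig, 1:nk, k:n)
  kok <- vapply(1:nk, function(i) all(valid[i:(i + k - 1)]), logical(1))

  runs <- list()
  tab <- table(kmers[kok])
  for (v in names(tab[tab >= 2])) {
    ps <- which(kmers == v & kok)
    chain <- ps[1]
    for (p in ps[-1]) {
      gp <- p - chain[length(chain)]
      if (gp >= pmin && gp <= pmax) {
        chain <- c(chain, p)
      } else {
        if (length(chain) >= params$min_repeats)
          runs[[length(runs) + 1]] <- chain
        chain <- p
      }
    }
    if (length(chain) >= params$min_repeats) runs[[length(runs) + 1]] <- chain
  }
  if (!length(runs)) return(list())

  spans <- t(vapply(runs, range, numeric(2)))
  ord <- order(spans[, 1])
  groups <- list(); cur <- integer(0); cur_end <- -Inf
  for (i in ord) {
    if (spans[i, 1] <= cur_end) {
      cur <- c(cur, i); cur_end <- max(cur_end, spans[i, 2])
    } else {
      if (length(cur)) groups[[length(groups) + 1]] <- cur
      cur <- i; cur_end <- spans[i, 2]
    }
  }
  groups[[length(groups) + 1]] <- cur
  chosen <- vapply(groups, function(idx) {
    sz <- lengths(runs[idx])
    cand <- idx[sz == max(sz)]
    cand[which.min(spans[cand, 1])]
  }, integer(1))

  dis_at <- function(q, t) {
    d <- 0
    for (j in seq_len(length(q) - 1)) {
      a <- q[j] + t; b <- q[j + 1] + t
      if (!valid[a] || !valid[b] || ch[a] != ch[b]) d <- d + 1
    }
    d
  }
  modal_of <- function(starts, L) {
    vapply(1:L, function(t) {
      col <- ch[starts + t - 1]
      col <- col[valid[starts + t - 1]]
      if (!length(col)) return("")
      tb <- table(factor(col, levels = c("A", "C", "G", "T")))
      c("A", "C", "G", "T")[which.max(tb)]
    }, "")
  }
  ident_at <- function(p, cons) {
    L <- length(cons)
    hit <- 0
    for (t in 1:L)
      if (valid[p + t - 1] && cons[t] != "" && ch[p + t - 1] == cons[t])
        hit <- hit + 1
    hit / L
  }

  refine_naive <- function(q, k0) {
    m <- length(q)
    allow <- if (m >= 4) 1 else 0
    tl <- 0
    while (q[1] + tl - 1 >= 1 && (k0 - (tl - 1)) <= rep_rng[2] &&
           dis_at(q, tl - 1) <= allow) tl <- tl - 1
    tr <- k0
    while (q[m] + tr <= n && (tr + 1 - tl) <= rep_rng[2] &&
           dis_at(q, tr) <= allow) tr <- tr + 1
    L <- tr - tl
    Lcap <- min(rep_rng[2], min(diff(q)) - sp_rng[1])
    if (L > Lcap) { tr <- tr - (L - Lcap); L <- Lcap }
    if (L < rep_rng[1]) return(NULL)
    list(starts = q + tl, L = L)
  }

  arrays <- list()
  for (ri in chosen) {
    q <- runs[[ri]]
    ref <- refine_naive(q, k)
    if (is.null(ref)) next
    L <- ref$L
    starts <- ref$starts
    gaps <- diff(starts) - L
    good <- gaps >= sp_rng[1] & gaps <= sp_rng[2]
    brk <- c(0, which(!good), length(starts))
    for (s in seq_len(length(brk) - 1)) {
      seg <- starts[(brk[s] + 1):brk[s + 1]]
      if (!length(seg)) next
      ext <- function(seg, L) {
      # end extension
      repeat {
        cons <- modal_of(seg, L)
        found <- FALSE
        best_id <- -1; best_p <- NA
        for (g in sp_rng[1]:sp_rng[2]) {
          p <- seg[1] - g - L
          if (p < 1) next
          id <- ident_at(p, cons)
          if (id >= params$min_chain_identity && id > best_id) {
            best_id <- id; best_p <- p
          }
        }
        if (!is.na(best_p)) { seg <- c(best_p, seg); found <- TRUE }
        if (!found) break
      }
      repeat {
        cons <- modal_of(seg, L)
        found <- FALSE
        best_id <- -1; best_p <- NA
        for (g in sp_rng[1]:sp_rng[2]) {
          p <- seg[length(seg)] + L + g
          if (p + L - 1 > n) next
          id <- ident_at(p, cons)
          if (id >= params$min_chain_identity && id > best_id) {
            best_id <- id; best_p <- p
          }
        }
        if (!is.na(best_p)) { seg <- c(seg, best_p); found <- TRUE }
        if (!found) break
      }
      repeat {
        if (length(seg) < 2) break
        cons <- modal_of(seg, L)
        if (ident_at(seg[1], cons) < params$min_chain_identity) {
          seg <- seg[-1]; next
        }
        if (ident_at(seg[length(seg)], cons) < params$min_chain_identity) {
          seg <- seg[-length(seg)]; next
        }
        break
      }
      seg
      }
      seg <- ext(seg, L)
      if (length(seg) < params$min_repeats) next
      # iterate refinement on the trimmed membership (chance seed matches
      # beyond the array can truncate the first pass)
      for (it in 1:3) {
        ref2 <- refine_naive(seg, L)
        if (is.null(ref2)) break
        seg2 <- ext(ref2$starts, ref2$L)
        if (ref2$L == L && identical(seg2, seg)) break
        seg <- seg2
        L <- ref2$L
      }
      if (length(seg) < params$min_repeats) next
      arrays[[length(arrays) + 1]] <- list(starts = seg, L = L)
    }
  }
  if (!length(arrays)) return(list())
  nrep <- vapply(arrays, function(a) length(a$starts), integer(1))
  st <- vapply(arrays, function(a) a$starts[1], numeric(1))
  en <- vapply(arrays, function(a) a$starts[length(a$starts)] + a$L, numeric(1))
  keep <- logical(length(arrays))
  for (i in order(-nrep, st)) {
    if (!any(keep & st < en[i] & en > st[i])) keep[i] <- TRUE
  }
  arrays <- arrays[keep]
  arrays[order(vapply(arrays, function(a) a$starts[1], numeric(1)))]
}

# compact (start0, end0, L, starts0) view for comparison
array_signature <- function(a) {
  if (is.list(a) && !is.null(a$repeats))
    list(starts = a$repeats$start, L = a$consensus$length)
  else
    list(starts = a$starts - 1L, L = a$L)
}

expect_same_arrays <- function(det, oracle) {
  expect_equal(length(det), length(oracle))
  if (length(det)) {
    for (i in seq_along(det)) {
      sd <- array_signature(det[[i]])
      so <- array_signature(oracle[[i]])
      expect_equal(sd$starts, so$starts)
      expect_equal(sd$L, so$L)
    }
  }
}

# Exhaustive both-strand sliding-window proto-spacer scan.
oracle_protospacers <- function(spacer, element_seq, min_identity = 0.95) {
  L <- nchar(spacer)
  n <- nchar(element_seq)
  ce <- strsplit(element_seq, "", fixed = TRUE)[[1]]
  res <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp(spacer)
    cp <- strsplit(pat, "", fixed = TRUE)[[1]]
    for (s in seq_len(max(0, n - L + 1))) {
      w <- ce[s:(s + L - 1)]
      mm <- sum(w != cp | !(w %in% c("A", "C", "G", "T")))
      if ((L - mm) / L > min_identity)
        res[[length(res) + 1]] <- data.frame(
          start = s - 1L, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(start = integer(0), strand = character(0),
                  mismatches = integer(0), stringsAsFactors = FALSE)
}

# Exhaustive nested-pairing maximisation (min hairpin loop 3) for short
# sequences; independent of the dynamic program.
oracle_max_pairs <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ok <- c("AT", "TA", "GC", "CG")
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1, j)
    for (kk in (i + 4):j) {
      if (paste0(b[i], b[kk]) %in% ok)
        best <- max(best, 1L + rec(i + 1, kk - 1) + rec(kk + 1, j))
    }
    best
  }
  rec(1L, length(b))
}
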