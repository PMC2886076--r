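# Synthetic multi-genome worlds with planted CRISPR/cas architecture and a
# ground-truth ledger.
#
# Each world emulates the comparative setting of enterobacterial CRISPR
# analysis: a conserved core-gene backbone (cysD, cysJ, ygcF, clpS,
# tRNA-Ser, infA, aat analogs plus fillers), four CRISPR loci anchored
# between fixed core-gene pairs, AT-rich leaders conserved per locus,
# spacers sampled with recorded provenance from a phage/plasmid pool,
# cas operons in intact / partial / relic / absent states, IS disruptions,
# 3'-degenerate terminal repeats, closely related strain pairs, and an
# anti-CRISPR scenario (cas-matching spacers in genomes lacking the cognate
# operon).
#
# Planted arrays are boundary-identifiable by construction: consecutive
# spacers differ in their first and last characters (and likewise at the
# leader and trailing junctions), so the column just outside each repeat is
# never conserved across repeat copies and the detector's boundary rule has
# a unique answer.  Provenance spacers satisfy these constraints by window
# selection, not by editing, so their mismatch budget is untouched.

.REPEAT1 <- "CGGTTTATCCCCGCTGGCGCGGGGAACWC"   # 29 bp, W = A/T
.REPEAT2 <- "GTTCACTGCCGTACAGGCAGCTTAGAAA"    # 28 bp

#' Printed repeat consensi of the two CRISPR repeat families
#'
#' CRISPR1/CRISPR2 share a 29 bp repeat (one ambiguous A/T position, IUPAC
#' W); CRISPR3/CRISPR4 share a 28 bp repeat.
#' @return consensus string
#' @export
crispr_repeat1 <- function() .REPEAT1

#' @rdname crispr_repeat1
#' @export
crispr_repeat2 <- function() .REPEAT2

.LOCI <- c("CRISPR1", "CRISPR2", "CRISPR3", "CRISPR4")

.CORE_TEMPLATES <- data.frame(
  name = c("cysD", "cysJ", "ygcF", "clpS", "tRNA-Ser", "infA", "aat",
           paste0("fill", 1:8)),
  type = c(rep("CDS", 4), "tRNA", "CDS", "CDS", rep("CDS", 8)),
  len = c(909L, 1803L, 750L, 321L, 90L, 219L, 702L,
          639L, 903L, 1203L, 741L, 606L, 960L, 825L, 1101L),
  stringsAsFactors = FALSE)

#' World configuration for the synthetic generator
#'
#' Defaults define the study conditions the package is tested under:
#' 6 genomes of 1 Mb, the two printed repeat consensi, ~32 bp spacers,
#' a 120 bp AT-rich (0.7) leader conserved per locus, a 40-element
#' phage/plasmid/chromosome pool, a quarter of spacers carrying recorded
#' provenance, one IS-disrupted array, a close strain pair at 10^-4
#' substitutions/site, and four genomes carrying the anti-CRISPR scenario.
#'
#' @param n_genomes number of genomes
#' @param genome_length chromosome length in bp
#' @param repeat1,repeat2 repeat consensi (IUPAC W allowed)
#' @param spacer_len_mean,spacer_len_sd spacer length distribution (bp),
#'   clipped to \[28, 36\]
#' @param leader_len leader length (bp)
#' @param leader_at leader AT fraction
#' @param leader_mut per-site leader divergence between genomes
#' @param gene_mut per-site coding divergence between genome copies of a
#'   core-gene template (stop-codon-safe)
#' @param prov_fraction fraction of private spacers copied from pool elements
#' @param prov_mut_prob probability a provenance spacer carries one planted
#'   mismatch
#' @param array_repeats named list of repeat-count ranges per locus
#' @param anti_repeats repeat-count range of anti-CRISPR arrays
#' @param stack_size number of ancestral (shared) spacers per locus
#' @param stack_keep range of ancestral spacers retained per genome
#' @param degenerate_3prime mutate the last `degeneracy_bp` bases of the
#'   final repeat (applied when an array has at least 4 repeats)
#' @param degeneracy_bp extent of terminal degeneracy (bp)
#' @param pool element-pool sizes (n_phage, n_plasmid, n_chromosome)
#' @param is_len IS element length (bp)
#' @param polarity "leader" plants new (private) spacers at the leader end;
#'   "uniform" shuffles spacer order (null model for polarity statistics)
#' @param genome_specs optional per-genome role list; see
#'   [default_genome_specs()]
#' @param seed integer driving all randomness (per-genome streams derived)
#' @return a validated configuration list
#' @export
world_config <- function(n_genomes = 6L, genome_length = 1000000L,
                         repeat1 = crispr_repeat1(), repeat2 = crispr_repeat2(),
                         spacer_len_mean = 32, spacer_len_sd = 2,
                         leader_len = 120L, leader_at = 0.7, leader_mut = 0.02,
                         gene_mut = 0.02,
                         prov_fraction = 0.25, prov_mut_prob = 0.4,
                         array_repeats = list(CRISPR1 = c(5L, 12L),
                                              CRISPR2 = c(5L, 12L),
                                              CRISPR3 = c(4L, 8L),
                                              CRISPR4 = c(4L, 8L)),
                         anti_repeats = c(4L, 6L),
                         stack_size = 8L, stack_keep = c(3L, 6L),
                         degenerate_3prime = TRUE, degeneracy_bp = 5L,
                         pool = list(n_phage = 25L, n_plasmid = 12L,
                                     n_chromosome = 3L),
                         is_len = 800L,
                         polarity = c("leader", "uniform"),
                         genome_specs = NULL,
                         seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(nchar(repeat1) > 0, nchar(repeat2) > 0,
            leader_at >= 0, leader_at <= 1, leader_mut >= 0, leader_mut <= 1,
            prov_fraction >= 0, prov_fraction <= 1,
            prov_mut_prob >= 0, prov_mut_prob <= 1,
            n_genomes >= 1)
  if (is.null(genome_specs)) genome_specs <- default_genome_specs(n_genomes)
  if (length(genome_specs) != n_genomes)
    stop("genome_specs must have one entry per genome")
  list(n_genomes = as.integer(n_genomes),
       genome_length = as.integer(genome_length),
       repeat1 = toupper(repeat1), repeat2 = toupper(repeat2),
       spacer_len_mean = spacer_len_mean, spacer_len_sd = spacer_len_sd,
       leader_len = as.integer(leader_len), leader_at = leader_at,
       leader_mut = leader_mut, gene_mut = gene_mut,
       prov_fraction = prov_fraction, prov_mut_prob = prov_mut_prob,
       array_repeats = array_repeats, anti_repeats = as.integer(anti_repeats),
       stack_size = as.integer(stack_size), stack_keep = as.integer(stack_keep),
       degenerate_3prime = degenerate_3prime,
       degeneracy_bp = as.integer(degeneracy_bp),
       pool = pool, is_len = as.integer(is_len), polarity = polarity,
       genome_specs = genome_specs, seed = as.integer(seed))
}

#' Default per-genome roles
#'
#' Role rotation: (1) intact Ecoli operon + anti-CRISPR3; (2) as 1 plus a
#' planted prophage, a self-targeting spacer and an IS-disrupted CRISPR2;
#' (3) partial Ecoli operon (cas3 frameshift, cse1 truncation) + anti;
#' (4) Ecoli relic (only a cas3 pseudogene) + anti; (5) CRISPR3/4 with an
#' intact Ypest operon, plasmid-derived spacers and an owned plasmid with a
#' self-target; (6) close relative of genome 1 at 10^-4 substitutions/site.
#'
#' @param n_genomes number of genomes
#' @return list of role descriptions
#' @export
default_genome_specs <- function(n_genomes) {
  base <- list(
    list(loci = c("CRISPR1", "CRISPR2", "CRISPR3"),
         cas = list(subtype = "Ecoli", state = "intact"), anti3 = TRUE),
    list(loci = c("CRISPR1", "CRISPR2", "CRISPR3"),
         cas = list(subtype = "Ecoli", state = "intact"), anti3 = TRUE,
         prophage = TRUE, self_prophage_spacer = TRUE,
         is_disrupt = "CRISPR2"),
    list(loci = c("CRISPR1", "CRISPR2", "CRISPR3"),
         cas = list(subtype = "Ecoli", state = "partial",
                    pseudo = c(cas3 = "frameshift", cse1 = "truncation")),
         anti3 = TRUE),
    list(loci = c("CRISPR1", "CRISPR2", "CRISPR3"),
         cas = list(subtype = "Ecoli", state = "relic",
                    pseudo = c(cas3 = "frameshift")), anti3 = TRUE),
    list(loci = c("CRISPR3", "CRISPR4"),
         cas = list(subtype = "Ypest", state = "intact"), anti3 = FALSE,
         plasmids = 1L, self_plasmid_spacer = TRUE),
    list(clone_of = 1L, clone_d = 1e-4))
  specs <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    s <- base[[(i - 1L) %% 6L + 1L]]
    if (!is.null(s$clone_of) && s$clone_of >= i) s <- base[[1L]]
    specs[[i]] <- s
  }
  specs
}

# ---------------------------------------------------------------------------
# helpers

.NONSTOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' @keywords internal
random_cds <- function(len_nt) {
  nc <- len_nt %/% 3L
  paste0("ATG",
         paste(sample(.NONSTOP_CODONS, nc - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

# point-mutate a CDS, reverting mutations that create internal stops
#' @keywords internal
mutate_cds <- function(dna, rate) {
  s <- mutate_seq(dna, rate)$seq
  nc <- nchar(s) %/% 3L
  if (nc > 1L) {
    at <- seq(1L, by = 3L, length.out = nc)
    cod <- substring(s, at, at + 2L)
    bad <- which(cod[-nc] %in% c("TAA", "TAG", "TGA"))
    if (length(bad)) {
      cod0 <- substring(dna, at, at + 2L)
      cod[bad] <- cod0[bad]
      s <- paste(cod, collapse = "")
    }
  }
  s
}

#' @keywords internal
first_char <- function(s) substr(s, 1L, 1L)
#' @keywords internal
last_char <- function(s) substr(s, nchar(s), nchar(s))
#' @keywords internal
set_char <- function(s, i, ch) { substr(s, i, i) <- ch; s }

# draw a random spacer whose boundary characters avoid the given values
#' @keywords internal
random_spacer <- function(len, not_first = NULL, not_last = NULL) {
  s <- random_seq(len)
  if (!is.null(not_first) && first_char(s) %in% not_first)
    s <- set_char(s, 1L, sample(setdiff(.BASES, not_first), 1L))
  if (!is.null(not_last) && last_char(s) %in% not_last)
    s <- set_char(s, len, sample(setdiff(.BASES, not_last), 1L))
  s
}

# sample a window (either strand) from a source sequence whose boundary
# characters avoid the given values; returns NULL when none is found
#' @keywords internal
pick_window <- function(src, len, not_first = NULL, not_last = NULL,
                        tries = 250L) {
  n <- nchar(src)
  if (n < len) return(NULL)
  cand <- sample.int(n - len + 1L, min(tries, n - len + 1L))
  strands <- sample(c("+", "-"), length(cand), replace = TRUE)
  for (i in seq_along(cand)) {
    w <- substr(src, cand[i], cand[i] + len - 1L)
    sp <- if (strands[i] == "+") w else revcomp(w)
    if (grepl("N", sp, fixed = TRUE)) next
    if (!is.null(not_first) && first_char(sp) %in% not_first) next
    if (!is.null(not_last) && last_char(sp) %in% not_last) next
    return(list(seq = sp, start = cand[i] - 1L, strand = strands[i]))
  }
  NULL
}

#' @keywords internal
spacer_len_draw <- function(cfg) {
  max(28L, min(36L, as.integer(round(stats::rnorm(1, cfg$spacer_len_mean,
                                                  cfg$spacer_len_sd)))))
}

# ---------------------------------------------------------------------------
# element pool

#' @keywords internal
make_pool_element <- function(element_id, class, len) {
  seq <- random_seq(len)
  products <- c("hypothetical protein", "DNA methylase", "integrase",
                "replication protein", "tail fiber protein",
                "antirestriction protein")
  genes <- list(); pos <- 1L + sample(40:120, 1L); gi <- 0L
  while (pos + 600L < len) {
    glen <- sample(600:1500, 1L)
    if (pos + glen > len - 20L) break
    gi <- gi + 1L
    genes[[gi]] <- data.frame(
      gene_id = paste0(element_id, ".g", gi), contig_id = element_id,
      start = pos - 1L, end = pos - 1L + glen,
      strand = sample(c("+", "-"), 1L), type = "CDS",
      product = sample(products, 1L), protein = NA_character_,
      stringsAsFactors = FALSE)
    pos <- pos + glen + sample(60:200, 1L)
  }
  gdf <- if (gi) do.call(rbind, genes) else empty_genes()
  new_mobile_element(element_id, seq, class, genes = gdf)
}

# ---------------------------------------------------------------------------
# arrays

# Build the ordered spacer list of one array.  Privates sit leader-side,
# the retained ancestral suffix sits trailer-side.  Consecutive spacers are
# guaranteed to differ in first and last characters.
#' @keywords internal
gen_array_spacers <- function(cfg, n_spacers, locus, elements, stack,
                              leader_last, extra_sources = list()) {
  keep <- min(sample(cfg$stack_keep[1]:cfg$stack_keep[2], 1L),
              nrow(stack), n_spacers - 1L)
  keep <- max(keep, 0L)
  suffix <- if (keep > 0L) stack[(nrow(stack) - keep + 1L):nrow(stack), ,
                                 drop = FALSE] else stack[0L, , drop = FALSE]
  n_priv <- n_spacers - keep
  rows <- list()
  prev_first <- NULL
  prev_last <- leader_last
  head_first <- if (nrow(suffix)) first_char(suffix$seq[1]) else NULL
  head_last <- if (nrow(suffix)) last_char(suffix$seq[1]) else NULL
  src_pool <- if (locus %in% c("CRISPR3", "CRISPR4"))
    Filter(function(e) e$element_class == "plasmid", elements)
  else Filter(function(e) e$element_class == "phage", elements)
  for (j in seq_len(n_priv)) {
    nf <- prev_first
    nl <- prev_last
    if (j == n_priv && nrow(suffix)) { nf <- c(nf, head_first); nl <- c(nl, head_last) }
    len <- spacer_len_draw(cfg)
    row <- NULL
    forced <- extra_sources[[as.character(j)]]
    if (!is.null(forced)) {
      w <- pick_window(forced$seq, len, nf, nl)
      if (!is.null(w))
        row <- data.frame(seq = w$seq, source_kind = forced$kind,
                          source_id = forced$id, source_start = w$start,
                          source_strand = w$strand, n_mut = 0L,
                          shared = FALSE, stringsAsFactors = FALSE)
    } else if (length(src_pool) && stats::runif(1) < cfg$prov_fraction) {
      el <- src_pool[[sample.int(length(src_pool), 1L)]]
      w <- pick_window(el$seq, len, nf, nl)
      if (!is.null(w)) {
        n_mut <- 0L
        if (stats::runif(1) < cfg$prov_mut_prob) {
          p <- sample(2:(len - 1L), 1L)       # internal: boundaries preserved
          w$seq <- substitute_at(w$seq, p)
          n_mut <- 1L
        }
        row <- data.frame(seq = w$seq, source_kind = "element",
                          source_id = el$element_id, source_start = w$start,
                          source_strand = w$strand, n_mut = n_mut,
                          shared = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (is.null(row))
      row <- data.frame(seq = random_spacer(len, nf, nl),
                        source_kind = "random", source_id = NA_character_,
                        source_start = NA_integer_, source_strand = NA_character_,
                        n_mut = 0L, shared = FALSE, stringsAsFactors = FALSE)
    rows[[j]] <- row
    prev_first <- first_char(row$seq)
    prev_last <- last_char(row$seq)
  }
  out <- do.call(rbind, c(rows, list(suffix)))
  if (is.null(out)) out <- stack[0L, , drop = FALSE]
  if (cfg$polarity == "uniform" && nrow(out) > 1L) {
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out <- repair_chain(out, leader_last)
  }
  rownames(out) <- NULL
  out
}

# restore the consecutive-differ boundary property after shuffling
#' @keywords internal
repair_chain <- function(sp, leader_last) {
  prev_last <- leader_last
  prev_first <- NULL
  for (j in seq_len(nrow(sp))) {
    s <- sp$seq[j]
    if (!is.null(prev_first) && first_char(s) == prev_first) {
      s <- set_char(s, 1L, sample(setdiff(.BASES, prev_first), 1L))
      sp$n_mut[j] <- sp$n_mut[j] + 1L
    }
    if (last_char(s) == prev_last) {
      s <- set_char(s, nchar(s), sample(setdiff(.BASES, prev_last), 1L))
      sp$n_mut[j] <- sp$n_mut[j] + 1L
    }
    sp$seq[j] <- s
    prev_first <- first_char(s)
    prev_last <- last_char(s)
  }
  sp
}

# Assemble one array segment: leader + (repeat spacer)* + repeat, with
# optional IS insertion and 3' terminal degeneracy.  Coordinates returned
# are relative to the segment start (0-based half-open).
#' @keywords internal
build_array_segment <- function(cfg, repeat_base, leader, spacers,
                                is_insert = NULL) {
  rep_seq <- repeat_base
  wpos <- as.integer(gregexpr("W", rep_seq, fixed = TRUE)[[1]])
  wpos <- wpos[wpos > 0L]
  for (p in wpos) rep_seq <- set_char(rep_seq, p, sample(c("A", "T"), 1L))
  L <- nchar(rep_seq)
  m <- nrow(spacers) + 1L
  parts <- character(0)
  rep_starts <- integer(0)
  sp_starts <- integer(0); sp_ends <- integer(0)
  is_span <- NULL
  pos <- 0L
  push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
  push(leader)
  leader_span <- c(0L, nchar(leader))
  for (j in seq_len(m)) {
    rep_starts <- c(rep_starts, pos)
    rj <- rep_seq
    if (j == m && cfg$degenerate_3prime && m >= 4L) {
      tail_pos <- (L - cfg$degeneracy_bp + 1L):L
      rj <- substitute_at(rj, tail_pos)
    }
    push(rj)
    if (j < m) {
      sp <- spacers$seq[j]
      if (!is.null(is_insert) && is_insert$after_spacer == j) {
        half <- nchar(sp) %/% 2L
        sp_starts <- c(sp_starts, pos)
        push(substr(sp, 1L, half))
        is_span <- c(pos, pos + nchar(is_insert$seq))
        push(is_insert$seq)
        push(substr(sp, half + 1L, nchar(sp)))
        sp_ends <- c(sp_ends, pos)
      } else {
        sp_starts <- c(sp_starts, pos)
        push(sp)
        sp_ends <- c(sp_ends, pos)
      }
    }
  }
  list(seq = paste(parts, collapse = ""), repeat_len = L,
       repeat_base = rep_seq, leader_span = leader_span,
       repeat_starts = rep_starts, spacer_starts = sp_starts,
       spacer_ends = sp_ends, is_span = is_span,
       split_spacer = if (is.null(is_insert)) NA_integer_
                      else is_insert$after_spacer,
       degenerate = cfg$degenerate_3prime && m >= 4L)
}

# ---------------------------------------------------------------------------
# the generator

#' Generate a synthetic multi-genome world
#'
#' See [world_config()] for the knobs.  Returns genomes (with annotations
#' and element spans), the mobile-element pool, and a ground-truth ledger
#' with exact array/spacer/cas/leader/group/anti-CRISPR coordinates.  Fixed
#' seed implies byte-identical output.
#'
#' @param config a [world_config()]
#' @return object of class `crispr_world`: list(genomes, elements, truth,
#'   config)
#' @export
generate_world <- function(config = world_config()) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, 0L), {
    # core templates
    templ <- .CORE_TEMPLATES
    tseqs <- lapply(seq_len(nrow(templ)), function(i) {
      if (templ$type[i] == "CDS") random_cds(templ$len[i])
      else random_seq(templ$len[i])
    })
    names(tseqs) <- templ$name
    is_template <- random_seq(cfg$is_len)

    # element pool
    elements <- list()
    mk <- function(class, n, len_rng) {
      for (i in seq_len(n)) {
        id <- paste0(substr(class, 1, 2), i)
        elements[[length(elements) + 1L]] <<-
          make_pool_element(id, class, sample(len_rng[1]:len_rng[2], 1L))
      }
    }
    mk("phage", cfg$pool$n_phage, c(6000L, 12000L))
    mk("plasmid", cfg$pool$n_plasmid, c(5000L, 10000L))
    mk("chromosome", cfg$pool$n_chromosome, c(15000L, 25000L))
    names(elements) <- vapply(elements, `[[`, "", "element_id")

    # leaders, one per locus, conserved across genomes
    leaders <- lapply(.LOCI, function(l)
      random_seq(cfg$leader_len, gc = 1 - cfg$leader_at))
    names(leaders) <- .LOCI

    # cas references / templates
    refs <- default_cas_refs()

    # anti-CRISPR spacer stack: windows of Ypest cas coding sequences
    anti_src <- refs[refs$subtype == "Ypest" &
                       refs$gene_name %in% c("cas1", "cas3", "csy2"), ]
    anti_stack <- local({
      rows <- list()
      prev_first <- NULL; prev_last <- NULL
      for (j in 1:7) {
        g <- anti_src[(j - 1L) %% nrow(anti_src) + 1L, ]
        w <- pick_window(g$cds, 32L, prev_first, prev_last)
        rows[[j]] <- data.frame(seq = w$seq, source_kind = "cas",
                                source_id = paste0("Ypest|", g$gene_name),
                                source_start = w$start, source_strand = w$strand,
                                n_mut = 0L, shared = TRUE,
                                stringsAsFactors = FALSE)
        prev_first <- first_char(w$seq); prev_last <- last_char(w$seq)
      }
      do.call(rbind, rows)
    })

    # ancestral spacer stacks (trailer-side, shared across genomes)
    stacks <- lapply(.LOCI, function(locus) {
      rows <- list()
      prev_first <- NULL; prev_last <- NULL
      src_pool <- if (locus %in% c("CRISPR3", "CRISPR4"))
        Filter(function(e) e$element_class == "plasmid", elements)
      else Filter(function(e) e$element_class == "phage", elements)
      for (j in seq_len(cfg$stack_size)) {
        len <- spacer_len_draw(cfg)
        row <- NULL
        if (length(src_pool) && stats::runif(1) < cfg$prov_fraction) {
          el <- src_pool[[sample.int(length(src_pool), 1L)]]
          w <- pick_window(el$seq, len, prev_first, prev_last)
          if (!is.null(w))
            row <- data.frame(seq = w$seq, source_kind = "element",
                              source_id = el$element_id, source_start = w$start,
                              source_strand = w$strand, n_mut = 0L,
                              shared = TRUE, stringsAsFactors = FALSE)
        }
        if (is.null(row))
          row <- data.frame(seq = random_spacer(len, prev_first, prev_last),
                            source_kind = "random", source_id = NA_character_,
                            source_start = NA_integer_,
                            source_strand = NA_character_, n_mut = 0L,
                            shared = TRUE, stringsAsFactors = FALSE)
        rows[[j]] <- row
        prev_first <- first_char(row$seq); prev_last <- last_char(row$seq)
      }
      do.call(rbind, rows)
    })
    names(stacks) <- .LOCI
    world <- list(templ = templ, tseqs = tseqs, is_template = is_template,
                  elements = elements, leaders = leaders, refs = refs,
                  anti_stack = anti_stack, stacks = stacks)
  })

  genomes <- vector("list", cfg$n_genomes)
  truth <- list(arrays = list(), spacers = list(), cas = list(),
                leaders = list(), groups = list(), anti = list())

  for (gi in seq_len(cfg$n_genomes)) {
    spec <- cfg$genome_specs[[gi]]
    gid <- sprintf("g%02d", gi)
    if (!is.null(spec$clone_of)) next   # second pass
    res <- with_seed(derive_seed(cfg$seed, gi), {
      build_one_genome(cfg, world, gid, spec)
    })
    genomes[[gi]] <- res$genome
    truth$arrays[[gi]] <- res$arrays
    truth$spacers[[gi]] <- res$spacers
    truth$cas[[gi]] <- res$cas
    truth$leaders[[gi]] <- res$leaders
    truth$anti[[gi]] <- data.frame(genome_id = gid,
                                   flagged = isTRUE(spec$anti3),
                                   stringsAsFactors = FALSE)
    if (!is.null(res$owned)) {
      for (eid in res$owned) world$elements[[eid]]$owner_genome <- gid
    }
  }

  # second pass: clones of already-built genomes
  group_id <- seq_len(cfg$n_genomes)
  for (gi in seq_len(cfg$n_genomes)) {
    spec <- cfg$genome_specs[[gi]]
    if (is.null(spec$clone_of)) next
    src <- spec$clone_of
    gid <- sprintf("g%02d", gi)
    parent <- genomes[[src]]
    child <- evolve_strain(parent, spec$clone_d, seed = derive_seed(cfg$seed, 5000L + gi))
    child$genome_id <- gid
    old_cid <- names(child$contigs)
    new_cid <- paste0(gid, ".chr")
    names(child$contigs) <- new_cid
    relabel_cid <- function(x) { x[x %in% old_cid] <- new_cid; x }
    child$genes$contig_id <- relabel_cid(child$genes$contig_id)
    child$genes$gene_id <- sub(paste0("^", parent$genome_id, "\\."),
                               paste0(gid, "."), child$genes$gene_id)
    if (nrow(child$element_spans))
      child$element_spans$contig_id <- relabel_cid(child$element_spans$contig_id)
    ps <- attr(child, "planted_spans")
    if (!is.null(ps)) {
      ps$contig_id <- relabel_cid(ps$contig_id)
      attr(child, "planted_spans") <- ps
    }
    genomes[[gi]] <- child
    relabel <- function(df) {
      if (is.null(df)) return(NULL)
      if (nrow(df)) {
        df$genome_id <- gid
        if ("contig_id" %in% names(df)) df$contig_id <- relabel_cid(df$contig_id)
      }
      df
    }
    truth$arrays[[gi]] <- relabel(truth$arrays[[src]])
    truth$spacers[[gi]] <- relabel(truth$spacers[[src]])
    truth$cas[[gi]] <- relabel(truth$cas[[src]])
    truth$leaders[[gi]] <- relabel(truth$leaders[[src]])
    truth$anti[[gi]] <- relabel(truth$anti[[src]])
    group_id[gi] <- group_id[src]
  }

  truth <- lapply(truth, function(x) {
    x <- Filter(Negate(is.null), x)
    if (length(x)) do.call(rbind, x) else NULL
  })
  truth$groups <- data.frame(genome_id = vapply(genomes, `[[`, "", "genome_id"),
                             group_id = match(group_id, unique(group_id)),
                             stringsAsFactors = FALSE)
  truth$elements <- data.frame(
    element_id = vapply(world$elements, `[[`, "", "element_id"),
    element_class = vapply(world$elements, `[[`, "", "element_class"),
    owner_genome = vapply(world$elements, `[[`, "", "owner_genome"),
    stringsAsFactors = FALSE)
  rownames(truth$elements) <- NULL

  structure(list(genomes = genomes, elements = unname(world$elements),
                 truth = truth, config = cfg),
            class = "crispr_world")
}

#' @export
print.crispr_world <- function(x, ...) {
  cat("<crispr_world>", length(x$genomes), "genomes,",
      length(x$elements), "pool elements,",
      if (!is.null(x$truth$arrays)) nrow(x$truth$arrays) else 0L,
      "planted arrays\n")
  invisible(x)
}

# Build one genome: returns genome, per-genome truth tables, owned elements.
#' @keywords internal
build_one_genome <- function(cfg, world, gid, spec) {
  contig_id <- paste0(gid, ".chr")
  parts <- character(0)
  pos <- 0L
  genes <- list()
  spans <- list()
  arr_truth <- list()
  sp_truth <- list()
  cas_truth <- list()
  leader_truth <- list()
  push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
  bg <- function(n) push(random_seq(n))
  add_gene <- function(name, strand = "+") {
    i <- match(name, world$templ$name)
    tmpl <- world$tseqs[[name]]
    dna <- if (world$templ$type[i] == "CDS") mutate_cds(tmpl, cfg$gene_mut)
           else mutate_seq(tmpl, cfg$gene_mut)$seq
    placed <- if (strand == "-") revcomp(dna) else dna
    st <- pos
    push(placed)
    prot <- if (world$templ$type[i] == "CDS")
      derive_protein_str(dna) else NA_character_
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = paste0(gid, ".", name), contig_id = contig_id,
      start = st, end = pos, strand = strand,
      type = world$templ$type[i], product = name, protein = prot,
      stringsAsFactors = FALSE)
  }

  # repeat-count draws (CRISPR2 correlated with CRISPR1)
  rr <- cfg$array_repeats
  n1 <- sample(rr$CRISPR1[1]:rr$CRISPR1[2], 1L)
  n2 <- max(rr$CRISPR2[1], min(rr$CRISPR2[2], n1 + sample(-2:2, 1L)))
  if (identical(spec$is_disrupt, "CRISPR2")) n2 <- max(n2, 8L)
  n3 <- if (isTRUE(spec$anti3)) sample(cfg$anti_repeats[1]:cfg$anti_repeats[2], 1L)
        else sample(rr$CRISPR3[1]:rr$CRISPR3[2], 1L)
  n4 <- sample(rr$CRISPR4[1]:rr$CRISPR4[2], 1L)
  n_rep <- c(CRISPR1 = n1, CRISPR2 = n2, CRISPR3 = n3, CRISPR4 = n4)

  add_array <- function(locus) {
    repeat_base <- if (locus %in% c("CRISPR1", "CRISPR2")) cfg$repeat1 else cfg$repeat2
    leader <- mutate_seq(world$leaders[[locus]], cfg$leader_mut)$seq
    m <- n_rep[[locus]]
    extra <- list()
    if (locus == "CRISPR1" && isTRUE(spec$self_prophage_spacer))
      extra[["1"]] <- list(seq = world$elements[[1]]$seq, kind = "element",
                           id = world$elements[[1]]$element_id)
    if (locus == "CRISPR4" && isTRUE(spec$self_plasmid_spacer) &&
        length(owned_ids))
      extra[["1"]] <- list(seq = world$elements[[owned_ids[1]]]$seq,
                           kind = "element", id = owned_ids[1])
    if (locus == "CRISPR3" && isTRUE(spec$anti3)) {
      k <- m - 1L
      run <- world$anti_stack[seq_len(min(k, nrow(world$anti_stack))), ,
                              drop = FALSE]
      spacers <- run[rev(seq_len(nrow(run))), , drop = FALSE]  # anchor trailer-side
      # leader junction: first spacer must differ from leader last char
      if (last_char(spacers$seq[1]) == last_char(leader))
        leader <- set_char(leader, nchar(leader),
                           sample(setdiff(.BASES, last_char(spacers$seq[1])), 1L))
      m <- nrow(spacers) + 1L
    } else {
      spacers <- gen_array_spacers(cfg, m - 1L, locus, world$elements,
                                   world$stacks[[locus]],
                                   last_char(leader), extra)
    }
    is_insert <- NULL
    if (identical(spec$is_disrupt, locus))
      is_insert <- list(seq = world$is_template, after_spacer = m %/% 2L)
    seg <- build_array_segment(cfg, repeat_base, leader, spacers, is_insert)
    st <- pos
    push(seg$seq)
    # trailing junction: next segment must not extend the final repeat column
    trailer_guard <<- first_char(spacers$seq[nrow(spacers)])
    arr_start <- st + seg$repeat_starts[1]
    arr_end <- st + seg$repeat_starts[length(seg$repeat_starts)] + seg$repeat_len
    arr_truth[[length(arr_truth) + 1L]] <<- data.frame(
      genome_id = gid, locus = locus, contig_id = contig_id,
      start = arr_start, end = arr_end,
      n_repeats = length(seg$repeat_starts), repeat_len = seg$repeat_len,
      repeat_base = seg$repeat_base,
      leader_start = st, leader_end = st + seg$leader_span[2],
      degenerate_3p = seg$degenerate,
      is_disrupted = !is.null(seg$is_span),
      is_start = if (!is.null(seg$is_span)) st + seg$is_span[1] else NA_integer_,
      is_end = if (!is.null(seg$is_span)) st + seg$is_span[2] else NA_integer_,
      repeat_starts = I(list(st + seg$repeat_starts)),
      stringsAsFactors = FALSE)
    if (!is.null(seg$is_span))
      spans[[length(spans) + 1L]] <<- data.frame(
        contig_id = contig_id, start = st + seg$is_span[1],
        end = st + seg$is_span[2], class = "IS", stringsAsFactors = FALSE)
    sp_truth[[length(sp_truth) + 1L]] <<- data.frame(
      genome_id = gid, locus = locus,
      index_from_leader = seq_len(nrow(spacers)) - 1L,
      seq = spacers$seq,
      start = st + seg$spacer_starts, end = st + seg$spacer_ends,
      source_kind = spacers$source_kind, source_id = spacers$source_id,
      source_start = spacers$source_start,
      source_strand = spacers$source_strand,
      n_mut = spacers$n_mut, shared = spacers$shared,
      split_by_is = !is.na(seg$split_spacer) &
        seq_len(nrow(spacers)) == seg$split_spacer,
      stringsAsFactors = FALSE)
    leader_truth[[length(leader_truth) + 1L]] <<- data.frame(
      genome_id = gid, locus = locus, contig_id = contig_id,
      start = st, end = st + seg$leader_span[2],
      at_fraction = at_fraction(leader), stringsAsFactors = FALSE)
  }

  add_operon <- function(cas) {
    subtype <- cas$subtype
    refs <- world$refs[world$refs$subtype == subtype, ]
    pseudo <- cas$pseudo
    states <- list()
    for (i in seq_len(nrow(refs))) {
      gname <- refs$gene_name[i]
      if (identical(cas$state, "relic") && !(gname %in% names(pseudo))) {
        states[[length(states) + 1L]] <- data.frame(
          genome_id = gid, subtype = subtype, gene = gname,
          status = "absent", start = NA_integer_, end = NA_integer_,
          pseudo_kind = NA_character_, stringsAsFactors = FALSE)
        next
      }
      dna <- mutate_cds(refs$cds[i], cfg$gene_mut)
      kind <- if (gname %in% names(pseudo)) pseudo[[gname]] else NA_character_
      status <- "intact"
      if (!is.na(kind)) {
        status <- "pseudo"
        if (kind == "frameshift") {
          cut <- nchar(dna) %/% 2L
          dna <- paste0(substr(dna, 1L, cut - 1L),
                        substr(dna, cut + 1L, nchar(dna)))
        } else {  # truncation
          dna <- substr(dna, 1L, max(90L, as.integer(nchar(dna) * 0.4)))
        }
      }
      st <- pos
      push(dna)
      if (status == "intact")
        genes[[length(genes) + 1L]] <<- data.frame(
          gene_id = paste0(gid, ".", subtype, ".", gname),
          contig_id = contig_id, start = st, end = pos, strand = "+",
          type = "CDS", product = paste(subtype, gname),
          protein = derive_protein_str(dna), stringsAsFactors = FALSE)
      states[[length(states) + 1L]] <- data.frame(
        genome_id = gid, subtype = subtype, gene = gname, status = status,
        start = st, end = pos, pseudo_kind = kind, stringsAsFactors = FALSE)
      bg(sample(30:90, 1L))
    }
    cas_truth[[length(cas_truth) + 1L]] <<- do.call(rbind, states)
  }

  owned_ids <- character(0)
  if (!is.null(spec$plasmids) && spec$plasmids > 0L) {
    plas <- names(world$elements)[vapply(world$elements, function(e)
      e$element_class == "plasmid" && is.na(e$owner_genome), logical(1))]
    owned_ids <- utils::head(plas, spec$plasmids)
  }
  trailer_guard <- NULL
  guard_bg <- function(n) {
    s <- random_seq(n)
    if (!is.null(trailer_guard) && first_char(s) == trailer_guard)
      s <- set_char(s, 1L, sample(setdiff(.BASES, trailer_guard), 1L))
    trailer_guard <<- NULL
    push(s)
  }

  loci <- spec$loci %||% character(0)
  bg(sample(2500:4000, 1L))
  for (f in c("fill1", "fill2", "fill3", "fill4")) {
    add_gene(f, strand = sample(c("+", "-"), 1L)); bg(sample(150:400, 1L))
  }
  add_gene("cysD"); bg(180L)
  if ("CRISPR1" %in% loci) { add_array("CRISPR1"); guard_bg(220L) }
  if (!is.null(spec$cas) && spec$cas$subtype == "Ecoli" &&
      spec$cas$state %in% c("intact", "partial", "relic"))
    add_operon(spec$cas)
  else if (!is.null(spec$cas) && spec$cas$subtype == "Ecoli")
    cas_truth[[length(cas_truth) + 1L]] <- data.frame(
      genome_id = gid, subtype = "Ecoli", gene = cas_subtype_genes("Ecoli"),
      status = "absent", start = NA_integer_, end = NA_integer_,
      pseudo_kind = NA_character_, stringsAsFactors = FALSE)
  bg(150L)
  add_gene("cysJ"); bg(200L)
  if ("CRISPR2" %in% loci) { add_array("CRISPR2"); guard_bg(250L) }
  add_gene("ygcF")
  bg(sample(1800:2600, 1L))
  for (f in c("fill5", "fill6")) {
    add_gene(f, strand = sample(c("+", "-"), 1L)); bg(sample(150:400, 1L))
  }
  add_gene("clpS"); bg(160L)
  if ("CRISPR3" %in% loci) { add_array("CRISPR3"); guard_bg(200L) }
  if (!is.null(spec$cas) && spec$cas$subtype == "Ypest" &&
      spec$cas$state %in% c("intact", "partial", "relic"))
    add_operon(spec$cas)
  bg(120L)
  add_gene("tRNA-Ser"); bg(160L)
  if ("CRISPR4" %in% loci) { add_array("CRISPR4"); guard_bg(200L) }
  add_gene("infA"); bg(sample(150:300, 1L))
  add_gene("aat")
  bg(sample(400:800, 1L))
  for (f in c("fill7", "fill8")) {
    add_gene(f, strand = sample(c("+", "-"), 1L)); bg(sample(150:400, 1L))
  }
  if (isTRUE(spec$prophage)) {
    bg(1200L)
    ph <- world$elements[[1]]
    st <- pos
    push(ph$seq)
    spans[[length(spans) + 1L]] <- data.frame(
      contig_id = contig_id, start = st, end = pos, class = "prophage",
      stringsAsFactors = FALSE)
  }
  # a couple of standalone IS copies in the backbone
  bg(900L); st <- pos; push(world$is_template)
  spans[[length(spans) + 1L]] <- data.frame(contig_id = contig_id, start = st,
                                            end = pos, class = "IS",
                                            stringsAsFactors = FALSE)
  if (pos > cfg$genome_length)
    stop("genome_length too small for requested content (need at least ",
         pos, " bp)")
  bg(cfg$genome_length - pos)

  contig <- paste(parts, collapse = "")
  genome <- new_genome(gid, stats::setNames(contig, contig_id),
                       genes = do.call(rbind, c(genes, list(empty_genes()))),
                       element_spans = do.call(rbind, c(spans, list(empty_spans()))))
  arrays_df <- if (length(arr_truth)) do.call(rbind, arr_truth) else NULL
  if (!is.null(arrays_df))
    attr(genome, "planted_spans") <- data.frame(
      contig_id = arrays_df$contig_id, start = arrays_df$start,
      end = arrays_df$end, stringsAsFactors = FALSE)
  list(genome = genome,
       arrays = arrays_df,
       spacers = if (length(sp_truth)) do.call(rbind, sp_truth) else NULL,
       cas = if (length(cas_truth)) do.call(rbind, cas_truth) else NULL,
       leaders = if (length(leader_truth)) do.call(rbind, leader_truth) else NULL,
       owned = if (length(owned_ids)) owned_ids else NULL)
}

#' @keywords internal
derive_protein_str <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Evolve a strain by point substitutions
#'
#' Applies substitutions at expected per-site density `d`, uniformly over
#' the genome but outside planted CRISPR arrays by default (closely related
#' strains carry identical arrays).  Annotations are carried over unchanged
#' (substitutions only, no indels).
#'
#' @param genome a genome object
#' @param d substitutions per site, in \[0, 0.05\]
#' @param seed integer seed
#' @param exclude_spans data frame (contig_id, start, end) of spans to leave
#'   untouched; defaults to the genome's planted-array attribute
#' @return the evolved genome
#' @export
evolve_strain <- function(genome, d, seed = 1L, exclude_spans = NULL) {
  if (d < 0 || d > 0.05) stop("evolve_strain: d out of [0, 0.05]")
  if (is.null(exclude_spans))
    exclude_spans <- attr(genome, "planted_spans")
  out <- genome
  with_seed(seed, {
    for (cid in names(out$contigs)) {
      s <- out$contigs[[cid]]
      n <- nchar(s)
      eligible <- rep(TRUE, n)
      if (!is.null(exclude_spans) && nrow(exclude_spans)) {
        ex <- exclude_spans[exclude_spans$contig_id == cid, , drop = FALSE]
        for (i in seq_len(nrow(ex)))
          eligible[(ex$start[i] + 1L):ex$end[i]] <- FALSE
      }
      idx <- which(eligible)
      k <- stats::rbinom(1L, length(idx), d)
      if (k > 0L) {
        posn <- sample(idx, k)
        out$contigs[[cid]] <- substitute_at(s, sort(posn))
      }
    }
  })
  out
}

#' Plant an anti-CRISPR scenario into a genome
#'
#' Replaces `k` spacers of the genome's CRISPR3-anchored array with
#' >= 95%-identity copies of windows of the given cas reference coding
#' sequences, and removes the cognate cas operon (if present).  The
#' spacer/provenance changes are recorded in the `anti_truth` attribute of
#' the returned genome.
#'
#' @param genome a genome with a CRISPR3-anchored array (between the clpS
#'   and tRNA-Ser core genes)
#' @param cas_refs reference data frame (see [default_cas_refs()]); the
#'   Ypest rows are used
#' @param k number of spacers to convert (0 = only remove the operon)
#' @param seed integer seed
#' @param params detector parameters used to locate the array
#' @return the modified genome
#' @export
plant_anti_crispr <- function(genome, cas_refs = default_cas_refs(), k = 2L,
                              seed = 1L, params = detector_params()) {
  genes <- genome$genes
  clp <- genes[genes$product == "clpS", , drop = FALSE]
  trn <- genes[genes$product == "tRNA-Ser", , drop = FALSE]
  if (!nrow(clp) || !nrow(trn))
    stop("plant_anti_crispr: clpS / tRNA-Ser anchors not found")
  cid <- clp$contig_id[1]
  contig <- genome$contigs[[cid]]
  arrs <- detect_arrays(contig, params, contig_id = cid)
  in_region <- Filter(function(a) a$start >= clp$end[1] && a$end <= trn$start[1],
                      arrs)
  if (!length(in_region))
    stop("plant_anti_crispr: no CRISPR3 array between clpS and tRNA-Ser")
  arr <- extract_spacers(in_region[[1]], contig, params)
  ypest <- cas_refs[cas_refs$subtype == "Ypest", , drop = FALSE]
  anti_rows <- list()
  with_seed(seed, {
    k_use <- min(k, nrow(arr$spacers))
    for (j in seq_len(k_use)) {
      sp <- arr$spacers[j, ]
      len <- sp$end - sp$start
      g <- ypest[sample.int(nrow(ypest), 1L), ]
      # keep the original boundary characters so the planted array stays
      # boundary-identifiable; windows are plentiful, editing is a fallback
      w <- pick_window(g$cds, len,
                       not_first = setdiff(.BASES, first_char(sp$seq)),
                       not_last = setdiff(.BASES, last_char(sp$seq)),
                       tries = 5000L)
      n_mut <- 0L
      if (is.null(w)) {
        w <- pick_window(g$cds, len, tries = 5000L)
        w$seq <- set_char(w$seq, 1L, first_char(sp$seq))
        w$seq <- set_char(w$seq, len, last_char(sp$seq))
        n_mut <- 2L
      }
      substr(contig, sp$start + 1L, sp$end) <- w$seq
      anti_rows[[j]] <- data.frame(spacer_index = j - 1L,
                                   gene_name = g$gene_name,
                                   source_start = w$start, n_mut = n_mut,
                                   stringsAsFactors = FALSE)
    }
  })
  genome$contigs[[cid]] <- contig
  # remove a cognate (Ypest) operon between the array and tRNA-Ser
  ypest_genes <- genes[grepl("^Ypest ", genes$product) &
                         genes$contig_id == cid, , drop = FALSE]
  if (nrow(ypest_genes)) {
    del <- c(min(ypest_genes$start) - 10L, max(ypest_genes$end) + 10L)
    genome <- splice_out(genome, cid, del[1], del[2])
  }
  attr(genome, "anti_truth") <- if (length(anti_rows))
    do.call(rbind, anti_rows)
  else data.frame(spacer_index = integer(0), gene_name = character(0),
                  source_start = integer(0), n_mut = integer(0))
  genome
}

# remove [start, end) from a contig, shifting annotations; genes inside the
# cut are dropped
#' @keywords internal
splice_out <- function(genome, contig_id, start, end) {
  s <- genome$contigs[[contig_id]]
  genome$contigs[[contig_id]] <-
    paste0(substr(s, 1L, start), substr(s, end + 1L, nchar(s)))
  w <- end - start
  shift <- function(df) {
    if (!nrow(df)) return(df)
    on <- df$contig_id == contig_id
    drop <- on & df$start < end & df$end > start
    df <- df[!drop, , drop = FALSE]
    on <- df$contig_id == contig_id
    late <- on & df$start >= end
    df$start[late] <- df$start[late] - w
    df$end[late] <- df$end[late] - w
    df
  }
  genome$genes <- shift(genome$genes)
  genome$element_spans <- shift(genome$element_spans)
  ps <- attr(genome, "planted_spans")
  if (!is.null(ps)) attr(genome, "planted_spans") <- shift(ps)
  genome
}

#' Write a world to disk
#'
#' Emits FASTA + GFF3 per genome, the element pool as FASTA + class TSV, and
#' the truth ledger as JSON.
#'
#' @param world a `crispr_world`
#' @param out_dir output directory
#' @return invisibly, the output directory
#' @export
write_world <- function(world, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in world$genomes) {
    write_genome(g, file.path(out_dir, paste0(g$genome_id, ".fna")),
                 file.path(out_dir, paste0(g$genome_id, ".gff3")))
  }
  write_elements(world$elements, file.path(out_dir, "elements.fna"),
                 file.path(out_dir, "elements.tsv"))
  tr <- world$truth
  tr$arrays$repeat_starts <- NULL
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(out_dir)
}
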