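# Genome distances, closely-related-strain grouping, divergence-time
# estimators and the repeat-count correlation statistic.
#
# Distances are p-distances (fraction of differing aligned positions); at
# the 0.02% grouping threshold multiple hits are negligible, so the
# uncorrected distance is model-robust (a Jukes-Cantor toggle is provided).

#' p-distance between two aligned sequences
#'
#' @param a,b equal-length aligned nucleotide strings; columns with a
#'   non-ACGT character in either sequence are excluded
#' @param jc apply the Jukes-Cantor correction
#' @return substitutions per site
#' @export
p_distance <- function(a, b, jc = FALSE) {
  ea <- seq_ints(a)
  eb <- seq_ints(b)
  if (length(ea) != length(eb))
    stop("p_distance: sequences must have equal length")
  ok <- !is.na(ea) & !is.na(eb)
  if (!any(ok)) stop("p_distance: no comparable columns")
  d <- mean(ea[ok] != eb[ok])
  if (jc) {
    if (d >= 0.75) stop("p_distance: saturation, JC undefined")
    d <- -3 / 4 * log(1 - 4 * d / 3)
  }
  d
}

#' @keywords internal
concat_contigs <- function(genome) paste(genome$contigs, collapse = "")

#' @keywords internal
core_concat <- function(genome, core) {
  fams <- core[core$genome_id == genome$genome_id, , drop = FALSE]
  fams <- fams[order(fams$family_id), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(fams)), function(i) {
    g <- genome$genes[genome$genes$gene_id == fams$gene_id[i], ]
    s <- substr(genome$contigs[[g$contig_id]], g$start + 1L, g$end)
    if (g$strand == "-") revcomp(s) else s
  }, "")
  names(pieces) <- fams$family_id
  pieces
}

#' Pairwise distance matrix across genomes
#'
#' `method = "core"` compares concatenated core-gene sequences (families
#' whose lengths differ between genomes are dropped); `method = "genome"`
#' compares whole chromosomes position-by-position, which is appropriate
#' for colinear strains (unrelated genomes saturate far above any grouping
#' threshold).
#'
#' @param genomes list of genome objects
#' @param method "core" or "genome"
#' @param core core-family table (required for `method = "core"`)
#' @param jc Jukes-Cantor correction toggle
#' @return symmetric matrix of substitutions/site with genome ids as
#'   dimnames
#' @export
distance_matrix <- function(genomes, method = c("genome", "core"),
                            core = NULL, jc = FALSE) {
  method <- match.arg(method)
  ids <- vapply(genomes, `[[`, "", "genome_id")
  n <- length(genomes)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  seqs <- if (method == "genome") {
    lapply(genomes, concat_contigs)
  } else {
    if (is.null(core)) stop("distance_matrix: core table required")
    pieces <- lapply(genomes, core_concat, core = core)
    fams <- Reduce(intersect, lapply(pieces, names))
    keep <- fams[vapply(fams, function(f)
      length(unique(vapply(pieces, function(p) nchar(p[[f]]), integer(1)))) == 1L,
      logical(1))]
    lapply(pieces, function(p) paste(p[keep], collapse = ""))
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    L <- min(nchar(seqs[[i]]), nchar(seqs[[j]]))
    d <- p_distance(substr(seqs[[i]], 1L, L), substr(seqs[[j]], 1L, L),
                    jc = jc)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Group closely related strains
#'
#' Single-linkage components of the graph whose edges join genomes at
#' distance strictly below `threshold` (default 0.02% substitutions per
#' position).  The representative of a group is its lexicographically
#' first genome id.
#'
#' @param D distance matrix from [distance_matrix()]
#' @param threshold grouping distance (default 2e-4)
#' @return data frame: genome_id, group_id, representative
#' @export
group_close_strains <- function(D, threshold = 2e-4) {
  ids <- rownames(D)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq_len(n)[-seq_len(i)]) {
    if (D[i, j] < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  gid <- match(root, unique(root))
  reps <- vapply(split(ids, gid), function(x) sort(x)[1], "")
  data.frame(genome_id = ids, group_id = gid,
             representative = reps[as.character(gid)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Molecular-clock divergence time
#'
#' `years = d / mu_year`.  At the published clock of 7.6e-10
#' substitutions/site/year, a 0.02% divergence dates to about 263,000
#' years.
#'
#' @param d substitutions per site
#' @param mu_year substitutions per site per year (default 7.6e-10)
#' @return years since divergence
#' @export
clock_years <- function(d, mu_year = 7.6e-10) {
  if (mu_year <= 0) stop("clock_years: mu_year must be positive")
  if (any(d < 0)) stop("clock_years: d must be non-negative")
  d / mu_year
}

#' Parameters of the conservative neutral dating
#'
#' Defaults: genomic mutation rate 1e-3 per generation, 5 Mb genome,
#' recombination contributing 2.5 times the polymorphism input of
#' mutation, 40 h doubling time, 8766 h per (Julian) year.
#'
#' @param U genomic mutations per generation
#' @param G genome size (bp)
#' @param rho_ratio recombination-to-mutation polymorphism input ratio
#' @param gen_hours hours per generation
#' @param hours_per_year hours per year
#' @param mu_year molecular-clock rate (substitutions/site/year)
#' @return named list of validated parameters
#' @export
divergence_params <- function(U = 1e-3, G = 5e6, rho_ratio = 2.5,
                              gen_hours = 40, hours_per_year = 8766,
                              mu_year = 7.6e-10) {
  p <- list(U = U, G = G, rho_ratio = rho_ratio, gen_hours = gen_hours,
            hours_per_year = hours_per_year, mu_year = mu_year)
  if (any(unlist(p) <= 0)) stop("divergence_params: all values must be positive")
  p
}

#' Conservative neutral-accumulation dating
#'
#' Per-site polymorphism input per generation is
#' `r = (U / G) * (1 + rho_ratio)`; the divergence `d` then corresponds to
#' `d / r` generations, converted to years via the doubling time.  With the
#' defaults, a 0.02% divergence gives about 286,000 generations
#' (~300,000 at one significant figure) and about 1,300 years.
#'
#' @param d substitutions per site
#' @param params [divergence_params()]
#' @return list: generations, years
#' @export
neutral_generations <- function(d, params = divergence_params()) {
  if (any(d < 0)) stop("neutral_generations: d must be non-negative")
  r <- (params$U / params$G) * (1 + params$rho_ratio)
  gen <- d / r
  list(generations = gen, years = gen * params$gen_hours / params$hours_per_year)
}

#' Squared correlation of repeat counts with a permutation p-value
#'
#' @param counts_x,counts_y paired per-genome repeat counts (length >= 3,
#'   both non-constant)
#' @param n_perm number of label permutations (default 10000)
#' @param seed RNG seed
#' @return list: r_squared, p_perm (one-sided, add-one smoothed), n
#' @export
repeat_correlation <- function(counts_x, counts_y, n_perm = 10000L,
                               seed = 1L) {
  if (length(counts_x) != length(counts_y) || length(counts_x) < 3L)
    stop("repeat_correlation: need paired counts of length >= 3")
  if (stats::sd(counts_x) == 0 || stats::sd(counts_y) == 0)
    stop("repeat_correlation: constant input, correlation undefined")
  r2 <- stats::cor(counts_x, counts_y)^2
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stats::cor(counts_x, sample(counts_y))^2, numeric(1)))
  list(r_squared = r2,
       p_perm = (1 + sum(perm >= r2)) / (n_perm + 1),
       n = length(counts_x))
}
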