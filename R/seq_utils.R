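# Low-level nucleotide utilities shared by all modules.  Sequences are plain
# uppercase character strings over {A,C,G,T,N}; positions are 0-based
# half-open internally (GFF conversion happens at the I/O boundary).

.BASE_LUT <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("ACGT") ] <- 0:3
  lut
})

.BASES <- c("A", "C", "G", "T")

#' Encode a nucleotide string as integers
#'
#' A=0, C=1, G=2, T=3; any other character (including N) becomes `NA` so that
#' every identity computation treats it as a mismatch.
#'
#' @param s a single nucleotide string
#' @return integer vector of length `nchar(s)`
#' @keywords internal
seq_ints <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  .BASE_LUT[utf8ToInt(s)]
}

#' @keywords internal
ints_seq <- function(v) {
  out <- rep("N", length(v))
  ok <- !is.na(v)
  out[ok] <- .BASES[v[ok] + 1L]
  paste(out, collapse = "")
}

#' Reverse complement
#'
#' @param s nucleotide string (IUPAC W is complemented to itself)
#' @return the reverse complement string
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  intToUtf8(rev(utf8ToInt(chartr("ACGTNWacgtn", "TGCANWtgcan", s))))
}

#' @keywords internal
random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Fraction of identical positions between two equal-length encodings
#'
#' `NA` (ambiguous bases) count as mismatches.
#' @keywords internal
ident_frac <- function(a, b) {
  if (length(a) != length(b)) stop("ident_frac: unequal lengths")
  if (length(a) == 0L) return(NA_real_)
  sum(!is.na(a) & !is.na(b) & a == b) / length(a)
}

#' @keywords internal
ident_frac_str <- function(x, y) ident_frac(seq_ints(x), seq_ints(y))

#' Rolling k-mer integer codes
#'
#' Base-4 polynomial code of every k-window; windows containing non-ACGT
#' characters get `NA`.
#' @keywords internal
kmer_codes <- function(enc, k) {
  n <- length(enc)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  v <- as.numeric(enc)
  for (j in 0:(k - 1L)) {
    code <- code + v[(1L + j):(m + j)] * 4^(k - 1L - j)
  }
  code
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Stable derived seed streams (kept below 2^31).
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Integer percentage, rounded half-up
#'
#' Matches the rounding style of published summary tables (e.g. 505/594 -> 85).
#' @param num,den numerator and denominator counts
#' @return integer percentage
#' @export
pct_int <- function(num, den) {
  if (any(den == 0)) stop("pct_int: zero denominator")
  as.integer(floor(100 * num / den + 0.5))
}

#' @keywords internal
at_fraction <- function(s) {
  v <- seq_ints(s)
  if (!length(v)) return(NA_real_)
  mean(v %in% c(0L, 3L))
}

# Mutate a nucleotide string at given 1-based positions to a different,
# randomly chosen base.  Returns the new string.
#' @keywords internal
substitute_at <- function(s, pos) {
  if (!length(pos)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# Point-mutate a string at a per-site rate (no indels); returns list(seq, pos).
#' @keywords internal
mutate_seq <- function(s, rate) {
  n <- nchar(s)
  if (rate <= 0 || n == 0L) return(list(seq = s, pos = integer(0)))
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(list(seq = s, pos = integer(0)))
  pos <- sort(sample.int(n, k))
  list(seq = substitute_at(s, pos), pos = pos)
}
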