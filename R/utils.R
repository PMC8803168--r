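# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that
# generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# GC fraction over A/C/G/T characters; other characters (N, gaps) are
# excluded from the denominator.
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(chars %in% c("G", "C")) / sum(acgt)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# 0-based half-open subsequence of a linear sequence given as a character
# string: positions [start, end).
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# Distance (bp) from a 0-based point to a 0-based half-open interval;
# 0 when the point lies inside.
point_interval_distance <- function(pos, start, end) {
  d <- pmax(start - pos, pos - (end - 1L))
  pmax(d, 0L)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
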