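# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
# Every public operation that uses randomness draws from one stream seeded
# here, so results are reproducible and independent of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# reverse complement without Biostrings S4 dispatch (hot path)
revcomp <- function(x) {
  x <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

# Substitute a fraction of positions, always to a different base.
# Returns the mutated string; positions drawn without replacement.
mutate_substitutions <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) {
    alt <- setdiff(DNA_BASES, chars[p])
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(sprintf("%s must be a single non-empty DNA string", what),
         call. = FALSE)
  invisible(x)
}

# Pairwise global alignment via the package's banded Needleman-Wunsch.
# band = 0 -> full DP. Identity counts gap columns in the denominator.
sat_align <- function(a, b, band = 0L) {
  assert_dna(a, "sequence a"); assert_dna(b, "sequence b")
  .nw_align_cpp(toupper(a), toupper(b), as.integer(band))
}

alignment_identity <- function(a, b, band = 0L) sat_align(a, b, band)$identity
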