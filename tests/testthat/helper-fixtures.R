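# Shared fixture builders. All randomness is locally seeded so tests are
# deterministic and order-independent.

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# substitute exactly round(d * nchar) positions, always to another base
mutate_dna <- function(s, d, seed = NULL) {
  gen <- function() {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(d * length(ch)))
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample(3, 1)]
    paste(ch, collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

hamming_div <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# tandem array of one monomer with per-copy substitutions
tandem <- function(monomer, n_copies, sub = 0, seed = 1) {
  withr::with_seed(seed, {
    paste(vapply(seq_len(n_copies), function(i)
      if (sub > 0) mutate_dna(monomer, sub) else monomer, character(1)),
      collapse = "")
  })
}

# two-arm pair sharing mutated copies of `donor` with flanking random DNA
shared_arm_pair <- function(donor, per_copy_div, flankA = c(15000, 8000),
                            flankB = c(5000, 12000), seed = 1) {
  withr::with_seed(seed, {
    list(a = paste0(rand_dna(flankA[1]), mutate_dna(donor, per_copy_div),
                    rand_dna(flankA[2])),
         b = paste0(rand_dna(flankB[1]), mutate_dna(donor, per_copy_div),
                    rand_dna(flankB[2])),
         a_start = flankA[1], b_start = flankB[1])
  })
}
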