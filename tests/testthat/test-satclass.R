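# Profile training, monomer classification, array annotation, dimhaps,
# k-mer signatures.

make_two_family_profiles <- function(div = 0.25, seed = 50) {
  consA <- rand_dna(170, seed = seed)
  consB <- mutate_dna(consA, div, seed = seed + 1)
  monoA <- withr::with_seed(seed + 2, vapply(1:10, function(i)
    mutate_dna(consA, 0.02), character(1)))
  monoB <- withr::with_seed(seed + 3, vapply(1:10, function(i)
    mutate_dna(consB, 0.02), character(1)))
  list(profiles = train_profiles(list(A = monoA, B = monoB)),
       consA = consA, consB = consB)
}

test_that("train_profiles produces self-consistent profiles", {
  mono <- rand_dna(150, seed = 60)
  ps <- train_profiles(list(F1 = rep(mono, 10)))
  prof <- ps$profiles$F1
  # profile consensus call equals the training monomer
  called <- paste(c("A", "C", "G", "T")[apply(prof$logodds, 1, which.max)],
                  collapse = "")
  expect_equal(called, mono)
  expect_false(prof$low_confidence)
  expect_equal(ps$training_counts[["F1"]], 10L)

  # own consensus scores higher under own profile, both ways
  fx <- make_two_family_profiles()
  sAA <- satarch:::score_profile(fx$consA, fx$profiles$profiles$A)
  sAB <- satarch:::score_profile(fx$consA, fx$profiles$profiles$B)
  sBB <- satarch:::score_profile(fx$consB, fx$profiles$profiles$B)
  sBA <- satarch:::score_profile(fx$consB, fx$profiles$profiles$A)
  expect_gt(sAA, sAB)
  expect_gt(sBB, sBA)

  expect_error(train_profiles(list(A = character(0))), "no training")
})

test_that("pseudocount controls unseen-base scores", {
  mono <- rand_dna(100, seed = 61)
  other <- paste0(if (substr(mono, 1, 1) == "A") "C" else "A",
                  substr(mono, 2, 100))
  ps0 <- train_profiles(list(F1 = rep(mono, 5)), pseudocount = 0)
  expect_equal(satarch:::score_profile(other, ps0$profiles$F1), -Inf)
  ps1 <- train_profiles(list(F1 = rep(mono, 5)), pseudocount = 0.01)
  expect_true(is.finite(satarch:::score_profile(other, ps1$profiles$F1)))
})

test_that("classify_monomers assigns family and strand, brute-force checked", {
  fx <- make_two_family_profiles()
  # the consensus itself
  hit <- classify_monomers(fx$consA, fx$profiles)
  expect_equal(hit$family, "A")
  expect_equal(hit$strand, "+")
  expect_gt(hit$margin, 0)
  # its reverse complement flips strand, keeps family
  hit_rc <- classify_monomers(satarch:::revcomp(fx$consA), fx$profiles)
  expect_equal(hit_rc$family, "A")
  expect_equal(hit_rc$strand, "-")

  # 10% from A, ~25% from B: A wins (cross-check by exhaustive scoring)
  q <- mutate_dna(fx$consA, 0.10, seed = 77)
  hit_q <- classify_monomers(q, fx$profiles)
  expect_equal(hit_q$family, "A")
  best_direct <- which.max(c(
    satarch:::score_profile(q, fx$profiles$profiles$A),
    satarch:::score_profile(q, fx$profiles$profiles$B)))
  expect_equal(best_direct, 1L)

  # order independence
  monos <- withr::with_seed(78, vapply(1:20, function(i)
    mutate_dna(if (i %% 2) fx$consA else fx$consB, 0.02), character(1)))
  df <- data.frame(sequence_name = "x", start = seq_along(monos) * 170 - 170,
                   end = seq_along(monos) * 170, strand = "+",
                   sequence = monos, stringsAsFactors = FALSE)
  fwd <- classify_monomers(df, fx$profiles)
  rev <- classify_monomers(df[rev(seq_len(nrow(df))), ], fx$profiles)
  expect_equal(fwd$family,
               rev$family[match(df$start, rev$start)])
})

test_that("annotate_satellite_arrays merges runs and assigns layers", {
  mk <- function(fams, starts) data.frame(
    sequence_name = "cen", start = starts, end = starts + 170,
    strand = "+", sequence = "N", family = fams, score = 1, margin = 10,
    stringsAsFactors = FALSE)

  # 100 consecutive same-family monomers: one array
  a1 <- annotate_satellite_arrays(mk(rep("SF1-1", 100),
                                     170 * (0:99)), 10, 500)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$n_monomers, 100L)
  expect_equal(a1$layer, "active")

  # inactive flanks around a central active array
  fams <- c(rep("SF1-5", 50), rep("SF1-1", 200), rep("SF1-5", 50))
  a3 <- annotate_satellite_arrays(mk(fams, 170 * (0:299)), 10, 500)
  expect_equal(nrow(a3), 3L)
  expect_equal(a3$family, c("SF1-5", "SF1-1", "SF1-5"))
  expect_equal(a3$layer, c("inactive", "active", "inactive"))

  # short runs are dropped
  a0 <- annotate_satellite_arrays(mk(rep("SF1-1", 5), 170 * (0:4)), 10, 500)
  expect_equal(nrow(a0), 0L)

  # dimer monomer families grouped to one array family
  fams_d <- rep(c("S3", "S4"), 30)
  ad <- annotate_satellite_arrays(mk(fams_d, 170 * (0:59)), 10, 500,
                                  family_groups = c(S3 = "SF1-1",
                                                    S4 = "SF1-1"))
  expect_equal(nrow(ad), 1L)
  expect_equal(ad$family, "SF1-1")

  shuffled <- mk(rep("SF1-1", 20), 170 * (19:0))
  expect_error(annotate_satellite_arrays(shuffled, 10, 500), "sorted")
})

test_that("call_dimhaps clusters by single linkage with specificity", {
  d0 <- rand_dna(340, seed = 80)
  # identical dimers on one chromosome: one dimhap, specificity 1
  x <- setNames(rep(d0, 3), c("a1", "a2", "a3"))
  chrom <- setNames(rep("chr1", 3), names(x))
  dh <- call_dimhaps(x, chrom)
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$specificity, 1.0)
  expect_equal(dh$n_members, 3L)

  # 95% identity below a 99% linkage threshold: two dimhaps
  y <- c(a = d0, b = mutate_dna(d0, 0.05, seed = 81))
  expect_equal(nrow(call_dimhaps(y, link_identity = 0.99)), 2L)

  # planted clades: 7 near-identical + 3 divergent = exactly 2 clusters
  cladeB <- mutate_dna(d0, 0.10, seed = 82)
  z <- c(withr::with_seed(83, vapply(1:7, function(i)
    mutate_dna(d0, 0.003), character(1))),
    withr::with_seed(84, vapply(1:3, function(i)
      mutate_dna(cladeB, 0.003), character(1))))
  names(z) <- paste0("arr", 1:10)
  chroms <- setNames(c(rep("chr17", 7), rep("chr19", 3)), names(z))
  dhz <- call_dimhaps(z, chroms, link_identity = 0.99)
  expect_equal(nrow(dhz), 2L)
  expect_setequal(dhz$modal_chromosome, c("chr17", "chr19"))
  expect_true(all(dhz$specificity == 1.0))

  expect_equal(nrow(call_dimhaps(character(0))), 0L)
})

test_that("kmer_signatures are exclusive, disjoint, and respect min_copies", {
  a <- tandem(rand_dna(120, seed = 90), 30, sub = 0.01, seed = 91)
  b <- tandem(rand_dna(120, seed = 92), 30, sub = 0.01, seed = 93)
  sigs <- kmer_signatures(c(chrA = a, chrB = b), k = 21, min_copies = 5)
  expect_gt(length(sigs$chrA), 0)
  expect_gt(length(sigs$chrB), 0)
  expect_equal(length(intersect(sigs$chrA, sigs$chrB)), 0L)
  # exhaustive check: every signature k-mer truly absent from the other
  # array on either strand
  other <- paste0(b, "NN", satarch:::revcomp(b))
  expect_false(any(vapply(sigs$chrA, grepl, logical(1), x = other,
                          fixed = TRUE)))

  sig_same <- kmer_signatures(c(x = a, y = a), k = 21, min_copies = 2)
  expect_equal(lengths(sig_same), c(x = 0L, y = 0L))

  sig_high <- kmer_signatures(c(chrA = a, chrB = b), k = 21,
                              min_copies = 10000)
  expect_true(all(lengths(sig_high) == 0L))

  expect_error(kmer_signatures(c(x = "ACGT", y = a), k = 21), "shortest")
  expect_error(kmer_signatures(c(x = a), k = 21), "at least 2")
})
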