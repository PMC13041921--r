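# Synthetic genome generator: libraries, arrays, arms, genomes, tracks.

test_that("monomer libraries honour length, divergence and determinism", {
  lib1 <- make_monomer_library(1, 171, 0.2, seed = 1)
  expect_equal(nrow(lib1$families), 1L)
  expect_equal(nchar(lib1$families$consensus), 171L)
  expect_match(lib1$families$consensus, "^[ACGT]+$")

  lib2 <- make_monomer_library(2, 170, 0.25, seed = 7)
  dv <- hamming_div(lib2$families$consensus[1], lib2$families$consensus[2])
  expect_lt(abs(dv - 0.25), 0.05)

  # multi-family libraries keep all pairwise divergences near the request
  lib6 <- make_monomer_library(6, 170, 0.2, seed = 3)
  pw <- utils::combn(6, 2, function(ij)
    hamming_div(lib6$families$consensus[ij[1]],
                lib6$families$consensus[ij[2]]))
  expect_true(all(abs(pw - 0.2) <= 0.2 * 0.2 + 1e-9))

  expect_identical(make_monomer_library(3, 170, 0.2, seed = 11),
                   make_monomer_library(3, 170, 0.2, seed = 11))
  expect_error(make_monomer_library(0, 170, 0.2, 1), "n_families")
  expect_error(make_monomer_library(2, 170, 0.6, 1), "divergence")
})

test_that("synthesize_array plants monomers exactly as specified", {
  lib <- make_monomer_library(2, 170, 0.2, seed = 7,
                              family_names = c("S3", "S4"))
  # zero-mutation dimer: exact length, alternating truth
  arr0 <- synthesize_array(lib, array_spec(c("S3", "S4"), 100))
  expect_equal(nchar(arr0$sequence), 100 * 340)
  expect_equal(nrow(arr0$truth), 200L)
  expect_equal(arr0$truth$feature_class, rep(c("S3", "S4"), 100))
  expect_equal(arr0$truth$start[1], 0L)
  expect_equal(arr0$truth$end[200], 34000L)

  # substitution rate is recovered by realignment to the consensus
  arr <- synthesize_array(lib, array_spec(c("S3", "S4"), 100,
                                          substitution_rate = 0.02,
                                          seed = 5))
  cons <- setNames(lib$families$consensus, lib$families$family)
  tr <- as.data.frame(arr$truth)
  div <- vapply(seq_len(nrow(tr)), function(i)
    hamming_div(substr(arr$sequence, tr$start[i] + 1, tr$end[i]),
                cons[[tr$feature_class[i]]]), numeric(1))
  expect_lt(abs(mean(div) - 0.02), 0.005)

  # 28-class pattern: period 28 in the truth class string
  lib28 <- make_monomer_library(28, 170, 0.1, seed = 2)
  pat <- lib28$families$family
  arr28 <- synthesize_array(lib28, array_spec(pat, 50))
  expect_equal(nrow(arr28$truth), 1400L)
  cls <- arr28$truth$feature_class
  expect_true(all(cls[1:(1400 - 28)] == cls[29:1400]))

  expect_error(synthesize_array(lib, array_spec("S5", 10)), "unknown family")
})

test_that("minus-strand arrays are reverse complements with remapped truth", {
  lib <- make_monomer_library(2, 60, 0.2, seed = 1,
                              family_names = c("A", "B"))
  plus <- synthesize_array(lib, array_spec(c("A", "B"), 10, seed = 3))
  minus <- synthesize_array(lib, array_spec(c("A", "B"), 10, seed = 3,
                                            strand = "-"))
  expect_equal(minus$sequence, satarch:::revcomp(plus$sequence))
  expect_true(all(minus$truth$strand == "-"))
  # first plus-strand monomer maps to the last minus-strand interval
  tr <- as.data.frame(minus$truth)
  last <- tr[nrow(tr), ]
  expect_equal(substr(minus$sequence, last$start + 1, last$end),
               satarch:::revcomp(substr(plus$sequence, 1,
                                        plus$truth$end[1])))
})

test_that("acrocentric arm plans preserve order, share PHRs, flag degraded units", {
  lib <- make_monomer_library(1, 171, 0.2, seed = 4, family_names = "SUB")
  model <- rdna_unit_model(coding_length = 2000, igs_length = 800, seed = 5)
  donor <- rand_dna(15000, seed = 6)
  plan <- list(
    list(type = "satellite", library = lib,
         spec = array_spec("SUB", 30)),
    list(type = "rdna", model = model, n_units = 10,
         substitution_rate = 0.005,
         insertions = list(list(unit = 4, position = 700, length = 300))),
    list(type = "phr_donor", sequence = donor, identity = 0.995,
         class = "phr"),
    list(type = "satellite", library = lib, spec = array_spec("SUB", 20)))
  arm1 <- synthesize_acrocentric_arm(plan, seed = 1, arm_name = "arm1")
  arm2 <- synthesize_acrocentric_arm(plan, seed = 2, arm_name = "arm2")

  tr <- as.data.frame(arm1$truth)
  # feature blocks appear in plan order along the arm
  blocks <- c("SUB", "rdna_unit", "phr")
  first_pos <- vapply(blocks, function(b)
    min(tr$start[tr$feature_class == b]), numeric(1))
  expect_true(all(diff(first_pos) > 0))

  # the degraded unit is flagged in truth, the rest are intact
  rd <- tr[tr$feature_class == "rdna_unit", ]
  expect_equal(sum(!rd$intact), 1L)
  expect_equal(which(!rd$intact), 4L)
  expect_equal(rd$end[4] - rd$start[4],
               2000 + 800 + 300)

  # PHR copies in two arms share the requested pairwise identity
  p1 <- tr[tr$feature_class == "phr", ]
  tr2 <- as.data.frame(arm2$truth)
  p2 <- tr2[tr2$feature_class == "phr", ]
  c1 <- substr(arm1$sequence, p1$start + 1, p1$end)
  c2 <- substr(arm2$sequence, p2$start + 1, p2$end)
  expect_lt(abs(hamming_div(c1, c2) - 0.005), 0.002)

  bad <- list(list(type = "unknown_thing"))
  expect_error(synthesize_acrocentric_arm(bad, seed = 1), "unknown")
})

test_that("synthesize_genome writes FASTA/BED that round-trip and is deterministic", {
  lib <- make_monomer_library(2, 80, 0.2, seed = 1,
                              family_names = c("A", "B"))
  cfg <- list(seed = 9, chromosomes = list(
    chr1 = list(library = lib, spec = array_spec(c("A", "B"), 30)),
    chr2 = list(library = lib, spec = array_spec("A", 40)),
    chr3 = list(library = lib, spec = array_spec("B", 25))))
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  g <- synthesize_genome(cfg, fasta_path = fa, bed_path = bed)
  expect_equal(names(read_fasta(fa)), c("chr1", "chr2", "chr3"))
  expect_equal(unname(read_fasta(fa)), unname(g$sequences))
  rt <- read_bed(bed)
  expect_equal(nrow(rt), nrow(g$truth))
  expect_true(!is.unsorted(order(rt$sequence_name, rt$start)))

  fa2 <- tempfile(fileext = ".fa"); bed2 <- tempfile(fileext = ".bed")
  synthesize_genome(cfg, fasta_path = fa2, bed_path = bed2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(bed), readLines(bed2))

  cfg$chromosomes$chr1$spec <- array_spec("Z", 10)
  expect_error(synthesize_genome(cfg), "unknown family")
})

test_that("depth tracks scale linearly with rDNA copies and methylation states hold", {
  model <- rdna_unit_model(coding_length = 2000, igs_length = 800, seed = 5)
  plan <- list(
    list(type = "spacer", length = 10000),
    list(type = "rdna", model = model, n_units = 5,
         substitution_rate = 0.005),
    list(type = "spacer", length = 10000))
  arm <- synthesize_acrocentric_arm(plan, seed = 3, arm_name = "arm")
  seqs <- setNames(arm$sequence, "arm")
  ts <- track_spec(mean_depth = 30, noise_sd = 2,
                   methylation_states = list(coding = 0.1, igs = 0.8),
                   bin_size = 100)
  tk <- simulate_depth_track(seqs, arm$truth, ts, rdna_total_copies = 100,
                             seed = 2)
  rd_sel <- tk$depth$bin_start >= 10000 & tk$depth$bin_start < 24000
  sc_sel <- tk$depth$bin_start < 10000
  expect_lt(abs(mean(tk$depth$value[rd_sel]) - 1500) / 1500, 0.05)
  expect_lt(abs(mean(tk$depth$value[sc_sel]) - 30) / 30, 0.1)

  # doubling the copies doubles the rDNA-region depth
  tk2 <- simulate_depth_track(seqs, arm$truth, ts, rdna_total_copies = 200,
                              seed = 2)
  ratio <- mean(tk2$depth$value[rd_sel]) / mean(tk$depth$value[rd_sel])
  expect_lt(abs(ratio - 2), 0.1)

  # zero copies silence the region
  tk0 <- simulate_depth_track(seqs, arm$truth, ts, rdna_total_copies = 0,
                              seed = 2)
  expect_lt(mean(tk0$depth$value[rd_sel]), 2)

  # methylation around requested states
  tr <- as.data.frame(arm$truth)
  rd <- tr[tr$feature_class == "rdna_unit", ]
  in_coding <- rep(FALSE, nrow(tk$methylation))
  for (i in seq_len(nrow(rd)))
    in_coding <- in_coding | (tk$methylation$bin_start >= rd$coding_start[i] &
                                tk$methylation$bin_start < rd$coding_end[i] - 100)
  expect_lt(abs(mean(tk$methylation$value[in_coding]) - 0.1), 0.03)

  expect_error(simulate_depth_track(seqs, arm$truth, ts,
                                    rdna_total_copies = -1), ">= 0")
})
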