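# rDNA unit detection, copy-number estimation and allocation, activity
# classification, CDR calling, and the sex comparison.

rdna_arm <- function(n_units = 5, insertions = list(), seed = 11,
                     model_seed = 5) {
  model <- rdna_unit_model(coding_length = 2000, igs_length = 800,
                           seed = model_seed)
  plan <- list(
    list(type = "spacer", length = 8000),
    list(type = "rdna", model = model, n_units = n_units,
         substitution_rate = 0.005, insertions = insertions),
    list(type = "spacer", length = 12000))
  arm <- synthesize_acrocentric_arm(plan, seed = seed, arm_name = "arm")
  list(arm = arm, model = model)
}

test_that("find_rdna_units detects intact tandem units in orientation", {
  fx <- rdna_arm(5)
  units <- find_rdna_units(fx$arm$sequence, fx$model, sequence_name = "arm")
  expect_equal(nrow(units), 5L)
  expect_true(all(units$intact))
  expect_true(all(units$orientation == "+"))
  truth <- as.data.frame(fx$arm$truth)
  rd <- truth[truth$feature_class == "rdna_unit", ]
  expect_equal(units$start, rd$start)
  expect_equal(units$end, rd$end)
})

test_that("planted insertions flag units as degraded with position and length", {
  fx <- rdna_arm(5, insertions = list(
    list(unit = 3, position = 1200, length = 300)))
  units <- find_rdna_units(fx$arm$sequence, fx$model, sequence_name = "arm")
  expect_equal(which(!units$intact), 3L)
  ins <- units$insertions[[3]]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$length, 300L)
  expect_lt(abs(ins$position - 1200), 160)
  # an insertion below the reporting floor stays intact
  fx_small <- rdna_arm(3, insertions = list(
    list(unit = 2, position = 500, length = 60)))
  u_small <- find_rdna_units(fx_small$arm$sequence, fx_small$model)
  expect_true(all(u_small$intact))
})

test_that("mixed-orientation arrays report per-unit orientation", {
  fx <- rdna_arm(5)
  s <- fx$arm$sequence
  # flip the second unit (12500..17000 with these sizes) in place
  truth <- as.data.frame(fx$arm$truth)
  rd <- truth[truth$feature_class == "rdna_unit", ]
  u2 <- rd[2, ]
  flipped <- paste0(substr(s, 1, u2$start),
                    satarch:::revcomp(substr(s, u2$start + 1, u2$end)),
                    substr(s, u2$end + 1, nchar(s)))
  units <- find_rdna_units(flipped, fx$model)
  expect_equal(sum(units$orientation == "-"), 1L)
  expect_equal(units$orientation[2], "-")
})

test_that("estimate_total_copies is the doubled depth ratio", {
  mk_track <- function(rdna_depth, sc_depth, n = 100) data.frame(
    chrom = "arm", bin_start = c(0:(n - 1) * 100, 20000 + 0:(n - 1) * 100),
    value = c(rep(rdna_depth, n), rep(sc_depth, n)))
  rd <- list(chrom = "arm", start = 0, end = 10000)
  sc <- list(chrom = "arm", start = 20000, end = 30000)
  expect_equal(estimate_total_copies(mk_track(1000, 20), rd, sc), 100)
  expect_equal(estimate_total_copies(mk_track(0, 20), rd, sc), 0)
  # exact linearity on noiseless tracks
  expect_equal(estimate_total_copies(mk_track(2000, 20), rd, sc),
               2 * estimate_total_copies(mk_track(1000, 20), rd, sc))
  expect_error(estimate_total_copies(mk_track(1000, 0), rd, sc),
               "zero depth")
  expect_error(estimate_total_copies(mk_track(1000, 20, n = 10), rd, sc),
               "bins")
})

test_that("copy estimation round-trips through simulated tracks", {
  fx <- rdna_arm(5)
  seqs <- setNames(fx$arm$sequence, "arm")
  ts <- track_spec(mean_depth = 30, noise_sd = 2, bin_size = 100)
  truth <- as.data.frame(fx$arm$truth)
  rd_rows <- truth[truth$feature_class == "rdna_unit", ]
  rd <- list(chrom = "arm", start = min(rd_rows$start),
             end = max(rd_rows$end))
  sc <- list(chrom = "arm", start = max(rd_rows$end) + 2000,
             end = nchar(fx$arm$sequence))
  for (copies in c(50, 100)) {
    tk <- simulate_depth_track(seqs, fx$arm$truth, ts,
                               rdna_total_copies = copies, seed = 3)
    est <- estimate_total_copies(tk$depth, rd, sc)
    expect_lt(abs(est - copies), 5)
  }
})

test_that("allocate_array_copies conserves totals by largest remainder", {
  a1 <- allocate_array_copies(100, c(a = 1.0))
  expect_equal(a1$copies, 100L)
  a2 <- allocate_array_copies(100, c(a = 0.25, b = 0.75))
  expect_equal(setNames(a2$copies, a2$array_id), c(a = 25L, b = 75L))
  # the Y-array share of a male total
  fr <- c(y = 0.135, a1 = 0.1, a2 = 0.1, a3 = 0.1, a4 = 0.1, a5 = 0.1,
          a6 = 0.1, a7 = 0.1, a8 = 0.1, a9 = 0.065)
  a3 <- allocate_array_copies(282, fr)
  expect_equal(sum(a3$copies), 282L)
  expect_equal(a3$copies[a3$array_id == "y"], 38L)
  # largest-remainder against the exhaustive-check oracle: totals are
  # conserved and every array is within 1 copy of its exact share
  expect_true(all(abs(a3$copies - fr / sum(fr) * 282) < 1))

  expect_error(allocate_array_copies(100, c(a = -0.1, b = 1.1)),
               "non-negative")
  expect_error(allocate_array_copies(100, c(a = 0.5, b = 0.4)), "outside")
})

test_that("activity classification follows coding methylation", {
  mk <- function(coding_m, igs_m) {
    units <- data.frame(sequence_name = "arr", start = 0, end = 3000,
                        coding_start = 0, coding_end = 2000,
                        orientation = "+", intact = TRUE)
    track <- data.frame(chrom = "arr", bin_start = 0:29 * 100,
                        value = c(rep(coding_m, 20), rep(igs_m, 10)))
    classify_activity(track, units)
  }
  act <- mk(0.1, 0.8)
  expect_equal(act$state, "active")
  expect_equal(act$igs_mean, 0.8)
  expect_equal(mk(0.9, 0.8)$state, "silent")

  # generator round-trip with the requested states
  fx <- rdna_arm(5)
  seqs <- setNames(fx$arm$sequence, "arm")
  ts <- track_spec(mean_depth = 30,
                   methylation_states = list(coding = 0.1, igs = 0.8),
                   bin_size = 100)
  tk <- simulate_depth_track(seqs, fx$arm$truth, ts,
                             rdna_total_copies = 50, seed = 4)
  units <- find_rdna_units(fx$arm$sequence, fx$model, sequence_name = "arm")
  act2 <- classify_activity(tk$methylation, units)
  expect_equal(act2$state, "active")
  expect_lt(abs(act2$igs_mean - 0.8), 0.05)

  bad_track <- data.frame(chrom = "other", bin_start = 0, value = 0.5)
  units1 <- data.frame(sequence_name = "arr", start = 0, end = 3000,
                       coding_start = 0, coding_end = 2000,
                       orientation = "+", intact = TRUE)
  expect_error(classify_activity(bad_track, units1), "cover")
})

test_that("call_cdrs finds planted hypomethylated dips", {
  mk_track <- function(v) data.frame(chrom = "cen",
                                     bin_start = seq_along(v) * 100 - 100,
                                     value = v)
  arr <- list(chrom = "cen", start = 0, end = 100000)
  flat <- mk_track(rep(0.8, 1000))
  expect_equal(nrow(call_cdrs(flat, arr)), 0L)

  v <- rep(0.8, 1000); v[400:599] <- 0.1      # 20 kb dip
  got <- call_cdrs(mk_track(v), arr)
  expect_equal(nrow(got), 1L)
  expect_lt(abs(got$start - 39900), 300)
  expect_lt(abs(got$end - 59900), 300)
  expect_lt(got$mean_methylation_inside, got$flank_mean)

  v2 <- rep(0.8, 1000); v2[200:320] <- 0.1; v2[600:720] <- 0.1
  expect_equal(nrow(call_cdrs(mk_track(v2), arr)), 2L)

  # dips narrower than min span are not called
  v3 <- rep(0.8, 1000); v3[500:549] <- 0.1    # 5 kb < 10 kb floor
  expect_equal(nrow(call_cdrs(mk_track(v3), arr)), 0L)
})

test_that("sex comparison matches the exact permutation distribution", {
  # identical groups: p near 1
  same <- data.frame(id = 1:10, sex = rep(c("m", "f"), each = 5),
                     copies = rep(c(450, 460, 470, 480, 490), 2))
  res_same <- compare_sex_copy_number(same, n_permutations = 1999, seed = 1)
  expect_gt(res_same$p_value, 0.5)

  # exact oracle on n = 10: enumerate all choose(10,5) assignments
  dat <- data.frame(id = 1:10, sex = rep(c("f", "m"), each = 5),
                    copies = c(400, 410, 395, 420, 405,
                               500, 510, 495, 520, 505))
  r <- rank(dat$copies)
  combs <- utils::combn(10, 5)
  EW <- 5 * 11 / 2
  obs <- abs(sum(r[dat$sex == "f"]) - EW)
  exact_p <- mean(apply(combs, 2, function(ix)
    abs(sum(r[ix]) - EW) >= obs - 1e-9))
  res <- compare_sex_copy_number(dat, n_permutations = 4999, seed = 2)
  expect_lt(abs(res$p_value - exact_p), 0.02)
  expect_gt(res$group_means[["m"]], res$group_means[["f"]])

  # the separation reported for males vs females is detected
  big <- withr::with_seed(3, data.frame(
    id = 1:60, sex = rep(c("m", "f"), each = 30),
    copies = c(rnorm(30, 500, 20), rnorm(30, 400, 20))))
  res_big <- compare_sex_copy_number(big, n_permutations = 1999, seed = 4)
  expect_lt(res_big$p_value, 0.01)
  expect_gt(res_big$group_means[["m"]], res_big$group_means[["f"]])

  expect_error(compare_sex_copy_number(
    data.frame(id = 1:3, sex = c("m", "f", "f"), copies = c(1, 2, 3))),
    "2 samples")
})
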