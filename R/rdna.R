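# rDNA array analysis: unit detection with degradation flags, depth-based
# total copy-number estimation, per-array copy allocation from fractional
# fluorescence intensities, methylation-based activity classification,
# centromere dip region (CDR) calling, and the sex comparison of copy
# numbers.

#' Find rDNA units by tandem hits to the coding consensus
#'
#' Units are seeded by exact k-mer anchors from the coding (45S-like)
#' consensus on both strands; anchors agreeing on a diagonal define one
#' coding hit. Within a unit, a jump of at least \code{min_insertion} bp
#' in the anchor diagonal along the consensus marks an insertion
#' (retrotransposon-like disruption); any insertion flags the unit
#' degraded (\code{intact = FALSE}). Each unit extends to the next
#' unit's coding start (or one IGS length past the coding end).
#'
#' @param sequence DNA string to scan.
#' @param unit_model list with \code{coding} and \code{igs} consensus
#'   strings (see \code{\link{rdna_unit_model}}).
#' @param sequence_name name recorded on the units.
#' @param min_insertion minimum alignment gap reported as an insertion;
#'   default 100 bp.
#' @param anchor_k,anchor_every seed length and spacing; defaults 32/150.
#' @return data.frame (sequence_name, start, end, coding_start,
#'   coding_end, orientation, intact) with an \code{insertions} list
#'   column of data.frames (position, length); empty when nothing hits.
#' @export
find_rdna_units <- function(sequence, unit_model, sequence_name = "seq",
                            min_insertion = 100L, anchor_k = 32L,
                            anchor_every = 150L) {
  assert_dna(sequence)
  if (is.null(unit_model$coding) || !nzchar(unit_model$coding))
    stop("unit_model$coding must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  coding <- toupper(unit_model$coding)
  igs_len <- nchar(unit_model$igs %||% "")
  Lc <- nchar(coding)
  Ls <- nchar(sequence)

  empty <- data.frame(sequence_name = character(0), start = integer(0),
                      end = integer(0), coding_start = integer(0),
                      coding_end = integer(0), orientation = character(0),
                      intact = logical(0))
  hits <- list()
  apos <- seq.int(1L, Lc - anchor_k + 1L, by = anchor_every)
  for (orient in c("+", "-")) {
    cseq <- if (orient == "+") coding else revcomp(coding)
    anch <- list()
    for (ap in apos) {
      hh <- anchor_hits(substr(cseq, ap, ap + anchor_k - 1L), sequence)
      if (length(hh))
        anch[[length(anch) + 1L]] <- data.frame(ap = ap, diag = hh - ap)
    }
    if (!length(anch)) next
    anch <- do.call(rbind, anch)
    anch <- anch[order(anch$diag, anch$ap), , drop = FALSE]
    # one diagonal cluster per unit copy; insertions shift downstream
    # anchors, so allow within-cluster spread up to half a unit
    cl <- cumsum(c(TRUE, diff(anch$diag) > Lc / 2))
    for (g in unique(cl)) {
      aa <- anch[cl == g, , drop = FALSE]
      if (nrow(aa) < 2L) next
      aa <- aa[order(aa$ap, aa$diag), , drop = FALSE]
      aa <- aa[!duplicated(aa$ap), , drop = FALSE]
      hits[[length(hits) + 1L]] <- list(anchors = aa, orientation = orient)
    }
  }
  if (!length(hits)) return(cbind(empty, insertions = I(list())[0]))

  units <- list()
  for (h in hits) {
    aa <- h$anchors
    orient <- h$orientation
    cs <- max(min(aa$diag), 0L)          # 0-based coding start estimate
    # insertions appear as jumps in the anchor diagonal along the unit
    jumps <- diff(aa$diag)
    ins <- data.frame(position = integer(0), length = integer(0))
    for (q in which(jumps >= min_insertion)) {
      at <- round((aa$ap[q] + aa$ap[q + 1L]) / 2)   # cseq coords
      if (orient == "-") at <- Lc - at + 1L          # consensus coords
      ins <- rbind(ins, data.frame(position = as.integer(at),
                                   length = as.integer(jumps[q])))
    }
    if (nrow(ins) > 1L) ins <- ins[order(ins$position), , drop = FALSE]
    extra <- sum(jumps[jumps >= min_insertion])
    u <- data.frame(
      sequence_name = sequence_name, start = cs,
      coding_start = cs, coding_end = min(cs + Lc + extra, Ls),
      orientation = orient, intact = nrow(ins) == 0L,
      stringsAsFactors = FALSE)
    u$insertions <- I(list(ins))
    units[[length(units) + 1L]] <- u
  }
  out <- do.call(rbind, units)
  out <- out[order(out$coding_start), , drop = FALSE]
  # unit end: next coding start, else coding end + IGS length
  nxt <- c(out$coding_start[-1], NA_integer_)
  out$end <- ifelse(!is.na(nxt) & nxt > out$coding_end &
                      nxt <= out$coding_end + 2L * max(igs_len, 1L),
                    nxt, pmin(out$coding_end + igs_len, Ls))
  out <- out[, c("sequence_name", "start", "end", "coding_start",
                 "coding_end", "orientation", "intact", "insertions")]
  rownames(out) <- NULL
  out
}

# mean track value over a 0-based half-open region
region_mean <- function(track, region, min_bins = 1L, what = "region") {
  sel <- track$chrom == region$chrom &
    track$bin_start >= region$start & track$bin_start < region$end
  if (sum(sel) < min_bins)
    stop(sprintf("%s covered by %d bins (need >= %d)", what, sum(sel),
                 min_bins), call. = FALSE)
  mean(track$value[sel])
}

#' Estimate total diploid rDNA copy number from read depth
#'
#' copies = 2 x mean depth over the rDNA reference region / mean depth
#' over a single-copy region. The single-copy baseline is assumed
#' present at 2 copies per diploid genome.
#'
#' @param depth_track data.frame (chrom, bin_start, value).
#' @param rdna_region,single_copy_region lists with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open); each must be covered
#'   by at least \code{min_bins} bins.
#' @param min_bins minimum bins per region; default 50.
#' @return estimated diploid copy number (real-valued; rounding is left
#'   to the caller).
#' @export
estimate_total_copies <- function(depth_track, rdna_region,
                                  single_copy_region, min_bins = 50L) {
  md_r <- region_mean(depth_track, rdna_region, min_bins, "rDNA region")
  md_s <- region_mean(depth_track, single_copy_region, min_bins,
                      "single-copy region")
  if (md_s <= 0)
    stop("single-copy region has zero depth", call. = FALSE)
  2 * md_r / md_s
}

#' Allocate total rDNA copies to arrays from fractional intensities
#'
#' Fractions (e.g. fractional fluorescence intensities per array from
#' FISH) are renormalized to 1 and converted to integer copies by
#' largest-remainder rounding, so the allocated copies sum exactly to
#' \code{round(total)}.
#'
#' @param total diploid copy-number estimate.
#' @param fractions named non-negative numeric vector summing to 1
#'   within [0.98, 1.02].
#' @return object of class \code{copy_allocation}: data.frame
#'   (array_id, fraction, copies) with attribute \code{total_copies}.
#' @export
allocate_array_copies <- function(total, fractions) {
  if (any(fractions < 0))
    stop("fractions must be non-negative", call. = FALSE)
  s <- sum(fractions)
  if (s < 0.98 || s > 1.02)
    stop(sprintf("fractions sum to %.4f, outside [0.98, 1.02]", s),
         call. = FALSE)
  if (is.null(names(fractions)))
    names(fractions) <- paste0("array", seq_along(fractions))
  f <- fractions / s
  n_total <- round(total)
  raw <- f * n_total
  base <- floor(raw)
  left <- n_total - sum(base)
  rem <- raw - base
  ord <- order(-rem, names(fractions))   # deterministic tie-break
  add <- integer(length(f))
  if (left > 0) add[ord[seq_len(left)]] <- 1L
  out <- data.frame(array_id = names(fractions), fraction = as.numeric(f),
                    copies = as.integer(base + add),
                    stringsAsFactors = FALSE)
  stopifnot(sum(out$copies) == n_total)
  attr(out, "total_copies") <- n_total
  class(out) <- c("copy_allocation", "data.frame")
  out
}

#' Classify rDNA array activity from methylation
#'
#' The coding regions of active rRNA genes are hypomethylated while the
#' IGS stays methylated in either state; an array is therefore called
#' \code{active} when the mean methylated fraction over its units'
#' coding regions falls below \code{threshold}, and \code{silent}
#' otherwise. The IGS mean is reported but not used for the call.
#'
#' @param methylation_track data.frame (chrom, bin_start, value).
#' @param units data.frame from \code{\link{find_rdna_units}} (needs
#'   sequence_name, start, end, coding_start, coding_end).
#' @param threshold methylated-fraction cutoff; default 0.5.
#' @return data.frame (array_id, coding_mean, igs_mean, state), one row
#'   per sequence_name in \code{units}.
#' @export
classify_activity <- function(methylation_track, units, threshold = 0.5) {
  if (!nrow(units)) stop("no rDNA units given", call. = FALSE)
  out <- lapply(split(units, units$sequence_name), function(u) {
    tr <- methylation_track[methylation_track$chrom == u$sequence_name[1], ,
                            drop = FALSE]
    in_any <- function(pos, starts, ends)
      vapply(pos, function(p) any(p >= starts & p < ends), logical(1))
    coding <- tr$value[in_any(tr$bin_start, u$coding_start, u$coding_end)]
    igs <- tr$value[in_any(tr$bin_start, u$coding_end, u$end)]
    if (!length(coding))
      stop("methylation track does not cover the coding regions of '",
           u$sequence_name[1], "'", call. = FALSE)
    data.frame(array_id = u$sequence_name[1],
               coding_mean = mean(coding),
               igs_mean = if (length(igs)) mean(igs) else NA_real_,
               state = if (mean(coding) < threshold) "active" else "silent",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call centromere dip regions (CDRs) in an active array
#'
#' Methylation is smoothed with a centered moving mean; maximal runs of
#' bins below \code{dip_factor} times the array mean that span at least
#' \code{min_cdr_span} bp are reported as CDRs, candidate kinetochore
#' sites.
#'
#' @param methylation_track data.frame (chrom, bin_start, value).
#' @param active_array list with \code{chrom}, \code{start}, \code{end}.
#' @param min_cdr_span minimum CDR span in bp; default 10000.
#' @param dip_factor dip threshold relative to the array mean; default 0.5.
#' @param smooth_bins moving-mean width in bins (odd); default 11.
#' @return data.frame (sequence_name, start, end,
#'   mean_methylation_inside, flank_mean), non-overlapping and sorted.
#' @export
call_cdrs <- function(methylation_track, active_array,
                      min_cdr_span = 10000L, dip_factor = 0.5,
                      smooth_bins = 11L) {
  sel <- methylation_track$chrom == active_array$chrom &
    methylation_track$bin_start >= active_array$start &
    methylation_track$bin_start < active_array$end
  tr <- methylation_track[sel, , drop = FALSE]
  if (nrow(tr) < smooth_bins)
    stop("methylation track does not cover the active array",
         call. = FALSE)
  tr <- tr[order(tr$bin_start), , drop = FALSE]
  bin_size <- if (nrow(tr) > 1L) min(diff(tr$bin_start)) else 1L
  v <- tr$value
  half <- smooth_bins %/% 2L
  sm <- stats::filter(v, rep(1 / smooth_bins, smooth_bins), sides = 2)
  sm[is.na(sm)] <- v[is.na(sm)]          # edges: unsmoothed
  cutoff <- dip_factor * mean(v)
  below <- as.numeric(sm) < cutoff
  runs <- rle(below)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  out <- list()
  for (q in which(runs$values)) {
    s <- tr$bin_start[starts_i[q]]
    e <- tr$bin_start[ends_i[q]] + bin_size
    if (e - s < min_cdr_span) next
    inside <- v[starts_i[q]:ends_i[q]]
    flank <- v[setdiff(seq_along(v),
                       max(1L, starts_i[q] - 2L * half):
                         min(length(v), ends_i[q] + 2L * half))]
    out[[length(out) + 1L]] <- data.frame(
      sequence_name = active_array$chrom, start = s, end = e,
      mean_methylation_inside = mean(inside),
      flank_mean = if (length(flank)) mean(flank) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sequence_name = character(0), start = integer(0),
                      end = integer(0),
                      mean_methylation_inside = numeric(0),
                      flank_mean = numeric(0)))
  do.call(rbind, out)
}

#' Compare diploid rDNA copy number between sexes
#'
#' Two-sided rank-sum test with a permutation null: the statistic is the
#' sum of ranks in the first (alphabetical) sex group, and the p-value
#' is the fraction of label permutations whose statistic deviates from
#' its expectation at least as much as observed. Direction is reported
#' via the group means.
#'
#' @param samples data.frame with columns \code{id}, \code{sex},
#'   \code{copies}; at least 2 samples per sex.
#' @param n_permutations number of permutations; default 9999.
#' @param seed integer seed.
#' @return list with \code{statistic} (rank sum of the first group),
#'   \code{p_value}, \code{group_means} (named), \code{n_permutations}.
#' @export
compare_sex_copy_number <- function(samples, n_permutations = 9999L,
                                    seed = 1L) {
  need <- c("sex", "copies")
  if (!all(need %in% names(samples)))
    stop("samples must carry columns sex and copies", call. = FALSE)
  tab <- table(samples$sex)
  if (length(tab) != 2L || any(tab < 2L))
    stop("need exactly 2 sexes with >= 2 samples each", call. = FALSE)
  g1 <- sort(names(tab))[1]
  is1 <- samples$sex == g1
  n1 <- sum(is1); n <- nrow(samples)
  r <- rank(samples$copies)
  W <- sum(r[is1])
  EW <- n1 * (n + 1) / 2
  obs_dev <- abs(W - EW)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    idx <- sample.int(n, n1)
    abs(sum(r[idx]) - EW)
  }, numeric(1)))
  p <- (1 + sum(perm >= obs_dev - 1e-9)) / (1 + n_permutations)
  means <- tapply(samples$copies, samples$sex, mean)
  list(statistic = W, p_value = p,
       group_means = setNames(as.numeric(means), names(means)),
       n_permutations = as.integer(n_permutations))
}
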