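# Tandem-repeat periodicity via k-mer recurrence-interval spectra,
# monomer segmentation, consensus building, and higher-order repeat
# detection.

#' Compute a k-mer recurrence-interval periodicity spectrum
#'
#' For every k-mer occurring at least twice, distances between
#' consecutive occurrences are tallied; the summed tally per distance is
#' the score of that period. Tandem arrays produce sharp peaks at the
#' repeat unit length (and its multiples for multi-monomer units).
#' K-mers containing ambiguous bases (N) are excluded.
#'
#' @param sequence DNA string, longer than 2k.
#' @param k k-mer size (>= 5); default 21.
#' @param max_period largest interval tallied, in bp; default 3000.
#' @return object of class \code{period_spectrum}: list with \code{k},
#'   \code{max_period}, \code{score_per_period} (named integer vector,
#'   only non-zero periods) and \code{n_kmers_used}.
#' @export
ntr_spectrum <- function(sequence, k = 21L, max_period = 3000L) {
  assert_dna(sequence)
  sequence <- toupper(sequence)
  k <- as.integer(k); max_period <- as.integer(max_period)
  if (k < 5L) stop("k must be >= 5", call. = FALSE)
  n <- nchar(sequence)
  if (n <= 2L * k)
    stop("sequence must be longer than 2k", call. = FALSE)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  dt <- data.table::data.table(kmer = kmers[keep], pos = starts[keep])
  data.table::setkey(dt, kmer, pos)
  dt[, grp := .GRP, by = kmer]
  counts <- dt[, .N, by = grp]
  used <- counts[N >= 2L, grp]
  dt2 <- dt[grp %in% used]
  tally <- .interval_tally_cpp(dt2$pos, dt2$grp, max_period)
  nz <- which(tally > 0L)
  structure(list(k = k, max_period = max_period,
                 score_per_period = setNames(tally[nz], nz),
                 n_kmers_used = length(used)),
            class = "period_spectrum")
}

#' @export
print.period_spectrum <- function(x, ...) {
  top <- dominant_period(x, 3L)
  cat(sprintf("<period_spectrum> k=%d, max_period=%d, %d recurrent k-mers\n",
              x$k, x$max_period, x$n_kmers_used))
  if (nrow(top))
    cat("  top periods:",
        paste(sprintf("%d (%d)", top$period, top$score), collapse = ", "),
        "\n")
  invisible(x)
}

#' Top periods of a spectrum
#'
#' @param spectrum a \code{period_spectrum}.
#' @param n_top number of periods to return.
#' @return data.frame (period, score), scores descending; ties broken by
#'   the smaller period. Empty spectrum gives an empty data.frame.
#' @export
dominant_period <- function(spectrum, n_top = 1L) {
  stopifnot(inherits(spectrum, "period_spectrum"))
  s <- spectrum$score_per_period
  if (!length(s))
    return(data.frame(period = integer(0), score = integer(0)))
  period <- as.integer(names(s))
  ord <- order(-as.integer(s), period)
  idx <- head(ord, n_top)
  data.frame(period = period[idx], score = as.integer(s[idx]),
             row.names = NULL)
}

# Highest-scoring recurrent k-mer whose modal recurrence interval equals
# `period` (within tolerance); used as the phase anchor for segmentation.
phase_anchor <- function(sequence, k, period, tol = 3L) {
  n <- nchar(sequence)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  dt <- data.table::data.table(kmer = kmers[keep], pos = starts[keep])
  data.table::setkey(dt, kmer, pos)
  score <- dt[, {
    d <- diff(pos)
    .(hits = sum(abs(d - period) <= tol))
  }, by = kmer]
  best <- score[order(-hits, kmer)][1]
  if (is.na(best$hits) || best$hits < 1L) return(NULL)
  list(kmer = best$kmer, positions = dt[kmer == best$kmer, pos])
}

#' Segment a tandem array into monomers
#'
#' Occurrences of a phase anchor define an in-phase lattice of monomer
#' boundaries; gaps between anchor hits that span several periods are
#' subdivided evenly, and the lattice is extended to both array ends by
#' stepping one period at a time. By default a rough pass (anchored on
#' the k-mer best supporting the detected period) yields a provisional
#' consensus which is aligned back to the array to fix the phase;
#' passing a consensus via \code{phase_to} phases boundaries to that
#' consensus start instead, so that segmented monomers are in register
#' with profiles trained on it. The trailing partial unit is
#' dropped when shorter than period/2.
#'
#' @param array_sequence DNA string of the tandem array.
#' @param period repeat unit length in bp (>= 10).
#' @param k anchor k-mer size; default 21.
#' @param sequence_name name recorded on the monomers.
#' @param phase_to optional consensus DNA string; monomer starts are
#'   placed at positions matching the consensus start.
#' @return data.frame of monomers (sequence_name, start, end, strand,
#'   sequence), 0-based half-open.
#' @export
segment_monomers <- function(array_sequence, period, k = 21L,
                             sequence_name = "array", phase_to = NULL) {
  assert_dna(array_sequence)
  array_sequence <- toupper(array_sequence)
  period <- as.integer(period)
  if (period < 10L) stop("period must be >= 10", call. = FALSE)
  n <- nchar(array_sequence)
  if (n < 2L * period)
    stop("array shorter than two periods", call. = FALSE)
  k <- min(as.integer(k), period - 1L)

  if (!is.null(phase_to)) {
    pos <- phased_positions(array_sequence, toupper(phase_to), k)
  } else {
    # rough pass from an arbitrary-phase anchor, then re-phase on a
    # provisional consensus aligned back to the array, so boundaries sit
    # at consensus starts rather than at an arbitrary rotation
    anchor <- phase_anchor(array_sequence, k, period)
    pos <- if (is.null(anchor)) integer(0) else sort(anchor$positions) - 1L
    if (length(pos) >= 3L) {
      rough_starts <- pos[pos + period <= n]
      take <- utils::head(rough_starts[-1], 30L)
      if (length(take) >= 2L) {
        prov <- build_consensus(substring(array_sequence, take + 1L,
                                          take + period))
        pp <- phased_positions(array_sequence, prov, k)
        if (length(pp) >= 3L) pos <- pp
      }
    }
    # the provisional consensus carries an arbitrary rotation; shift the
    # lattice so it tiles from the array start
    if (length(pos)) pos <- pos - (pos[1] %% period)
  }
  if (!length(pos)) {
    bounds <- seq.int(0L, n, by = period)   # fixed-phase fallback
  } else {
    bounds <- pos[1]
    for (i in seq_along(pos)[-1]) {
      gap <- pos[i] - bounds[length(bounds)]
      m <- round(gap / period)
      if (m >= 1L && abs(gap - m * period) <= m * 3L + 3L) {
        step <- gap / m                     # subdivide into m near-equal units
        bounds <- c(bounds,
                    round(bounds[length(bounds)] + step * seq_len(m)))
      } else if (gap > period / 2) {
        bounds <- c(bounds, pos[i])
      }
    }
    # extend to both ends
    first <- bounds[1]
    if (first > 0L) {
      left <- first - period * seq_len(ceiling(first / period))
      left <- pmax(left[left > -period / 2], 0L)
      bounds <- c(rev(left), bounds)
    }
    last <- bounds[length(bounds)]
    if (last + period <= n) {
      bounds <- c(bounds, seq.int(last + period, n, by = period))
      last <- bounds[length(bounds)]
    }
    if (n - last >= period / 2) bounds <- c(bounds, n)
    bounds <- unique(pmin(pmax(bounds, 0L), n))
  }
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  keep <- (ends - starts) >= period / 2 & (ends - starts) <= 2L * period
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(sequence_name = sequence_name, start = starts, end = ends,
             strand = "+",
             sequence = substring(array_sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

# Candidate in-phase monomer start positions (0-based, sorted): exact
# matches of consensus k-mers, shifted back by the k-mer offset so each
# candidate marks a position aligned with the consensus start.
phased_positions <- function(array_sequence, consensus, k) {
  L <- nchar(consensus)
  offsets <- unique(c(seq.int(1L, max(1L, L - k + 1L), by = 7L),
                      L - k + 1L))
  cand <- integer(0)
  for (o in offsets) {
    hh <- anchor_hits(substr(consensus, o, o + k - 1L), array_sequence)
    if (length(hh)) cand <- c(cand, hh - o)       # 0-based starts
  }
  if (!length(cand)) return(integer(0))
  cand <- sort(cand)
  # collapse candidates within 3 bp (indel jitter) to their median
  cl <- cumsum(c(TRUE, diff(cand) > 3L))
  as.integer(round(tapply(cand, cl, stats::median)))
}

#' Build a majority-rule consensus of monomers
#'
#' Monomers are star-aligned to the longest monomer; the consensus is the
#' column-wise majority base, ties broken alphabetically. Columns where a
#' gap is the majority are removed, keeping the consensus length near the
#' median monomer length.
#'
#' @param monomers character vector of monomer sequences, or a data.frame
#'   with a \code{sequence} column (as from \code{segment_monomers}).
#' @return consensus DNA string.
#' @export
build_consensus <- function(monomers) {
  if (is.data.frame(monomers)) monomers <- monomers$sequence
  monomers <- toupper(monomers)
  if (length(monomers) < 2L)
    stop("need at least 2 monomers for a consensus", call. = FALSE)
  ref_i <- which.max(nchar(monomers))
  ref <- monomers[ref_i]
  L <- nchar(ref)
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(DNA_BASES, "-")))
  for (i in seq_along(monomers)) {
    if (i == ref_i) {
      cols <- strsplit(ref, "")[[1]]
      idx <- match(cols, colnames(counts))
      counts[cbind(seq_len(L), idx)] <-
        counts[cbind(seq_len(L), idx)] + 1L
      next
    }
    al <- sat_align(ref, monomers[i], band = 16L)
    ra <- strsplit(al$a_aln, "")[[1]]
    ba <- strsplit(al$b_aln, "")[[1]]
    keep <- ra != "-"           # project onto reference columns
    rc <- ba[keep]
    idx <- match(rc, colnames(counts))
    ok <- !is.na(idx)
    counts[cbind(which(ok), idx[ok])] <- counts[cbind(which(ok), idx[ok])] + 1L
  }
  # majority per column, alphabetical tie-break among bases; drop columns
  # where the gap wins outright
  best <- apply(counts, 1L, function(r) {
    m <- max(r)
    w <- which(r == m)
    if (length(w) > 1L) w <- setdiff(w, 5L)[1]   # bases beat gap on ties
    colnames(counts)[w[1]]
  })
  paste(best[best != "-"], collapse = "")
}

#' Detect higher-order repeats in a monomer class string
#'
#' For each candidate unit size u, the support is the fraction of
#' positions i with class[i] == class[i + u]. Units with support at or
#' above \code{min_support} are reported unless their size is a multiple
#' of a smaller reported unit, making e.g. dimer versus 28-mer calls
#' unambiguous.
#'
#' @param class_string character vector of ordered monomer class labels.
#' @param max_unit largest unit size considered, in monomers.
#' @param min_support minimum match fraction; default 0.8.
#' @return data.frame (unit_size, support, unit_class_sequence), sorted
#'   by support (descending); empty when nothing qualifies or the string
#'   is shorter than 4 labels.
#' @export
detect_hor <- function(class_string, max_unit = 60L, min_support = 0.8) {
  n <- length(class_string)
  empty <- data.frame(unit_size = integer(0), support = numeric(0),
                      unit_class_sequence = character(0))
  if (n < 4L) return(empty)
  max_unit <- min(as.integer(max_unit), n - 2L)
  cand <- lapply(2:max_unit, function(u) {
    sup <- mean(class_string[seq_len(n - u)] ==
                  class_string[seq_len(n - u) + u])
    data.frame(unit_size = u, support = sup)
  })
  cand <- do.call(rbind, cand)
  cand <- cand[cand$support >= min_support, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$unit_size), , drop = FALSE]
  kept <- integer(0)
  for (u in cand$unit_size)
    if (!any(u %% kept == 0L)) kept <- c(kept, u)
  cand <- cand[cand$unit_size %in% kept, , drop = FALSE]
  cand$unit_class_sequence <- vapply(cand$unit_size, function(u)
    paste(class_string[seq_len(u)], collapse = ","), character(1))
  cand <- cand[order(-cand$support, cand$unit_size), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
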