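# Pseudo-homologous region (PHR) detection between heterologous
# chromosome arms, the PHR network, and self-identity matrices for
# triangular heatmaps.

# Exact-match anchor positions (1-based) of `pattern` in `subject`.
anchor_hits <- function(pattern, subject) {
  r <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (r[1] == -1L) integer(0) else as.integer(r)
}

# Best-supported diagonal (b_pos - a_pos) among anchor hits; NULL when
# support is insufficient.
modal_diagonal <- function(diags, tol = 200L, min_support = 3L) {
  if (length(diags) < min_support) return(NULL)
  diags <- sort(diags)
  best_n <- 0L; best_med <- NULL
  i <- 1L
  for (i in seq_along(diags)) {
    j <- findInterval(diags[i] + tol, diags)
    n <- j - i + 1L
    if (n > best_n) {
      best_n <- n
      best_med <- stats::median(diags[i:j])
    }
  }
  if (best_n >= min_support) round(best_med) else NULL
}

#' Windowed high-identity alignment between two sequences
#'
#' Each window of sequence A is anchored in B (both orientations) by
#' exact k-mer seed matches; when enough seeds agree on a diagonal, the
#' window is globally aligned (banded) to the corresponding slice of B
#' and the identity recorded (matches over aligned columns, gap columns
#' included). Collinear same-orientation window hits with gaps up to one
#' window are chained into segments.
#'
#' @param seq_a,seq_b DNA strings.
#' @param window window size in bp (>= 1000); default 5000.
#' @param step step between window starts (<= window); default window/2.
#' @param name_a,name_b sequence names used in the output.
#' @param anchor_k seed k-mer length; default 32.
#' @param anchor_every spacing of seeds within a window; default 200.
#' @param min_anchor_support seeds that must agree on a diagonal before
#'   a window is aligned; default 3.
#' @return data.frame of segments (seq_a, start_a, end_a, seq_b,
#'   start_b, end_b, identity, orientation, n_windows), 0-based
#'   half-open, sorted by start_a.
#' @export
windowed_identity <- function(seq_a, seq_b, window = 5000L,
                              step = window %/% 2L,
                              name_a = "A", name_b = "B",
                              anchor_k = 32L, anchor_every = 200L,
                              min_anchor_support = 3L) {
  assert_dna(seq_a, "seq_a"); assert_dna(seq_b, "seq_b")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1000L) stop("window must be >= 1000", call. = FALSE)
  if (step > window || step < 1L)
    stop("step must lie in [1, window]", call. = FALSE)
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la < window)
    return(empty_segments())
  win_starts <- seq.int(0L, la - window, by = step)
  if (win_starts[length(win_starts)] != la - window)
    win_starts <- c(win_starts, la - window)

  hits <- list()
  for (orient in c("+", "-")) {
    b_str <- if (orient == "+") seq_b else revcomp(seq_b)
    for (ws in win_starts) {
      wseq <- substr(seq_a, ws + 1L, ws + window)
      apos <- seq.int(1L, window - anchor_k + 1L, by = anchor_every)
      diags <- integer(0)
      for (ap in apos) {
        hh <- anchor_hits(substr(wseq, ap, ap + anchor_k - 1L), b_str)
        if (length(hh)) diags <- c(diags, hh - (ws + ap))
      }
      dg <- modal_diagonal(diags, tol = 200L,
                           min_support = min_anchor_support)
      if (is.null(dg)) next
      bs <- ws + dg                     # 0-based slice start in b_str
      be <- bs + window
      bs <- max(bs, 0L); be <- min(be, lb)
      if (be - bs < window / 2) next
      al <- .nw_align_cpp(wseq, substr(b_str, bs + 1L, be),
                          band = 256L)
      tr <- trim_alignment(al)
      if (is.null(tr) || tr$columns < 300L || tr$identity < 0.8) next
      hits[[length(hits) + 1L]] <- data.frame(
        start_a = ws + tr$a_off, end_a = ws + tr$a_off + tr$a_len,
        bs = bs + tr$b_off, be = bs + tr$b_off + tr$b_len,
        diag = dg, identity = tr$identity, matches = tr$matches,
        columns = tr$columns, orientation = orient,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_segments())
  hits <- do.call(rbind, hits)

  # chain collinear hits per orientation
  segs <- list()
  for (orient in unique(hits$orientation)) {
    h <- hits[hits$orientation == orient, , drop = FALSE]
    h <- h[order(h$start_a), , drop = FALSE]
    chain_id <- cumsum(c(TRUE, diff(h$start_a) > window |
                           abs(diff(h$diag)) > window))
    for (cid in unique(chain_id)) {
      cc <- h[chain_id == cid, , drop = FALSE]
      bs <- min(cc$bs); be <- max(cc$be)
      if (orient == "-") { tmp <- lb - be; be <- lb - bs; bs <- tmp }
      segs[[length(segs) + 1L]] <- data.frame(
        seq_a = name_a, start_a = min(cc$start_a), end_a = max(cc$end_a),
        seq_b = name_b, start_b = bs, end_b = be,
        identity = sum(cc$matches) / sum(cc$columns),
        orientation = orient, n_windows = nrow(cc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$start_a, out$seq_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}


# Trim a global window alignment to its best local sub-segment: Kadane
# max-subarray on per-column scores (+1 match, -3 mismatch/gap; the
# penalty keeps the trim from drifting into unrelated flanks). Window
# edges overhanging the truly shared region are thereby discarded.
trim_alignment <- function(al) {
  a <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
  sc <- ifelse(a == b, 1L, -3L)
  cs <- cumsum(sc)
  lows <- cummin(c(0L, cs[-length(cs)]))
  gain <- cs - lows
  end <- which.max(gain)
  if (gain[end] <= 0L) return(NULL)
  start <- which(c(0L, cs[-length(cs)]) == lows[end])
  start <- start[start <= end][1]
  idx <- start:end
  a_in <- a[idx] != "-"; b_in <- b[idx] != "-"
  list(a_off = sum(a[seq_len(start - 1L)] != "-"),
       b_off = sum(b[seq_len(start - 1L)] != "-"),
       a_len = sum(a_in), b_len = sum(b_in),
       matches = sum(a[idx] == b[idx]), columns = length(idx),
       identity = mean(a[idx] == b[idx]))
}

empty_segments <- function() {
  data.frame(seq_a = character(0), start_a = integer(0),
             end_a = integer(0), seq_b = character(0),
             start_b = integer(0), end_b = integer(0),
             identity = numeric(0), orientation = character(0),
             n_windows = integer(0), stringsAsFactors = FALSE)
}

#' Call pseudo-homologous regions from identity segments
#'
#' Segments on the same sequence pair and orientation that abut or
#' overlap are merged (identity combined by span weighting), then both
#' thresholds are applied: identity at least \code{min_identity} over a
#' span of at least \code{min_span} bp on both sequences.
#'
#' @param segments data.frame from \code{\link{windowed_identity}}.
#' @param min_identity minimum identity; default 0.99.
#' @param min_span minimum span in bp; default 10000.
#' @return data.frame of PHR segments sorted by (seq_a, start_a), with a
#'   \code{merged} flag marking segments produced by merging.
#' @export
call_phrs <- function(segments, min_identity = 0.99, min_span = 10000L) {
  if (!nrow(segments)) {
    out <- empty_segments(); out$merged <- logical(0); return(out)
  }
  key <- paste(segments$seq_a, segments$seq_b, segments$orientation)
  merged <- list()
  for (kk in unique(key)) {
    s <- segments[key == kk, , drop = FALSE]
    s <- s[order(s$start_a), , drop = FALSE]
    # merge only collinear segments: overlapping/abutting on BOTH
    # sequences, so distinct homologous copies stay separate
    clusters <- list()
    for (i in seq_len(nrow(s))) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (s$start_a[i] <= max(s$end_a[cl]) &&
            s$start_b[i] <= max(s$end_b[cl]) &&
            s$end_b[i] >= min(s$start_b[cl])) {
          clusters[[ci]] <- c(cl, i); placed <- TRUE; break
        }
      }
      if (!placed) clusters[[length(clusters) + 1L]] <- i
    }
    for (cl in clusters) {
      ss <- s[cl, , drop = FALSE]
      w <- pmin(ss$end_a - ss$start_a, ss$end_b - ss$start_b)
      merged[[length(merged) + 1L]] <- data.frame(
        seq_a = ss$seq_a[1], start_a = min(ss$start_a),
        end_a = max(ss$end_a), seq_b = ss$seq_b[1],
        start_b = min(ss$start_b), end_b = max(ss$end_b),
        identity = sum(ss$identity * w) / sum(w),
        orientation = ss$orientation[1], merged = nrow(ss) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, merged)
  span <- pmin(out$end_a - out$start_a, out$end_b - out$start_b)
  out <- out[out$identity >= min_identity & span >= min_span, ,
             drop = FALSE]
  out <- out[order(out$seq_a, out$start_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the PHR sharing network across chromosomes
#'
#' One undirected edge per chromosome pair: \code{shared_bp} sums the
#' smaller span of each PHR between the pair, \code{mean_identity} is
#' the bp-weighted mean identity.
#'
#' @param phrs data.frame from \code{\link{call_phrs}}.
#' @param acrocentric_names character vector of chromosome names to flag
#'   acrocentric.
#' @param nodes optional character vector of all node names; defaults to
#'   the chromosomes seen in \code{phrs} plus \code{acrocentric_names}.
#' @return object of class \code{phr_network}: list with \code{nodes}
#'   (name, acrocentric) and \code{edges} (a, b, shared_bp,
#'   mean_identity).
#' @export
phr_network <- function(phrs, acrocentric_names = character(0),
                        nodes = NULL) {
  node_names <- sort(unique(c(phrs$seq_a, phrs$seq_b,
                              acrocentric_names, nodes)))
  nd <- data.frame(name = node_names,
                   acrocentric = node_names %in% acrocentric_names,
                   stringsAsFactors = FALSE)
  if (!nrow(phrs)) {
    edges <- data.frame(a = character(0), b = character(0),
                        shared_bp = integer(0), mean_identity = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    a <- pmin(phrs$seq_a, phrs$seq_b)
    b <- pmax(phrs$seq_a, phrs$seq_b)
    keep <- a != b                      # no self-edges
    bp <- pmin(phrs$end_a - phrs$start_a, phrs$end_b - phrs$start_b)
    dt <- data.table::data.table(a = a[keep], b = b[keep],
                                 bp = bp[keep],
                                 ident = phrs$identity[keep])
    edges <- as.data.frame(dt[, .(shared_bp = sum(bp),
                                  mean_identity = sum(ident * bp) / sum(bp)),
                              by = .(a, b)])
  }
  structure(list(nodes = nd, edges = edges), class = "phr_network")
}

#' @export
print.phr_network <- function(x, ...) {
  cat(sprintf("<phr_network> %d nodes (%d acrocentric), %d edges\n",
              nrow(x$nodes), sum(x$nodes$acrocentric), nrow(x$edges)))
  invisible(x)
}

#' Write a PHR network edge list as TSV
#' @param network a \code{phr_network}.
#' @param path output path.
#' @export
write_phr_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Self-identity matrix of a sequence
#'
#' The sequence is tiled into non-overlapping windows; every window pair
#' (i <= j) is globally aligned and its identity recorded. The diagonal
#' is 1 by definition. The long-format output (i, j, identity) is the
#' matrix behind triangular self-identity heatmaps.
#'
#' @param sequence DNA string, at least two windows long.
#' @param window window size in bp; default 5000.
#' @return data.frame (i, j, start_i, start_j, identity) with window
#'   indices 1-based and class \code{self_identity_matrix}; the window
#'   size is attached as attribute \code{window}.
#' @export
self_identity_matrix <- function(sequence, window = 5000L) {
  assert_dna(sequence)
  sequence <- toupper(sequence)
  window <- as.integer(window)
  n <- nchar(sequence)
  if (n < 2L * window)
    stop("sequence must span at least two windows", call. = FALSE)
  n_win <- n %/% window
  starts <- (seq_len(n_win) - 1L) * window
  wins <- substring(sequence, starts + 1L, starts + window)
  rows <- list()
  for (i in seq_len(n_win)) for (j in i:n_win) {
    ident <- if (i == j) 1.0 else
      .nw_align_cpp(wins[i], wins[j], band = max(64L, window %/% 8L))$identity
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, start_i = starts[i], start_j = starts[j],
      identity = ident)
  }
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  class(out) <- c("self_identity_matrix", "data.frame")
  out
}
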