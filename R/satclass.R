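# Profile-based classification of satellite monomers into families,
# array-level annotation with active/inactive layers, dimer haplotypes,
# and chromosome-specific k-mer signatures.

#' Train position-specific log-odds profiles from labeled monomers
#'
#' Each family's monomers are star-aligned to the family consensus and
#' base counts are accumulated per consensus column. Column
#' probabilities (with pseudocounts) are converted to log-odds against a
#' uniform background. Families trained from fewer than 5 monomers are
#' flagged low-confidence but remain usable.
#'
#' @param labeled_monomers named list mapping family name to a character
#'   vector of monomer sequences.
#' @param pseudocount added per base per column (fraction of the column
#'   total); 0 allows -Inf scores for unseen bases.
#' @return object of class \code{profile_set}.
#' @export
train_profiles <- function(labeled_monomers, pseudocount = 0.01) {
  if (!length(labeled_monomers) || is.null(names(labeled_monomers)))
    stop("labeled_monomers must be a non-empty named list", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  profiles <- list()
  for (fam in sort(names(labeled_monomers))) {
    mono <- toupper(labeled_monomers[[fam]])
    if (!length(mono))
      stop("family '", fam, "' has no training monomers", call. = FALSE)
    lens <- nchar(mono)
    if (max(lens) > 1.1 * min(lens))
      stop("family '", fam, "' monomer lengths differ by more than 10%",
           call. = FALSE)
    cons <- if (length(mono) >= 2L) build_consensus(mono) else mono[1]
    L <- nchar(cons)
    counts <- matrix(0, nrow = L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    for (m in mono) {
      if (nchar(m) == L && m == cons) {
        idx <- match(strsplit(cons, "")[[1]], DNA_BASES)
        counts[cbind(seq_len(L), idx)] <- counts[cbind(seq_len(L), idx)] + 1
        next
      }
      al <- sat_align(cons, m, band = 16L)
      ca <- strsplit(al$a_aln, "")[[1]]
      ma <- strsplit(al$b_aln, "")[[1]]
      keep <- ca != "-"
      mc <- ma[keep]
      idx <- match(mc, DNA_BASES)
      ok <- !is.na(idx)
      counts[cbind(which(ok), idx[ok])] <- counts[cbind(which(ok), idx[ok])] + 1
    }
    tot <- rowSums(counts)
    prob <- (counts + pseudocount * pmax(tot, 1)) /
      (pmax(tot, 1) * (1 + 4 * pseudocount))
    logodds <- log(prob / 0.25)
    profiles[[fam]] <- list(logodds = logodds, consensus = cons,
                            length = L, n_training = length(mono),
                            low_confidence = length(mono) < 5L)
  }
  structure(list(profiles = profiles,
                 training_counts = vapply(profiles, `[[`, 0L, "n_training"),
                 background = rep(0.25, 4L)),
            class = "profile_set")
}

#' Train a profile set directly from a monomer library
#'
#' Convenience wrapper: each family consensus acts as its single training
#' monomer (profiles are flagged low-confidence).
#' @param library a \code{monomer_library}.
#' @param pseudocount see \code{\link{train_profiles}}.
#' @return a \code{profile_set}.
#' @export
profiles_from_library <- function(library, pseudocount = 0.01) {
  stopifnot(inherits(library, "monomer_library"))
  train_profiles(setNames(as.list(library$families$consensus),
                          library$families$family), pseudocount)
}

# Total log-odds of `seq` under one profile. Sequences whose
# length matches the profile are scored directly; others are projected
# onto profile columns by global alignment to the profile consensus.
score_profile <- function(seq, prof) {
  L <- prof$length
  lo <- prof$logodds
  if (nchar(seq) == L) {
    idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
    ok <- !is.na(idx)
    if (!any(ok)) return(-Inf)
    return(sum(lo[cbind(which(ok), idx[ok])]))
  }
  al <- sat_align(prof$consensus, seq, band = 24L)
  ca <- strsplit(al$a_aln, "")[[1]]
  sa <- strsplit(al$b_aln, "")[[1]]
  keep <- ca != "-"
  sc <- sa[keep]
  idx <- match(sc, DNA_BASES)
  ok <- !is.na(idx)
  if (!any(ok)) return(-Inf)
  sum(lo[cbind(which(ok), idx[ok])])
}

#' Classify monomers against a profile set
#'
#' Every monomer is scored against every profile on both strands; the
#' best (family, strand) wins. Scores are summed log-odds over profile
#' columns (monomer lengths are near-constant, so totals are comparable
#' across families). Assignments whose margin
#' over the runner-up family falls below \code{min_margin} are labeled
#' \code{"ambiguous"}. Results are independent of monomer and profile
#' order (ties broken by lexicographic family name).
#'
#' @param monomers data.frame from \code{\link{segment_monomers}} (or any
#'   data.frame with a \code{sequence} column), or a character vector.
#' @param profiles a \code{profile_set}.
#' @param min_margin minimum log-odds gap to the runner-up family;
#'   default 2.0.
#' @return data.frame: the monomer columns plus \code{family},
#'   \code{score}, \code{margin}, \code{strand}.
#' @export
classify_monomers <- function(monomers, profiles, min_margin = 2.0) {
  stopifnot(inherits(profiles, "profile_set"))
  if (is.character(monomers))
    monomers <- data.frame(sequence_name = "query",
                           start = 0L, end = nchar(monomers),
                           strand = "+", sequence = monomers,
                           stringsAsFactors = FALSE)
  if (!nrow(monomers))
    return(cbind(monomers[0, , drop = FALSE],
                 family = character(0), score = numeric(0),
                 margin = numeric(0)))
  fams <- names(profiles$profiles)   # already sorted at training
  res <- lapply(monomers$sequence, function(s) {
    s <- toupper(s)
    rc <- revcomp(s)
    sc_f <- vapply(fams, function(f)
      score_profile(s, profiles$profiles[[f]]), numeric(1))
    sc_r <- vapply(fams, function(f)
      score_profile(rc, profiles$profiles[[f]]), numeric(1))
    per_fam <- pmax(sc_f, sc_r)
    ord <- order(-per_fam, fams)
    best <- ord[1]
    margin <- if (length(fams) > 1L) per_fam[best] - per_fam[ord[2]] else Inf
    data.frame(family = fams[best], score = per_fam[best],
               margin = margin,
               strand = if (sc_f[best] >= sc_r[best]) "+" else "-",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$family[res$margin < min_margin] <- "ambiguous"
  out <- monomers
  out$family <- res$family
  out$score <- res$score
  out$margin <- res$margin
  out$strand <- res$strand
  out
}

#' Merge monomer assignments into annotated satellite arrays
#'
#' Maximal runs of same-family monomers (inter-monomer gaps at most
#' \code{max_gap} bp) become arrays; runs with fewer than
#' \code{min_array_monomers} monomers are dropped. Within each declared
#' centromere window the largest array (by monomer count) is labeled
#' \code{active}; all other arrays are \code{inactive} flanking layers.
#'
#' @param assignments data.frame from \code{\link{classify_monomers}},
#'   sorted by (sequence_name, start).
#' @param min_array_monomers minimum monomers per array; default 10.
#' @param max_gap largest within-array gap in bp; default 500.
#' @param centromere_windows optional named list mapping sequence_name to
#'   c(start, end); when given, active/inactive layers are assigned per
#'   window, otherwise the largest array per sequence is active.
#' @param family_groups optional named character vector mapping monomer
#'   family to an array-level family (e.g. both monomer types of a dimer
#'   to their subSF label); unmapped families keep their own name.
#' @return data.frame (sequence_name, start, end, family, layer,
#'   n_monomers).
#' @export
annotate_satellite_arrays <- function(assignments, min_array_monomers = 10L,
                                      max_gap = 500L,
                                      centromere_windows = NULL,
                                      family_groups = NULL) {
  need <- c("sequence_name", "start", "end", "family")
  if (!all(need %in% names(assignments)))
    stop("assignments must carry ", paste(need, collapse = ", "),
         call. = FALSE)
  idx <- order(assignments$sequence_name, assignments$start)
  if (!identical(idx, seq_len(nrow(assignments))))
    stop("assignments must be sorted by (sequence_name, start)",
         call. = FALSE)
  grp_of <- function(f) {
    if (is.null(family_groups)) return(f)
    g <- family_groups[f]
    ifelse(is.na(g), f, g)
  }
  assignments$family <- grp_of(assignments$family)
  arrays <- list()
  for (nm in unique(assignments$sequence_name)) {
    a <- assignments[assignments$sequence_name == nm, , drop = FALSE]
    if (!nrow(a)) next
    new_run <- c(TRUE, a$family[-1] != a$family[-nrow(a)] |
                   a$start[-1] - a$end[-nrow(a)] > max_gap)
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      rr <- a[run_id == r, , drop = FALSE]
      if (nrow(rr) < min_array_monomers) next
      if (rr$family[1] == "ambiguous") next
      arrays[[length(arrays) + 1L]] <- data.frame(
        sequence_name = nm, start = min(rr$start), end = max(rr$end),
        family = rr$family[1], n_monomers = nrow(rr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(arrays))
    return(data.frame(sequence_name = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      layer = character(0), n_monomers = integer(0)))
  out <- do.call(rbind, arrays)
  out$layer <- "inactive"
  for (nm in unique(out$sequence_name)) {
    sel <- out$sequence_name == nm
    if (!is.null(centromere_windows) &&
        !is.null(centromere_windows[[nm]])) {
      w <- centromere_windows[[nm]]
      inwin <- sel & out$start < w[2] & out$end > w[1]
    } else inwin <- sel
    if (any(inwin)) {
      cand <- which(inwin)
      best <- cand[order(-out$n_monomers[cand], out$start[cand])][1]
      out$layer[best] <- "active"
    }
  }
  out <- out[order(out$sequence_name, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("sequence_name", "start", "end", "family", "layer", "n_monomers")]
}

#' Call centromere-specific dimer haplotypes (dimhaps)
#'
#' Array dimer consensuses are clustered by single linkage at
#' \code{link_identity} pairwise identity (global alignment, gap columns
#' counted). Each cluster is one dimhap; its specificity is the fraction
#' of member arrays on the modal chromosome.
#'
#' @param array_dimer_consensuses named character vector of dimer
#'   consensus sequences, one per array.
#' @param chromosomes named character vector mapping array name to
#'   chromosome; defaults to the array names themselves.
#' @param link_identity single-linkage threshold; default 0.99.
#' @return data.frame (dimhap_id, n_members, specificity,
#'   modal_chromosome, consensus_dimer) with a \code{members} list column.
#' @export
call_dimhaps <- function(array_dimer_consensuses, chromosomes = NULL,
                         link_identity = 0.99) {
  x <- array_dimer_consensuses
  if (!length(x))
    return(data.frame(dimhap_id = character(0), n_members = integer(0),
                      specificity = numeric(0),
                      modal_chromosome = character(0),
                      consensus_dimer = character(0)))
  if (is.null(names(x))) names(x) <- paste0("array", seq_along(x))
  if (is.null(chromosomes)) chromosomes <- setNames(names(x), names(x))
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- alignment_identity(x[[i]], x[[j]], band = 32L)
    if (id >= link_identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  out <- lapply(sort(unique(cl)), function(cid) {
    members <- names(x)[cl == cid]
    chroms <- chromosomes[members]
    modal <- names(sort(table(chroms), decreasing = TRUE))[1]
    data.frame(dimhap_id = sprintf("dimhap_%02d", cid),
               n_members = length(members),
               specificity = mean(chroms == modal),
               modal_chromosome = modal,
               consensus_dimer = x[[members[1]]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$members <- lapply(sort(unique(cl)), function(cid) names(x)[cl == cid])
  out
}

#' Chromosome-specific k-mer signatures of active arrays
#'
#' For each array, the set of canonical k-mers (lexicographic minimum of
#' the k-mer and its reverse complement) occurring at least
#' \code{min_copies} times in that array and never in any other array.
#' Disjointness across arrays holds by construction and is asserted.
#'
#' @param active_arrays named character vector of active-array sequences
#'   (>= 2 arrays).
#' @param k k-mer size; default 21.
#' @param min_copies minimum in-array copy number; default 5.
#' @return named list of character vectors (possibly empty) of k-mers.
#' @export
kmer_signatures <- function(active_arrays, k = 21L, min_copies = 5L) {
  if (length(active_arrays) < 2L)
    stop("need at least 2 active arrays", call. = FALSE)
  if (any(nchar(active_arrays) < k))
    stop("k exceeds the shortest array", call. = FALSE)
  k <- as.integer(k)
  canon_counts <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq)
    starts <- seq_len(n - k + 1L)
    km <- substring(seq, starts, starts + k - 1L)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    canon <- pmin(km, rc)
    table(canon)
  }
  counts <- lapply(active_arrays, canon_counts)
  nms <- names(active_arrays)
  sigs <- setNames(vector("list", length(nms)), nms)
  for (i in seq_along(nms)) {
    own <- counts[[i]]
    cand <- names(own)[own >= min_copies]
    for (j in seq_along(nms)) {
      if (j == i || !length(cand)) next
      cand <- cand[!cand %in% names(counts[[j]])]
    }
    sigs[[i]] <- sort(cand)
  }
  # pairwise disjointness is structural; assert it anyway
  all_k <- unlist(sigs, use.names = FALSE)
  stopifnot(!anyDuplicated(all_k))
  sigs
}

#' Serialize a profile set as a TSV matrix
#'
#' Long format: family, position (1-based), log-odds for A/C/G/T, plus
#' the training count per family; round-trips through
#' \code{\link{read_profiles}}.
#' @param profiles a \code{profile_set}.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_set"))
  rows <- lapply(names(profiles$profiles), function(fam) {
    p <- profiles$profiles[[fam]]
    data.frame(family = fam, position = seq_len(p$length),
               consensus = strsplit(p$consensus, "")[[1]],
               A = p$logodds[, "A"], C = p$logodds[, "C"],
               G = p$logodds[, "G"], T = p$logodds[, "T"],
               n_training = p$n_training, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a profile set written by \code{\link{write_profiles}}
#' @param path path to the TSV.
#' @return a \code{profile_set}.
#' @export
read_profiles <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c(consensus = "character"))
  profiles <- lapply(split(df, df$family), function(d) {
    d <- d[order(d$position), ]
    lo <- as.matrix(d[, c("A", "C", "G", "T")])
    dimnames(lo) <- list(NULL, c("A", "C", "G", "T"))
    list(logodds = lo, consensus = paste(d$consensus, collapse = ""),
         length = nrow(d), n_training = d$n_training[1],
         low_confidence = d$n_training[1] < 5L)
  })
  profiles <- profiles[sort(names(profiles))]
  structure(list(profiles = profiles,
                 training_counts = vapply(profiles, `[[`, 0L,
                                          "n_training"),
                 background = rep(0.25, 4L)),
            class = "profile_set")
}

#' Write k-mer signatures as a two-column TSV (array, kmer)
#' @param signatures named list from \code{\link{kmer_signatures}}.
#' @param path output path.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(
    array = rep(names(signatures), lengths(signatures)),
    kmer = unlist(signatures, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
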