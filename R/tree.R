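# Monomer/dimer phylogenetics: neighbor-joining trees from alignment
# identity distances, and a permutation test for chromosome-specific
# homogenization of satellite variants.

#' Build a neighbor-joining tree from sequences
#'
#' Pairwise distance is 1 minus global-alignment identity (gap columns
#' counted). The tree is estimated with neighbor joining, a standard
#' minimum-evolution heuristic; on an additive distance matrix NJ
#' recovers the true topology.
#'
#' @param sequences named character vector (>= 3 sequences).
#' @param newick_path optional path; when given the tree is also written
#'   in Newick format.
#' @return an \code{ape} \code{phylo} object.
#' @export
build_tree <- function(sequences, newick_path = NULL) {
  if (length(sequences) < 3L)
    stop("need at least 3 sequences", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <-
      1 - alignment_identity(sequences[[i]], sequences[[j]], band = 32L)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(newick_path)) ape::write.tree(tree, file = newick_path)
  tree
}

#' Test chromosome-specific homogenization of satellite monomers
#'
#' The concordance statistic is the fraction of taxa whose nearest tree
#' neighbor (smallest patristic distance; ties averaged over the tied
#' set) shares the taxon's chromosome label. Significance is assessed by
#' permuting labels across taxa: p = (1 + #permuted >= observed) /
#' (1 + n_permutations). A p-value near 1 (and a statistic near the
#' label-frequency baseline) indicates no differential homogenization,
#' i.e. variants are exchanged freely across chromosomes.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param chromosome_labels named character vector mapping tip label to
#'   chromosome (>= 2 chromosomes represented).
#' @param n_permutations number of label shuffles (>= 100 recommended;
#'   fewer allowed with a warning for degenerate tiny inputs).
#' @param seed integer seed for the permutations.
#' @return list with \code{statistic}, \code{p_value},
#'   \code{n_permutations}.
#' @export
homogenization_test <- function(tree, chromosome_labels,
                                n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  labels <- chromosome_labels[tips]
  if (any(is.na(labels)))
    stop("chromosome_labels must cover every tip", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need at least 2 chromosomes represented", call. = FALSE)
  n <- length(tips)
  if (n < 4L)
    warning("very few taxa: permutation p-value is coarse")
  D <- ape::cophenetic.phylo(tree)
  diag(D) <- Inf
  # nearest neighbour index set per taxon (ties kept)
  nn <- lapply(seq_len(n), function(i) which(D[i, ] == min(D[i, ])))
  concord <- function(lab) {
    mean(vapply(seq_len(n), function(i) mean(lab[nn[[i]]] == lab[i]),
                numeric(1)))
  }
  observed <- concord(labels)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
    concord(sample(labels)), numeric(1)))
  p <- (1 + sum(perm >= observed)) / (1 + n_permutations)
  list(statistic = observed, p_value = p,
       n_permutations = as.integer(n_permutations))
}
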