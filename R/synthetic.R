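# Synthetic genome generator: satellite arrays, acrocentric arms, rDNA
# arrays and matching depth/methylation tracks, all with planted ground
# truth so downstream stages can be validated without external data.

#' Build a library of satellite monomer families
#'
#' Families are derived from a common ancestral monomer so that every
#' pair of family consensuses diverges by approximately
#' \code{inter_family_divergence} (Hamming fraction). Mutation positions
#' are resampled (bounded retries) until all pairwise divergences fall
#' within 20\% of the request, so the library honours its contract
#' deterministically for a fixed seed.
#'
#' @param n_families number of families (>= 1).
#' @param monomer_length consensus length in bp (e.g. 170 for
#'   alpha-satellite monomers, 171 for subterminal satellite).
#' @param inter_family_divergence target pairwise divergence, in (0, 0.5).
#' @param seed integer seed.
#' @param family_names optional character vector of family names.
#' @return an object of class \code{monomer_library}: list with
#'   \code{families} (data.frame: family, consensus, monomer_length) and
#'   \code{seed}.
#' @export
make_monomer_library <- function(n_families, monomer_length,
                                 inter_family_divergence = 0.2,
                                 seed = 1L, family_names = NULL) {
  if (!is.numeric(n_families) || n_families < 1)
    stop("n_families must be >= 1", call. = FALSE)
  if (inter_family_divergence <= 0 || inter_family_divergence >= 0.5)
    stop("inter_family_divergence must lie in (0, 0.5)", call. = FALSE)
  n_families <- as.integer(n_families)
  if (is.null(family_names))
    family_names <- paste0("F", seq_len(n_families))
  if (length(family_names) != n_families || anyDuplicated(family_names))
    stop("family_names must be unique and match n_families", call. = FALSE)

  D <- inter_family_divergence
  L <- as.integer(monomer_length)
  with_seed(seed, {
    ancestor <- random_dna(L)
    if (n_families == 1L) {
      cons <- ancestor
    } else if (n_families == 2L) {
      # exact: mutate family 2 from family 1 at round(D * L) positions
      cons <- c(ancestor, mutate_substitutions(ancestor, round(D * L)))
    } else {
      # mutate each family from the ancestor at rate r chosen so that the
      # expected pairwise divergence is D: P(differ) = 2r - (4/3) r^2
      r <- (2 - sqrt(4 - (16 / 3) * D)) / (8 / 3)
      ok <- FALSE
      for (try in 1:200) {
        cons <- vapply(seq_len(n_families), function(i)
          mutate_substitutions(ancestor, round(r * L)), character(1))
        dv <- utils::combn(n_families, 2, function(ij) {
          a <- strsplit(cons[ij[1]], "")[[1]]
          b <- strsplit(cons[ij[2]], "")[[1]]
          mean(a != b)
        })
        if (all(abs(dv - D) <= 0.2 * D)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not realise requested inter-family divergence; ",
             "try a longer monomer or larger divergence", call. = FALSE)
    }
    structure(list(
      families = data.frame(family = family_names, consensus = cons,
                            monomer_length = L, stringsAsFactors = FALSE),
      seed = as.integer(seed)), class = "monomer_library")
  })
}

#' @export
print.monomer_library <- function(x, ...) {
  cat(sprintf("<monomer_library> %d families, monomer length %d bp\n",
              nrow(x$families), x$families$monomer_length[1]))
  invisible(x)
}

#' Specify a tandem satellite array
#'
#' @param unit_pattern ordered character vector of family names forming
#'   the repeating unit (length 2 for a dimer, 28 for the X-chromosome
#'   higher-order repeat, ...).
#' @param n_units number of repetitions of the unit (>= 1).
#' @param substitution_rate per-base substitution probability, in [0, 0.25].
#' @param indel_rate per-base single-base indel probability, in [0, 0.25];
#'   net indels are capped at +/- 3 bp per monomer so monomer lengths stay
#'   near nominal.
#' @param strand "+" or "-"; "-" emits the reverse complement with truth
#'   coordinates on the emitted sequence.
#' @param seed integer seed.
#' @return an object of class \code{array_spec}.
#' @export
array_spec <- function(unit_pattern, n_units, substitution_rate = 0,
                       indel_rate = 0, strand = "+", seed = 1L) {
  if (length(unit_pattern) < 1L) stop("unit_pattern is empty", call. = FALSE)
  if (n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  for (r in c(substitution_rate, indel_rate))
    if (r < 0 || r > 0.25)
      stop("mutation rates must lie in [0, 0.25]", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be + or -", call. = FALSE)
  structure(list(unit_pattern = as.character(unit_pattern),
                 n_units = as.integer(n_units),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, strand = strand,
                 seed = as.integer(seed)), class = "array_spec")
}

# Mutate one monomer copy: substitutions at `sub_rate`, single-base indels
# at `indel_rate` with net length change capped at +/- 3 bp.
mutate_monomer <- function(consensus, sub_rate, indel_rate) {
  L <- nchar(consensus)
  seq <- mutate_substitutions(consensus, rbinom(1L, L, sub_rate))
  if (indel_rate > 0) {
    n_indel <- min(rbinom(1L, L, indel_rate), 3L)
    for (k in seq_len(n_indel)) {
      chars <- strsplit(seq, "")[[1]]
      p <- sample.int(length(chars), 1L)
      if (runif(1) < 0.5 && length(chars) > 1L) {
        chars <- chars[-p]                       # deletion
      } else {
        ins <- DNA_BASES[sample.int(4L, 1L)]     # insertion
        chars <- append(chars, ins, after = p)
      }
      seq <- paste(chars, collapse = "")
    }
  }
  seq
}

#' Synthesize a tandem satellite array with planted truth
#'
#' Concatenates \code{n_units} copies of the repeating unit defined by
#' \code{spec$unit_pattern}, mutating each monomer copy independently.
#' The truth table holds one record per monomer with its family and
#' strand. On strand "-" the reverse complement is emitted and truth
#' coordinates refer to the emitted sequence.
#'
#' @param library a \code{monomer_library}.
#' @param spec an \code{array_spec}.
#' @param sequence_name name used in truth records.
#' @return list with \code{sequence} (DNA string) and \code{truth}.
#' @export
synthesize_array <- function(library, spec, sequence_name = "array") {
  stopifnot(inherits(library, "monomer_library"),
            inherits(spec, "array_spec"))
  fam <- library$families
  unknown <- setdiff(spec$unit_pattern, fam$family)
  if (length(unknown))
    stop("unknown family in unit_pattern: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cons <- setNames(fam$consensus, fam$family)

  with_seed(spec$seed, {
    classes <- rep(spec$unit_pattern, times = spec$n_units)
    seqs <- vapply(classes, function(f)
      mutate_monomer(cons[[f]], spec$substitution_rate, spec$indel_rate),
      character(1), USE.NAMES = FALSE)
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    starts <- ends - lens
    seq <- paste(seqs, collapse = "")
    truth <- data.frame(sequence_name = sequence_name, start = starts,
                        end = ends, feature_class = classes, strand = "+",
                        monomer_index = seq_along(classes),
                        stringsAsFactors = FALSE)
    if (spec$strand == "-") {
      total <- nchar(seq)
      seq <- revcomp(seq)
      new_start <- total - truth$end
      truth$end <- total - truth$start
      truth$start <- new_start
      truth$strand <- "-"
    }
    list(sequence = seq, truth = as_truth(truth))
  })
}

#' Build a scaled-down rDNA unit model
#'
#' One rDNA unit is a 45S-like coding region followed by an intergenic
#' spacer (IGS). Real units are tens of kb; the model defaults are
#' desk-scale stand-ins that preserve the coding/IGS structure.
#'
#' @param coding_length coding (45S-like) length in bp.
#' @param igs_length intergenic spacer length in bp.
#' @param seed integer seed.
#' @return list with \code{coding} and \code{igs} consensus strings.
#' @export
rdna_unit_model <- function(coding_length = 3000, igs_length = 1500,
                            seed = 99L) {
  with_seed(seed, list(coding = random_dna(coding_length),
                       igs = random_dna(igs_length)))
}

# --- acrocentric arm plans -------------------------------------------------

#' Plan features for an acrocentric short arm
#'
#' Each feature is a list with a \code{type} field, placed in order from
#' telomere to centromere:
#' \describe{
#'   \item{satellite}{\code{library}, \code{spec} (an \code{array_spec}),
#'     optional \code{class} label for the truth block.}
#'   \item{rdna}{\code{model} (from \code{\link{rdna_unit_model}}),
#'     \code{n_units}, \code{substitution_rate}, and optional
#'     \code{insertions}: list of \code{list(unit, position, length,
#'     class)} planting a retrotransposon-like insertion inside that
#'     unit's coding region (the unit is then flagged degraded).}
#'   \item{phr_donor}{\code{sequence} (donor DNA shared with another
#'     arm), \code{identity} target in (0, 1]; the donor is copied and
#'     mutated down to the requested identity.}
#'   \item{spacer}{\code{length}: random transposable-element-like
#'     spacer DNA.}
#' }
#'
#' rDNA units are emitted so that transcription (coding then IGS) runs
#' from the telomere toward the centromere.
#'
#' @param plan list of feature lists, ordered telomere to centromere.
#' @param seed integer seed.
#' @param arm_name sequence name used in truth records.
#' @return list with \code{sequence} and \code{truth}; rDNA truth rows
#'   carry \code{intact} and coding coordinates in attribute columns.
#' @export
synthesize_acrocentric_arm <- function(plan, seed = 1L, arm_name = "arm") {
  if (!length(plan)) stop("empty arm plan", call. = FALSE)
  with_seed(seed, {
    pieces <- character(0)
    rows <- list()
    pos <- 0L
    feature_seeds <- sample.int(1e6, length(plan))
    for (i in seq_along(plan)) {
      f <- plan[[i]]
      type <- f$type %||% stop("plan feature without type", call. = FALSE)
      if (type == "satellite") {
        sp <- f$spec
        sp$seed <- feature_seeds[i]
        arr <- synthesize_array(f$library, sp, sequence_name = arm_name)
        tr <- arr$truth
        tr$start <- tr$start + pos
        tr$end <- tr$end + pos
        if (!is.null(f$class)) tr$block <- f$class
        rows[[length(rows) + 1L]] <- tr
        pieces <- c(pieces, arr$sequence)
        pos <- pos + nchar(arr$sequence)
      } else if (type == "rdna") {
        em <- emit_rdna_block(f, feature_seeds[i], arm_name, pos)
        rows[[length(rows) + 1L]] <- em$truth
        pieces <- c(pieces, em$sequence)
        pos <- pos + nchar(em$sequence)
      } else if (type == "phr_donor") {
        target <- f$identity %||% 0.99
        if (target <= 0 || target > 1)
          stop("phr_donor identity must be in (0, 1]", call. = FALSE)
        # each arm's copy carries half the divergence, so two arms built
        # from the same donor share the requested pairwise identity
        n_mut <- round((1 - target) / 2 * nchar(f$sequence))
        seq <- mutate_substitutions(f$sequence, n_mut)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_name = arm_name, start = pos, end = pos + nchar(seq),
          feature_class = f$class %||% "phr_donor", strand = "+",
          stringsAsFactors = FALSE)
        pieces <- c(pieces, seq)
        pos <- pos + nchar(seq)
      } else if (type == "spacer") {
        seq <- random_dna(f$length)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_name = arm_name, start = pos, end = pos + nchar(seq),
          feature_class = "spacer", strand = "+", stringsAsFactors = FALSE)
        pieces <- c(pieces, seq)
        pos <- pos + nchar(seq)
      } else stop("unknown plan feature type: ", type, call. = FALSE)
    }
    truth <- data.table::rbindlist(rows, fill = TRUE)
    truth <- as_truth(as.data.frame(truth))
    list(sequence = paste(pieces, collapse = ""), truth = truth)
  })
}

# Emit one rDNA block (tandem units, telomere->centromere transcription).
emit_rdna_block <- function(f, seed, arm_name, pos) {
  model <- f$model
  n_units <- f$n_units %||% stop("rdna feature needs n_units", call. = FALSE)
  sub_rate <- f$substitution_rate %||% 0.005
  insertions <- f$insertions %||% list()
  with_seed(seed, {
    pieces <- character(0)
    rows <- list()
    p <- pos
    for (u in seq_len(n_units)) {
      coding <- mutate_substitutions(model$coding,
                                     rbinom(1L, nchar(model$coding), sub_rate))
      igs <- mutate_substitutions(model$igs,
                                  rbinom(1L, nchar(model$igs), sub_rate))
      ins_here <- Filter(function(x) x$unit == u, insertions)
      intact <- length(ins_here) == 0L
      for (ins in ins_here) {
        ipos <- min(max(1L, ins$position), nchar(coding))
        coding <- paste0(substr(coding, 1L, ipos), random_dna(ins$length),
                         substr(coding, ipos + 1L, nchar(coding)))
      }
      unit_seq <- paste0(coding, igs)
      rows[[u]] <- data.frame(
        sequence_name = arm_name, start = p, end = p + nchar(unit_seq),
        feature_class = "rdna_unit", strand = "+",
        coding_start = p, coding_end = p + nchar(coding),
        intact = intact, stringsAsFactors = FALSE)
      pieces <- c(pieces, unit_seq)
      p <- p + nchar(unit_seq)
    }
    list(sequence = paste(pieces, collapse = ""),
         truth = do.call(rbind, rows))
  })
}

#' Synthesize a multi-chromosome genome and write FASTA + truth BED
#'
#' @param config list with \code{seed} and \code{chromosomes}: a named
#'   list mapping chromosome name to either an arm \code{plan} (see
#'   \code{\link{synthesize_acrocentric_arm}}) or a list with
#'   \code{library} and \code{spec} for a plain satellite chromosome.
#' @param fasta_path,bed_path output paths; omit (NULL) to skip writing.
#' @return list with \code{sequences} (named character vector),
#'   \code{truth}, and the paths written.
#' @export
synthesize_genome <- function(config, fasta_path = NULL, bed_path = NULL) {
  if (is.null(config$chromosomes) || !length(config$chromosomes))
    stop("config must declare at least one chromosome", call. = FALSE)
  seed <- config$seed %||% 1L
  chrom_names <- names(config$chromosomes)
  if (is.null(chrom_names) || any(!nzchar(chrom_names)))
    stop("chromosomes must be named", call. = FALSE)
  seqs <- list(); truths <- list()
  chrom_seeds <- with_seed(seed, sample.int(1e6, length(chrom_names)))
  for (i in seq_along(chrom_names)) {
    nm <- chrom_names[i]
    ch <- config$chromosomes[[i]]
    if (!is.null(ch$plan)) {
      out <- synthesize_acrocentric_arm(ch$plan, seed = chrom_seeds[i],
                                        arm_name = nm)
    } else if (!is.null(ch$library) && !is.null(ch$spec)) {
      sp <- ch$spec; sp$seed <- chrom_seeds[i]
      out <- synthesize_array(ch$library, sp, sequence_name = nm)
    } else stop("chromosome '", nm,
                "' needs either a plan or library+spec", call. = FALSE)
    seqs[[nm]] <- out$sequence
    truths[[nm]] <- as.data.frame(out$truth)
  }
  truth <- as_truth(as.data.frame(data.table::rbindlist(truths, fill = TRUE)))
  sequences <- unlist(seqs)
  if (!is.null(fasta_path)) write_fasta(sequences, fasta_path)
  if (!is.null(bed_path)) write_bed(truth, bed_path)
  list(sequences = sequences, truth = truth,
       fasta = fasta_path, bed = bed_path)
}

#' Specify depth/methylation track simulation
#'
#' @param mean_depth single-copy (diploid) mean read depth.
#' @param noise_sd Gaussian noise s.d. on per-bin depth.
#' @param methylation_states named list/vector mapping feature_class to
#'   methylated fraction in [0, 1]; bins outside any listed class get the
#'   \code{default_methylation}.
#' @param bin_size bin width in bp (>= 1).
#' @param default_methylation background methylated fraction.
#' @return object of class \code{track_spec}.
#' @export
track_spec <- function(mean_depth = 30, noise_sd = 2,
                       methylation_states = list(), bin_size = 100L,
                       default_methylation = 0.5) {
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (bin_size < 1) stop("bin_size must be >= 1", call. = FALSE)
  ms <- unlist(methylation_states)
  if (length(ms) && (any(ms < 0) || any(ms > 1)))
    stop("methylation states must lie in [0, 1]", call. = FALSE)
  structure(list(mean_depth = mean_depth, noise_sd = noise_sd,
                 methylation_states = as.list(ms),
                 bin_size = as.integer(bin_size),
                 default_methylation = default_methylation),
            class = "track_spec")
}

#' Simulate depth and methylation tracks over a synthetic genome
#'
#' Depth follows the diploid convention: a single-copy region sits at
#' \code{mean_depth}; bins overlapping rDNA units are scaled by
#' \code{rdna_total_copies / 2}, emulating the collapse of all genomic
#' copies onto the reference unit coordinates. Methylation per bin is
#' drawn from a beta distribution centred on the state requested for the
#' bin's feature class.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param truth truth table for those sequences.
#' @param spec a \code{track_spec}.
#' @param rdna_total_copies diploid rDNA copy number to emulate (>= 0).
#' @param rdna_class feature class of rDNA units in the truth table.
#' @param seed integer seed.
#' @return list with \code{depth} and \code{methylation} data.frames
#'   (chrom, bin_start, value).
#' @export
simulate_depth_track <- function(sequences, truth, spec,
                                 rdna_total_copies = 0,
                                 rdna_class = "rdna_unit", seed = 1L) {
  stopifnot(inherits(spec, "track_spec"))
  if (rdna_total_copies < 0)
    stop("rdna_total_copies must be >= 0", call. = FALSE)
  truth <- as.data.frame(truth)
  bs <- spec$bin_size
  with_seed(seed, {
    depth <- list(); meth <- list()
    for (nm in names(sequences)) {
      L <- nchar(sequences[[nm]])
      bin_start <- seq.int(0L, L - 1L, by = bs)
      n <- length(bin_start)
      bin_mid <- bin_start + bs %/% 2L
      tr <- truth[truth$sequence_name == nm, , drop = FALSE]
      # feature class per bin: the class whose interval covers the midpoint
      cls <- rep(NA_character_, n)
      if (nrow(tr)) {
        hit <- IRanges::findOverlaps(
          IRanges::IRanges(bin_mid + 1L, bin_mid + 1L),
          IRanges::IRanges(tr$start + 1L, tr$end), select = "first")
        cls <- tr$feature_class[hit]
      }
      mult <- ifelse(!is.na(cls) & cls == rdna_class,
                     rdna_total_copies / 2, 1)
      d <- mult * spec$mean_depth +
        rnorm(n, 0, spec$noise_sd) * sqrt(pmax(mult, 1e-9))
      d <- pmax(d, 0)
      # methylation state by feature class; coding sub-state if the truth
      # carries coding coordinates and a distinct "coding"/"igs" request
      m_target <- rep(spec$default_methylation, n)
      for (k in names(spec$methylation_states))
        m_target[!is.na(cls) & cls == k] <-
          spec$methylation_states[[k]]
      if (any(c("coding", "igs") %in% names(spec$methylation_states)) &&
          "coding_start" %in% names(tr) && nrow(tr)) {
        rd <- tr[tr$feature_class == rdna_class & !is.na(tr$coding_start), ,
                 drop = FALSE]
        if (nrow(rd)) {
          in_coding <- IRanges::overlapsAny(
            IRanges::IRanges(bin_mid + 1L, bin_mid + 1L),
            IRanges::IRanges(rd$coding_start + 1L, rd$coding_end))
          in_unit <- IRanges::overlapsAny(
            IRanges::IRanges(bin_mid + 1L, bin_mid + 1L),
            IRanges::IRanges(rd$start + 1L, rd$end))
          if ("coding" %in% names(spec$methylation_states))
            m_target[in_coding] <- spec$methylation_states[["coding"]]
          if ("igs" %in% names(spec$methylation_states))
            m_target[in_unit & !in_coding] <- spec$methylation_states[["igs"]]
        }
      }
      conc <- 80
      mv <- rbeta(n, pmax(m_target * conc, 1e-3),
                  pmax((1 - m_target) * conc, 1e-3))
      depth[[nm]] <- data.frame(chrom = nm, bin_start = bin_start,
                                value = d, stringsAsFactors = FALSE)
      meth[[nm]] <- data.frame(chrom = nm, bin_start = bin_start,
                               value = mv, stringsAsFactors = FALSE)
    }
    list(depth = do.call(rbind, depth), methylation = do.call(rbind, meth))
  })
}
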