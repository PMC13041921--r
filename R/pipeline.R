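# Configuration, run orchestration and reporting: one command takes a
# synthetic (or user-supplied) genome through periodicity, classification,
# PHR calling and rDNA analysis, writing standard-format artifacts and a
# machine-readable report.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "satarch_out",
    stages = list(simulate = TRUE, periodicity = TRUE, classify = TRUE,
                  phr = TRUE, rdna = TRUE),
    fasta = NULL,                 # required when simulate is disabled
    simulate = list(
      n_centromeres = 2L,
      dimer_units = 150L,
      flank_units = 40L,
      substitution_rate = 0.02,
      monomer_length = 170L,
      inter_family_divergence = 0.2,
      arm_subterminal_units = 120L,
      arm_rdna_units = 6L,
      phr_length = 12000L,
      phr_identity = 0.995,
      mean_depth = 30,
      rdna_total_copies = 100L),
    periodicity = list(k = 21L, max_period = 3000L),
    classify = list(min_margin = 2.0, min_array_monomers = 10L,
                    max_gap = 500L),
    phr = list(window = 5000L, step = 2500L, min_identity = 0.99,
               min_span = 10000L),
    rdna = list(activity_threshold = 0.5, min_cdr_span = 10000L,
                dip_factor = 0.5))
}

check_keys <- function(x, template, path = "") {
  bad <- setdiff(names(x), names(template))
  if (length(bad))
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  for (k in names(x))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      check_keys(x[[k]], template[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (naming them), and fills in
#' the documented defaults for everything unspecified.
#'
#' @param path path to a YAML config file; NULL returns pure defaults.
#' @return object of class \code{pipeline_config} (a named list).
#' @export
load_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    yaml::read_yaml(path) %||% list()
  }
  check_keys(user, defaults)
  cfg <- modifyList(defaults, user)
  for (k in setdiff(names(defaults), names(cfg)))
    cfg[k] <- list(defaults[[k]])        # keep NULL-valued defaults
  cfg <- cfg[names(defaults)]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Save a pipeline configuration as YAML
#' @param config a \code{pipeline_config}.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Build the default synthetic study system: dimeric centromeres with
# inactive flanks plus two acrocentric arms sharing a PHR segment and
# carrying rDNA.
default_synthetic_config <- function(p, seed) {
  lib <- make_monomer_library(4L, p$monomer_length,
                              p$inter_family_divergence, seed = seed,
                              family_names = c("S3", "S4", "S3o", "S4o"))
  model <- rdna_unit_model(seed = seed + 7L)
  donor <- with_seed(seed + 13L, random_dna(p$phr_length))
  chroms <- list()
  for (i in seq_len(p$n_centromeres)) {
    nm <- sprintf("cen%d", i)
    chroms[[nm]] <- list(plan = list(
      list(type = "satellite", library = lib,
           spec = array_spec(c("S3o", "S4o"), p$flank_units,
                             p$substitution_rate), class = "flank_left"),
      list(type = "satellite", library = lib,
           spec = array_spec(c("S3", "S4"), p$dimer_units,
                             p$substitution_rate), class = "active"),
      list(type = "satellite", library = lib,
           spec = array_spec(c("S3o", "S4o"), p$flank_units,
                             p$substitution_rate), class = "flank_right")))
  }
  sublib <- make_monomer_library(1L, 171L, 0.2, seed = seed + 3L,
                                 family_names = "MarmoSAT")
  for (i in 1:2) {
    nm <- sprintf("arm%d", i)
    chroms[[nm]] <- list(plan = list(
      list(type = "satellite", library = sublib,
           spec = array_spec("MarmoSAT", p$arm_subterminal_units,
                             p$substitution_rate)),
      list(type = "spacer", length = 3000L),
      list(type = "rdna", model = model, n_units = p$arm_rdna_units,
           substitution_rate = 0.005),
      list(type = "phr_donor", sequence = donor,
           identity = p$phr_identity, class = "phr"),
      list(type = "spacer", length = 20000L),
      list(type = "satellite", library = lib,
           spec = array_spec(c("S3", "S4"), p$dimer_units %/% 2L,
                             p$substitution_rate), class = "active")))
  }
  list(library = lib, model = model,
       genome_config = list(seed = seed, chromosomes = chroms))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order simulate, periodicity, classify,
#' phr, rdna over a synthetic genome (or a user FASTA), writing FASTA,
#' BED, TSV and Newick artifacts plus a JSON report of per-stage counts,
#' parameters and the seed. Reruns with the same config are
#' reproducible.
#'
#' @param config a \code{pipeline_config} from \code{\link{load_config}}.
#' @param outdir output directory (overrides the config when given).
#' @return the run report (named list), invisibly written to
#'   \code{report.json}.
#' @export
run_pipeline <- function(config = load_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, parameters = unclass(config), stages = list())

  # --- simulate ------------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    sim <- default_synthetic_config(config$simulate, seed)
    genome <- synthesize_genome(sim$genome_config,
                                fasta_path = file.path(outdir, "genome.fa"),
                                bed_path = file.path(outdir, "truth.bed"))
    tracks <- simulate_depth_track(
      genome$sequences, genome$truth,
      track_spec(mean_depth = config$simulate$mean_depth,
                 methylation_states = list(active = 0.8, coding = 0.1,
                                           igs = 0.8)),
      rdna_total_copies = config$simulate$rdna_total_copies,
      seed = seed + 1L)
    write_track(tracks$depth, file.path(outdir, "depth.tsv"))
    write_track(tracks$methylation, file.path(outdir, "methylation.tsv"))
    report$stages$simulate <- list(
      n_chromosomes = length(genome$sequences),
      genome_bp = sum(nchar(genome$sequences)),
      n_truth_records = nrow(genome$truth))
  } else {
    if (is.null(config$fasta) || !file.exists(config$fasta))
      stop("simulate stage disabled and no input FASTA found",
           call. = FALSE)
    genome <- list(sequences = read_fasta(config$fasta), truth = NULL)
    sim <- NULL; tracks <- NULL
  }
  seqs <- genome$sequences

  # --- periodicity ---------------------------------------------------------
  if (isTRUE(config$stages$periodicity)) {
    pp <- config$periodicity
    spectra <- lapply(seqs, function(s)
      ntr_spectrum(s, k = pp$k, max_period = pp$max_period))
    doms <- lapply(names(spectra), function(nm) {
      d <- dominant_period(spectra[[nm]], 3L)
      if (nrow(d)) cbind(sequence_name = nm, d) else NULL
    })
    doms <- do.call(rbind, doms)
    write.table(doms, file.path(outdir, "periods.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$stages$periodicity <- list(
      n_sequences = length(spectra),
      dominant_periods = setNames(
        lapply(names(spectra),
               function(nm) dominant_period(spectra[[nm]], 1L)$period),
        names(spectra)))
  }

  # --- classify ------------------------------------------------------------
  if (isTRUE(config$stages$classify)) {
    if (is.null(sim))
      stop("classify stage requires the simulate stage in this release",
           call. = FALSE)
    cp <- config$classify
    profs <- profiles_from_library(sim$library)
    period <- sim$library$families$monomer_length[1]
    annos <- list()
    for (nm in names(seqs)) {
      tr <- genome$truth[genome$truth$sequence_name == nm, ]
      sat <- tr[tr$feature_class %in% sim$library$families$family, ]
      if (nrow(sat) < 4L) next
      span <- range(c(sat$start, sat$end))
      mono <- segment_monomers(substr(seqs[[nm]], span[1] + 1L, span[2]),
                               period, sequence_name = nm,
                               phase_to = sim$library$families$consensus[1])
      mono$start <- mono$start + span[1]
      mono$end <- mono$end + span[1]
      cls <- classify_monomers(mono, profs, min_margin = cp$min_margin)
      annos[[nm]] <- annotate_satellite_arrays(
        cls, min_array_monomers = cp$min_array_monomers,
        max_gap = cp$max_gap,
        family_groups = c(S3 = "SF1-1", S4 = "SF1-1",
                          S3o = "SF1-5", S4o = "SF1-5"))
    }
    annos <- do.call(rbind, annos)
    if (!is.null(annos) && nrow(annos)) {
      bed <- data.frame(sequence_name = annos$sequence_name,
                        start = annos$start, end = annos$end,
                        feature_class = paste0(annos$family, "_",
                                               annos$layer),
                        strand = "+")
      write_bed(bed, file.path(outdir, "arrays.bed"))
    }
    report$stages$classify <- list(
      n_arrays = if (is.null(annos)) 0L else nrow(annos),
      n_active = if (is.null(annos)) 0L else sum(annos$layer == "active"))
  }

  # --- phr -----------------------------------------------------------------
  if (isTRUE(config$stages$phr)) {
    pf <- config$phr
    arm_names <- grep("^arm", names(seqs), value = TRUE)
    if (length(arm_names) >= 2L) {
      segs <- windowed_identity(seqs[[arm_names[1]]], seqs[[arm_names[2]]],
                                window = pf$window, step = pf$step,
                                name_a = arm_names[1],
                                name_b = arm_names[2])
      phrs <- call_phrs(segs, min_identity = pf$min_identity,
                        min_span = pf$min_span)
      net <- phr_network(phrs, acrocentric_names = arm_names)
      write_bedpe(phrs, file.path(outdir, "phrs.bedpe"))
      write_phr_network(net, file.path(outdir, "phr_network.tsv"))
      report$stages$phr <- list(n_segments = nrow(segs),
                                n_phrs = nrow(phrs),
                                n_edges = nrow(net$edges))
    } else report$stages$phr <- list(n_segments = 0L, n_phrs = 0L,
                                     n_edges = 0L)
  }

  # --- rdna ----------------------------------------------------------------
  if (isTRUE(config$stages$rdna) && !is.null(sim)) {
    rp <- config$rdna
    units <- list()
    for (nm in grep("^arm", names(seqs), value = TRUE)) {
      u <- find_rdna_units(seqs[[nm]], sim$model, sequence_name = nm)
      if (nrow(u)) units[[nm]] <- u
    }
    units_df <- do.call(rbind, units)
    n_units <- if (is.null(units_df)) 0L else nrow(units_df)
    copies <- NA_real_
    if (n_units > 0L && !is.null(tracks)) {
      u1 <- units_df[1, ]
      rdna_region <- list(chrom = u1$sequence_name,
                          start = min(units_df$start[
                            units_df$sequence_name == u1$sequence_name]),
                          end = max(units_df$end[
                            units_df$sequence_name == u1$sequence_name]))
      tr <- genome$truth
      spacer <- tr[tr$feature_class == "spacer" &
                     tr$sequence_name == u1$sequence_name &
                     tr$end - tr$start >= 10000L, ][1, ]
      sc_region <- list(chrom = spacer$sequence_name,
                        start = spacer$start, end = spacer$end)
      copies <- estimate_total_copies(tracks$depth, rdna_region, sc_region)
      act <- classify_activity(tracks$methylation, units_df,
                               threshold = rp$activity_threshold)
      write.table(act, file.path(outdir, "rdna_activity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ub <- data.frame(sequence_name = units_df$sequence_name,
                       start = units_df$start, end = units_df$end,
                       feature_class = ifelse(units_df$intact, "rdna_unit",
                                              "rdna_unit_degraded"),
                       strand = units_df$orientation)
      write_bed(ub, file.path(outdir, "rdna_units.bed"))
    }
    report$stages$rdna <- list(n_units = n_units,
                               estimated_total_copies = copies)
  }

  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  report
}
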