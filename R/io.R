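# Standard-format I/O shared by all stages. Coordinates are 0-based
# half-open (BED convention) everywhere in the package.

#' Construct a ground-truth annotation table
#'
#' A truth table records every planted feature of a synthetic sequence:
#' one row per feature, 0-based half-open coordinates, sorted by
#' (sequence_name, start). Extra columns (e.g. \code{family},
#' \code{intact}) are carried through untouched.
#'
#' @param df data.frame with at least \code{sequence_name}, \code{start},
#'   \code{end}, \code{feature_class}, \code{strand}.
#' @return the validated, sorted data.frame with class
#'   \code{"synthetic_truth"}.
#' @export
as_truth <- function(df) {
  need <- c("sequence_name", "start", "end", "feature_class", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("truth table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) && any(df$start < 0 | df$end <= df$start))
    stop("truth table has invalid coordinates (need 0 <= start < end)",
         call. = FALSE)
  df <- df[order(df$sequence_name, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("synthetic_truth", "data.frame")
  df
}

#' Read a FASTA file as a named character vector
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (60-column wrapped)
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named", call. = FALSE)
  x <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Write a truth/annotation table as BED9
#'
#' name carries the feature class, score is 0, thickStart/thickEnd mirror
#' the interval, itemRgb is unused ("0").
#' @param truth a truth or annotation data.frame.
#' @param path output path.
#' @export
write_bed <- function(truth, path) {
  df <- as.data.frame(truth)
  name <- df$feature_class %||% df$family
  bed <- data.frame(df$sequence_name, df$start, df$end, name, 0L,
                    df$strand %||% "+", df$start, df$end, "0")
  bed <- bed[order(bed[[1]], bed[[2]]), ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by this package
#' @param path path to a BED file (>= 6 columns used).
#' @return a \code{synthetic_truth} data.frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  df <- data.frame(sequence_name = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   feature_class = as.character(raw[[4]]),
                   strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else "+",
                   stringsAsFactors = FALSE)
  as_truth(df)
}

#' Write a binned genomic track (chrom, bin_start, value)
#' @param track data.frame with columns chrom, bin_start, value.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  write.table(track[, c("chrom", "bin_start", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned genomic track
#' @param path path to a 3-column TSV (chrom, bin_start, value).
#' @return data.frame with columns chrom, bin_start, value.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("track not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "bin_start", "value"),
                   stringsAsFactors = FALSE)
  df
}

#' Write PHR segments as BEDPE
#' @param phrs data.frame of PHR segments.
#' @param path output path.
#' @export
write_bedpe <- function(phrs, path) {
  df <- as.data.frame(phrs)
  if (!nrow(df)) { file.create(path); return(invisible(path)) }
  out <- data.frame(df$seq_a, df$start_a, df$end_a,
                    df$seq_b, df$start_b, df$end_b,
                    sprintf("PHR_%d", seq_len(nrow(df))),
                    round(df$identity * 1000), "+", df$orientation)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
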