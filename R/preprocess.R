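#' Bin centre positions into fixed-width windows
#'
#' Counts inferred nucleosome centres in consecutive `bin_size` bp bins
#' anchored at coordinate 0: bin i covers `[i*bin_size, (i+1)*bin_size)`.
#' The 30 bp default matches the ~30 bp positional uncertainty of
#' MNase-Seq read centres.
#'
#' @param positions Sorted (or unsorted) integer vector of centre
#'   coordinates on one chromosome, all in `[0, chrom_length)`.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 30).
#' @return Integer vector of counts of length `ceiling(chrom_length / bin_size)`.
#' @export
bin_counts <- function(positions, chrom_length, bin_size = 30L) {
  stopifnot(bin_size >= 1)
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  if (length(positions) == 0L) return(integer(n_bins))
  if (any(positions < 0L) || any(positions >= chrom_length)) {
    stop("centre position outside [0, chrom_length)")
  }
  tabulate(positions %/% as.integer(bin_size) + 1L, nbins = n_bins)
}

#' Bin per-chromosome centres into tracks
#'
#' @param centers A `data.table` with columns `chrom`, `pos`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return Named list of integer count vectors, one per chromosome in
#'   `chrom_sizes` (all-zero for chromosomes without reads), with the bin
#'   size attached as attribute `bin_size`.
#' @export
bin_tracks <- function(centers, chrom_sizes, bin_size = 30L) {
  by_chrom <- split_centers(centers)
  tracks <- lapply(names(chrom_sizes), function(ch) {
    bin_counts(by_chrom[[ch]] %||% integer(), chrom_sizes[[ch]], bin_size)
  })
  names(tracks) <- names(chrom_sizes)
  attr(tracks, "bin_size") <- as.integer(bin_size)
  tracks
}

#' Subtract the control track from the signal track
#'
#' Corrects MNase sequence bias (and other shared experimental artifacts)
#' by subtracting, bin by bin, the control count from the signal count and
#' truncating negative differences to 0: a deficit relative to naked DNA
#' carries no information beyond "not enriched".
#'
#' @param signal Integer count vector (one chromosome).
#' @param control Integer count vector of the same length and bin size.
#' @param control_scale Multiplier applied to the control before
#'   subtraction (default 1: raw counts are subtracted). A value other
#'   than 1 compensates for unequal library depths.
#' @return Non-negative corrected count vector (integer when
#'   `control_scale` is 1).
#' @export
subtract_control <- function(signal, control, control_scale = 1) {
  if (length(signal) != length(control)) {
    stop("signal and control tracks differ in length (",
         length(signal), " vs ", length(control), " bins)")
  }
  corrected <- pmax(signal - control_scale * control, 0)
  if (control_scale == 1) corrected <- as.integer(round(corrected))
  corrected
}

#' Subtract control from signal across all chromosomes
#'
#' @param signal_tracks,control_tracks Named lists of count vectors as
#'   returned by [bin_tracks()]; must cover the same chromosomes.
#' @param control_scale See [subtract_control()].
#' @return Named list of corrected tracks.
#' @export
correct_tracks <- function(signal_tracks, control_tracks, control_scale = 1) {
  if (!setequal(names(signal_tracks), names(control_tracks))) {
    stop("signal and control tracks cover different chromosomes")
  }
  out <- lapply(names(signal_tracks), function(ch) {
    subtract_control(signal_tracks[[ch]], control_tracks[[ch]], control_scale)
  })
  names(out) <- names(signal_tracks)
  attr(out, "bin_size") <- attr(signal_tracks, "bin_size")
  out
}

#' Write a count track as bedGraph
#'
#' Emits one `chrom start end count` line per non-zero bin, for
#' inspection in a genome browser.
#'
#' @param tracks Named list of count vectors with a `bin_size` attribute.
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  bs <- attr(tracks, "bin_size")
  rows <- lapply(names(tracks), function(ch) {
    counts <- tracks[[ch]]
    i <- which(counts != 0)
    if (!length(i)) return(NULL)
    data.table::data.table(chrom = ch, start = (i - 1L) * bs,
                           end = i * bs, count = counts[i])
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
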