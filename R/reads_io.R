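#' Read a chromosome-sizes table
#'
#' Parses a two-column, tab-separated table in the UCSC `chrom.sizes`
#' dialect (chromosome name, length in bp).
#'
#' @param path Path to the sizes file (may be gzipped).
#' @return A named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom.sizes file must have two columns: ", path)
  if (any(!is.finite(dt$length)) || any(dt$length <= 0)) {
    stop("chromosome lengths must be positive integers")
  }
  stats::setNames(as.integer(dt$length), dt$chrom)
}

#' Read mapped reads from BED6 or minimal TSV
#'
#' Reads single-end mapped reads and reduces each record to the triple
#' (chromosome, 5'-end coordinate, strand). For BED6 input the 5' end of a
#' `+` read is `start` and of a `-` read is `end - 1` (BED intervals are
#' 0-based, half-open). The TSV dialect carries the 5' coordinate directly
#' in its three columns `chrom`, `five_prime`, `strand`.
#'
#' Reads on chromosomes absent from `chrom_sizes` (when supplied) are
#' dropped with a message stating how many were removed.
#'
#' @param path Input file, plain or gzipped.
#' @param format `"auto"` (sniff by column count), `"bed6"` or `"tsv"`.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   drop reads on unknown chromosomes.
#' @return A `data.table` with columns `chrom`, `five_prime`, `strand`.
#' @export
read_mapped_reads <- function(path, format = c("auto", "bed6", "tsv"),
                              chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  empty_input <- file.size(path) == 0L
  dt <- if (empty_input) data.table::data.table() else {
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1))
  }
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), five_prime = integer(),
                                  strand = character()))
  }
  if (format == "auto") format <- if (ncol(dt) >= 6L) "bed6" else "tsv"
  if (format == "bed6") {
    if (ncol(dt) < 6L) stop("BED6 input requires 6 columns: ", path)
    start <- suppressWarnings(as.integer(dt[[2L]]))
    end <- suppressWarnings(as.integer(dt[[3L]]))
    strand <- as.character(dt[[6L]])
    bad <- which(is.na(start) | is.na(end) | end <= start)
    if (length(bad)) stop("malformed BED line ", bad[1L], " in ", path)
    reads <- data.table::data.table(
      chrom = as.character(dt[[1L]]),
      five_prime = data.table::fifelse(strand == "-", end - 1L, start),
      strand = strand)
  } else {
    if (ncol(dt) < 3L) stop("TSV input requires 3 columns: ", path)
    five_prime <- suppressWarnings(as.integer(dt[[2L]]))
    bad <- which(is.na(five_prime))
    if (length(bad)) stop("malformed TSV line ", bad[1L], " in ", path)
    reads <- data.table::data.table(
      chrom = as.character(dt[[1L]]),
      five_prime = five_prime,
      strand = as.character(dt[[3L]]))
  }
  bad_strand <- which(!reads$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("unknown strand symbol '", reads$strand[bad_strand[1L]],
         "' on line ", bad_strand[1L], " of ", path)
  }
  if (any(reads$five_prime < 0L)) stop("negative 5' coordinate in ", path)
  if (!is.null(chrom_sizes)) {
    known <- reads$chrom %in% names(chrom_sizes)
    if (!all(known)) {
      message(sum(!known), " reads on chromosomes absent from the sizes table dropped")
      reads <- reads[known]
    }
  }
  reads[]
}

#' Infer nucleosome-centre positions from read 5' ends
#'
#' A single-end MNase-Seq read starts at one border of the ~150 bp
#' nucleosomal fragment, so the dyad is recovered by shifting the 5' end
#' half a fragment inwards: `five_prime + shift` on the `+` strand and
#' `five_prime - shift` on the `-` strand (mirror rule). Centres falling
#' outside `[0, chrom_length)` are discarded and counted in a message.
#'
#' @param reads A `data.table` as returned by [read_mapped_reads()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param shift Half-fragment shift in bp (default 75).
#' @return A `data.table` with columns `chrom`, `pos` (sorted within
#'   chromosome), one row per inferred centre.
#' @export
compute_centers <- function(reads, chrom_sizes, shift = 75L) {
  stopifnot(shift > 0)
  shift <- as.integer(shift)
  chrom <- pos <- NULL
  centers <- data.table::data.table(
    chrom = reads$chrom,
    pos = data.table::fifelse(reads$strand == "+",
                              reads$five_prime + shift,
                              reads$five_prime - shift))
  len <- unname(chrom_sizes[centers$chrom])
  keep <- !is.na(len) & centers$pos >= 0L & centers$pos < len
  if (any(!keep)) {
    message(sum(!keep), " inferred centres outside chromosome bounds discarded")
  }
  centers <- centers[keep]
  data.table::setorder(centers, chrom, pos)
  centers[]
}

#' Remove positions covered by an excessive number of reads
#'
#' Single positions carrying an implausible pile-up of identical read
#' centres are amplification or sequencing artifacts. Every centre at a
#' coordinate whose multiplicity exceeds the cap is removed (the whole
#' position, not a trim down to the cap). Genuine positioned-nucleosome
#' enrichment survives because it is spread over a ~30 bp window, not
#' stacked on one coordinate.
#'
#' @param centers A `data.table` with columns `chrom`, `pos`.
#' @param max_per_position Cap on centre multiplicity at one coordinate
#'   (default 5). Ignored when `quantile` is given.
#' @param quantile Optional alternative policy: drop positions whose
#'   multiplicity lies above this quantile of the per-position
#'   multiplicity distribution (e.g. 0.9999).
#' @return Filtered centres, same shape; the number of removed positions
#'   is reported in a message.
#' @export
filter_excessive_positions <- function(centers, max_per_position = 5L,
                                       quantile = NULL) {
  if (nrow(centers) == 0L) return(centers)
  chrom <- pos <- N <- NULL
  mult <- centers[, .N, by = .(chrom, pos)]
  cap <- if (!is.null(quantile)) {
    stopifnot(quantile > 0, quantile <= 1)
    as.numeric(stats::quantile(mult$N, quantile, names = FALSE))
  } else {
    stopifnot(max_per_position >= 1)
    as.numeric(max_per_position)
  }
  drop <- mult[N > cap]
  if (nrow(drop)) {
    message(nrow(drop), " positions with > ", format(cap),
            " reads removed (", sum(drop$N), " reads)")
    centers <- centers[!drop, on = c("chrom", "pos")]
  }
  centers[]
}

#' Split centres into per-chromosome sorted position vectors
#'
#' @param centers A `data.table` with columns `chrom`, `pos`.
#' @return Named list of sorted integer vectors, one per chromosome.
#' @keywords internal
split_centers <- function(centers) {
  lapply(split(centers$pos, centers$chrom), sort)
}
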