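# Sliding-window caller. The five-bin window advances one 30 bp bin at
# a time; every window where the positioned-nucleosome model wins
# strictly becomes a call scored by its log Bayes factor against the
# all-background model.

#' Scan one chromosome for well-positioned nucleosomes
#'
#' Evaluates the eight-model comparison in every window of 5 consecutive
#' bins. Windows whose five bins are all zero are skipped without model
#' evaluation: with no reads the all-background model wins trivially, so
#' the fast path cannot change the call set. The whole scan is
#' vectorized over windows; the uniform-prior marginal is served from a
#' per-chromosome lookup table.
#'
#' @param counts Corrected bin counts of one chromosome.
#' @param hyper List with `alpha`, `beta` (from
#'   [estimate_gamma_hyperparams()]).
#' @param lambda_max Uniform-prior upper bound; conventionally
#'   `max(counts)` of this chromosome.
#' @param chrom Chromosome name stamped on the calls.
#' @param bin_size Bin width in bp (default 30).
#' @param step_bins Window stride in bins (default 1).
#' @param offset Shift (bp) added to all reported coordinates; used by
#'   the optional bin-offset sweep.
#' @param skip_zero Disable to force model evaluation of all-zero
#'   windows (used to verify the fast path is exact).
#' @return A `data.table` of unresolved calls: `chrom`, `start`, `end`
#'   (150 bp window), `center_start`, `center_end` (central bin),
#'   `log_bayes_factor`, `winner_margin`.
#' @export
scan_chromosome <- function(counts, hyper, lambda_max, chrom = "chr",
                            bin_size = 30L, step_bins = 1L, offset = 0L,
                            skip_zero = TRUE) {
  B <- length(counts)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    center_start = integer(), center_end = integer(),
    log_bayes_factor = numeric(), winner_margin = numeric())
  if (B < 5L) return(empty)
  i0 <- seq.int(0L, B - 5L, by = step_bins)  # 0-based first bin of window
  y1 <- counts[i0 + 1L]; y2 <- counts[i0 + 2L]; y3 <- counts[i0 + 3L]
  y4 <- counts[i0 + 4L]; y5 <- counts[i0 + 5L]
  if (skip_zero) {
    live <- (y1 + y2 + y3 + y4 + y5) > 0L
    i0 <- i0[live]
    if (!length(i0)) return(empty)
    y1 <- y1[live]; y2 <- y2[live]; y3 <- y3[live]
    y4 <- y4[live]; y5 <- y5[live]
  }

  utab <- precompute_uniform_table(lambda_max,
                                   max_total = max(y1 + y2, y3, y4 + y5))
  lf1 <- lfactorial(y1) + lfactorial(y2)
  lf2 <- lfactorial(y3)
  lf3 <- lfactorial(y4) + lfactorial(y5)
  s1 <- y1 + y2; s2 <- y3; s3 <- y4 + y5
  a <- hyper$alpha; b <- hyper$beta
  bg1 <- -lf1 + lm_gamma_suff(s1, 2L, a, b)
  bg2 <- -lf2 + lm_gamma_suff(s2, 1L, a, b)
  bg3 <- -lf3 + lm_gamma_suff(s3, 2L, a, b)
  en1 <- -lf1 + uniform_table_lookup(utab, s1, 2L)
  en2 <- -lf2 + uniform_table_lookup(utab, s2, 1L)
  en3 <- -lf3 + uniform_table_lookup(utab, s3, 2L)

  m0 <- bg1 + bg2 + bg3; m1 <- bg1 + en2 + bg3
  m2 <- en1 + en2 + en3; m3 <- en1 + bg2 + en3
  m4 <- en1 + en2 + bg3; m5 <- bg1 + en2 + en3
  m6 <- en1 + bg2 + bg3; m7 <- bg1 + bg2 + en3
  best_other <- pmax(m0, m2, m3, m4, m5, m6, m7)
  hit <- m1 > best_other
  if (!any(hit)) return(empty)
  i0 <- i0[hit]
  start <- i0 * bin_size + as.integer(offset)
  data.table::data.table(
    chrom = chrom,
    start = start,
    end = start + 5L * bin_size,
    center_start = start + 2L * bin_size,
    center_end = start + 3L * bin_size,
    log_bayes_factor = (m1 - m0)[hit],
    winner_margin = (m1 - best_other)[hit])
}

#' Resolve overlapping calls
#'
#' Adjacent accepted windows can claim overlapping central bins (only
#' possible with the bin-offset sweep or sub-bin strides). Calls are
#' kept greedily in descending log Bayes factor, a call surviving iff
#' its central 30 bp bin does not overlap the central bin of any
#' already-kept call; ties break deterministically by leftmost start.
#'
#' @param calls A `data.table` of calls (one or more chromosomes).
#' @return The resolved calls, sorted by chromosome and start.
#' @export
resolve_overlaps <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  chrom <- NULL
  out <- lapply(split(calls, calls$chrom), function(cc) {
    ord <- order(-cc$log_bayes_factor, cc$start)
    cs <- cc$center_start[ord]; ce <- cc$center_end[ord]
    # greedy by score; a coordinate bitmap over the occupied span makes
    # each overlap query O(bin width) instead of O(kept calls)
    base <- min(cs)
    blocked <- logical(max(ce) - base)
    keep <- logical(length(ord))
    for (k in seq_along(ord)) {
      span <- (cs[k] - base + 1L):(ce[k] - base)
      if (!any(blocked[span])) {
        keep[k] <- TRUE
        blocked[span] <- TRUE
      }
    }
    cc[sort(ord[keep])]
  })
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start)
  res[]
}

#' Run the full calling pipeline
#'
#' Reads to centres to binned tracks to control-corrected tracks to
#' per-chromosome model scan to resolved calls. Hyperparameters and the
#' uniform-prior bound are estimated per chromosome from the corrected
#' track; chromosomes whose corrected track is all zero are skipped.
#'
#' @param signal_reads,control_reads Read tables from
#'   [read_mapped_reads()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 30).
#' @param shift Centre shift in bp (default 75).
#' @param cap Per-position read cap for artifact removal
#'   ([filter_excessive_positions()]); `NULL` disables the filter.
#' @param control_scale Control depth multiplier (default 1).
#' @param offset_sweep Also scan the 4 shifted phases of the bin grid
#'   and resolve the union (default off).
#' @param verbose Print per-chromosome fit and call summaries.
#' @return A list of class `nf_callset`: `calls` (resolved
#'   `data.table`), `params` (per-chromosome `alpha`, `beta`,
#'   `lambda_max`, window and call counts), `config`.
#' @export
call_nucleosomes <- function(signal_reads, control_reads, chrom_sizes,
                             bin_size = 30L, shift = 75L, cap = 5L,
                             control_scale = 1, offset_sweep = FALSE,
                             verbose = FALSE) {
  sig_centers <- compute_centers(signal_reads, chrom_sizes, shift)
  ctl_centers <- compute_centers(control_reads, chrom_sizes, shift)
  if (!is.null(cap)) {
    sig_centers <- filter_excessive_positions(sig_centers, cap)
    ctl_centers <- filter_excessive_positions(ctl_centers, cap)
  }
  offsets <- if (offset_sweep) {
    as.integer(round(seq(0, bin_size - 1, length.out = 5)))
  } else 0L
  all_calls <- list()
  params <- list()
  for (ch in names(chrom_sizes)) {
    sig_pos <- sig_centers$pos[sig_centers$chrom == ch]
    ctl_pos <- ctl_centers$pos[ctl_centers$chrom == ch]
    corrected0 <- NULL
    for (off in offsets) {
      # shifting the grid by `off` = binning positions - off on the 0 grid
      sp <- sig_pos - off; cp <- ctl_pos - off
      len <- chrom_sizes[[ch]] - off
      corrected <- subtract_control(
        bin_counts(sp[sp >= 0], len, bin_size),
        bin_counts(cp[cp >= 0], len, bin_size),
        control_scale)
      if (off == 0L) corrected0 <- corrected
      lambda_max <- max(corrected)
      if (lambda_max == 0) next
      hyper <- tryCatch(estimate_gamma_hyperparams(corrected),
                        warning = function(w) {
                          suppressWarnings(estimate_gamma_hyperparams(corrected))
                        })
      all_calls[[length(all_calls) + 1L]] <-
        scan_chromosome(corrected, hyper, lambda_max, chrom = ch,
                        bin_size = bin_size, offset = off)
      if (off == 0L) {
        params[[ch]] <- list(alpha = hyper$alpha, beta = hyper$beta,
                             lambda_max = lambda_max,
                             n_bins = length(corrected))
      }
    }
    if (is.null(params[[ch]]) && !is.null(corrected0)) {
      params[[ch]] <- list(alpha = NA_real_, beta = NA_real_,
                           lambda_max = 0, n_bins = length(corrected0))
    }
    if (verbose && !is.null(params[[ch]])) {
      p <- params[[ch]]
      message(sprintf("%s: alpha=%.3f beta=%.3f lambda_max=%g bins=%d",
                      ch, p$alpha, p$beta, p$lambda_max, p$n_bins))
    }
  }
  calls <- resolve_overlaps(data.table::rbindlist(all_calls))
  if (verbose) message(nrow(calls), " nucleosomes called")
  structure(list(calls = calls, params = params,
                 config = list(bin_size = as.integer(bin_size),
                               shift = as.integer(shift),
                               cap = cap, control_scale = control_scale,
                               offset_sweep = offset_sweep)),
            class = "nf_callset")
}

#' @export
print.nf_callset <- function(x, ...) {
  cat("nucleofinder call set:", nrow(x$calls), "calls on",
      length(x$params), "chromosome(s)\n")
  invisible(x)
}

#' Write calls as BED6
#'
#' One line per call covering the central 30 bp bin, name `nucN`, score
#' the log Bayes factor rounded to 3 decimals, strand `.`. The full
#' 150 bp window is the centre bin extended by 60 bp on each side.
#' Output ordering (chromosome, start) is deterministic.
#'
#' @param calls A calls `data.table` or an `nf_callset`.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  if (inherits(calls, "nf_callset")) calls <- calls$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nucleofinder calls: chrom, center_start, center_end, name, log_bayes_factor, strand", con)
  if (nrow(calls)) {
    chrom <- NULL
    calls <- data.table::copy(calls)
    data.table::setorder(calls, chrom, start)
    writeLines(sprintf("%s\t%d\t%d\tnuc%d\t%.3f\t.",
                       calls$chrom, calls$center_start, calls$center_end,
                       seq_len(nrow(calls)), calls$log_bayes_factor), con)
  }
  invisible(path)
}

#' Read back a calls BED file
#'
#' @param path A file written by [write_calls()].
#' @param flank Half-width (bp) by which the central bin is extended to
#'   recover the full window (default 60).
#' @return A calls `data.table` (without `winner_margin`).
#' @export
read_calls <- function(path, flank = 60L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      center_start = integer(), center_end = integer(),
      log_bayes_factor = numeric()))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  data.table::data.table(
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]) - as.integer(flank),
    end = as.integer(dt[[3L]]) + as.integer(flank),
    center_start = as.integer(dt[[2L]]),
    center_end = as.integer(dt[[3L]]),
    log_bayes_factor = as.numeric(dt[[5L]]))
}

#' Dump per-chromosome model parameters as JSON
#'
#' @param callset An `nf_callset`.
#' @param path Output JSON path.
#' @export
write_params_json <- function(callset, path) {
  jsonlite::write_json(callset$params, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
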