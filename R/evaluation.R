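# The three assessment procedures: specificity under within-window read
# permutation, inter-nucleosome spacing downstream of active TSSs, and
# the AA/TT vs GC dinucleotide signature at call centres.

#' Permute read centres within fixed windows
#'
#' Destroys local positioning while conserving coverage: within each
#' consecutive `window` bp block of a chromosome, every centre is
#' reassigned an independent uniform position inside the block. Counts
#' per block (and hence per chromosome) are conserved exactly. Calls
#' surviving this permutation are, by construction, false positives.
#'
#' @param centers A `data.table` with columns `chrom`, `pos`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Block width in bp (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Permuted centres, same shape, sorted.
#' @export
permute_reads <- function(centers, chrom_sizes, window = 1000L, seed = NULL) {
  stopifnot(window >= 1)
  if (!is.null(seed)) set.seed(seed)
  window <- as.integer(window)
  len <- unname(chrom_sizes[centers$chrom])
  if (any(is.na(len))) stop("centres on chromosomes absent from chrom_sizes")
  block_start <- (centers$pos %/% window) * window
  block_len <- pmin(window, len - block_start)
  chrom <- pos <- NULL
  out <- data.table::data.table(
    chrom = centers$chrom,
    pos = block_start +
      as.integer(floor(stats::runif(nrow(centers)) * block_len)))
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Permutation specificity assessment
#'
#' Runs the caller on the data as given and again after permuting the
#' signal read centres within `window` bp blocks (the control is left
#' untouched), and summarizes the two call counts as a specificity:
#' post-permutation calls are false positives, uncalled candidate
#' regions true negatives. A method specific to well-positioned
#' nucleosomes calls many regions before permutation and few after.
#'
#' @param signal_reads,control_reads Read tables from
#'   [read_mapped_reads()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Permutation block width in bp (default 1000).
#' @param seed Seed for the permutation.
#' @param ... Passed to [call_nucleosomes()].
#' @return A [compute_specificity()] report plus `calls_before_set`,
#'   `calls_after_set` (the two call tables).
#' @export
permutation_specificity <- function(signal_reads, control_reads, chrom_sizes,
                                    window = 1000L, seed = NULL, ...) {
  before <- call_nucleosomes(signal_reads, control_reads, chrom_sizes, ...)
  cfg <- before$config
  sig_centers <- compute_centers(signal_reads, chrom_sizes, cfg$shift)
  ctl_centers <- compute_centers(control_reads, chrom_sizes, cfg$shift)
  if (!is.null(cfg$cap)) {
    sig_centers <- filter_excessive_positions(sig_centers, cfg$cap)
    ctl_centers <- filter_excessive_positions(ctl_centers, cfg$cap)
  }
  perm <- permute_reads(sig_centers, chrom_sizes, window, seed)
  corrected <- correct_tracks(
    bin_tracks(perm, chrom_sizes, cfg$bin_size),
    bin_tracks(ctl_centers, chrom_sizes, cfg$bin_size),
    cfg$control_scale)
  after <- list()
  for (ch in names(chrom_sizes)) {
    track <- corrected[[ch]]
    if (max(track) == 0) next
    hyper <- suppressWarnings(estimate_gamma_hyperparams(track))
    after[[ch]] <- scan_chromosome(track, hyper, max(track), chrom = ch,
                                   bin_size = cfg$bin_size)
  }
  after <- resolve_overlaps(data.table::rbindlist(after))
  candidates <- sum(floor(chrom_sizes / cfg$bin_size))
  rep <- compute_specificity(nrow(after), candidates,
                             calls_before = nrow(before$calls))
  rep$calls_before_set <- before$calls
  rep$calls_after_set <- after
  rep
}

#' Specificity from post-permutation calls
#'
#' With no genuine positioning left after permutation, every surviving
#' call is a false positive and every uncalled candidate region a true
#' negative; specificity is `TN / (TN + FP)`. The candidate universe is
#' taken at resolved-call granularity: one disjoint 30 bp central bin
#' per candidate, i.e. `chromosome length / 30` regions.
#'
#' @param calls_after_perm Number of calls on the permuted data (FP).
#' @param total_candidate_regions Number of candidate regions.
#' @param calls_before Optional pre-permutation call count, carried
#'   through for reporting.
#' @return List with `calls_before`, `calls_after`, `candidate_regions`,
#'   `true_negatives`, `specificity`.
#' @export
compute_specificity <- function(calls_after_perm, total_candidate_regions,
                                calls_before = NA_integer_) {
  if (total_candidate_regions <= 0) stop("no candidate regions")
  if (calls_after_perm > total_candidate_regions) {
    stop("more false positives than candidate regions")
  }
  tn <- total_candidate_regions - calls_after_perm
  list(calls_before = calls_before,
       calls_after = calls_after_perm,
       candidate_regions = total_candidate_regions,
       true_negatives = tn,
       specificity = tn / (tn + calls_after_perm))
}

#' Average read-count profile around call centres
#'
#' Averages, positionally across calls, the centre counts in `profile_bin`
#' bp bins over the 150 bp window extended by `flank` bp on each side.
#' A well-positioned call set yields a bell-shaped profile peaking in the
#' central 30 bp. Calls whose extended window leaves the chromosome are
#' dropped with a message.
#'
#' @param calls A calls `data.table` or `nf_callset`.
#' @param centers Read centres (`chrom`, `pos`), typically unfiltered
#'   signal centres.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param flank Extension on each side in bp (default 60).
#' @param profile_bin Profile bin width in bp (default 10).
#' @return Numeric vector of mean counts per bin, length
#'   `(150 + 2 * flank) / profile_bin`.
#' @export
average_profile <- function(calls, centers, chrom_sizes, flank = 60L,
                            profile_bin = 10L) {
  if (inherits(calls, "nf_callset")) calls <- calls$calls
  if (nrow(calls) == 0L) stop("no calls to profile")
  span <- 150L + 2L * as.integer(flank)
  n_bins <- span %/% as.integer(profile_bin)
  by_chrom <- split_centers(centers)
  total <- numeric(n_bins)
  used <- 0L
  dropped <- 0L
  for (ch in unique(calls$chrom)) {
    pos <- by_chrom[[ch]] %||% integer()
    cc <- calls[calls$chrom == ch]
    win_start <- cc$center_start + 15L - span %/% 2L
    ok <- win_start >= 0L & win_start + span <= chrom_sizes[[ch]]
    dropped <- dropped + sum(!ok)
    for (ws in win_start[ok]) {
      lo <- findInterval(ws - 1L, pos)       # centres <= ws - 1
      hi <- findInterval(ws + span - 1L, pos)
      if (hi > lo) {
        rel <- (pos[(lo + 1L):hi] - ws) %/% profile_bin + 1L
        total <- total + tabulate(rel, nbins = n_bins)
      }
      used <- used + 1L
    }
  }
  if (dropped > 0L) message(dropped, " calls truncated at chromosome edges dropped")
  if (used == 0L) stop("all calls dropped at chromosome edges")
  total / used
}

#' Estimate inter-nucleosome spacing downstream of active TSSs
#'
#' For each gene passing the expression filter, call centres within
#' `window` bp downstream of the TSS (strand-oriented distances) are
#' given integer nucleosome indices that need not be consecutive, so
#' missing calls do not corrupt the estimate: for each candidate spacing
#' d on a grid, indices `k_i = floor(c_i/d + 0.5)` are assigned
#' (candidates producing duplicate indices are invalid), an ordinary
#' least-squares line of centre on index is fitted, and the d minimizing
#' the residual sum of squares is kept; the refitted slope is the gene's
#' spacing. Ties on the RSS break to the candidate d closest to its own
#' fitted slope (self-consistent numbering), then to the smaller d.
#' The report is the mean and SD of the per-gene slopes.
#'
#' @param calls A calls `data.table` or `nf_callset`.
#' @param tss A `data.frame` with columns `chrom`, `pos` (TSS,
#'   0-based), `strand`, `rpkm`.
#' @param rpkm_min Expression filter: keep genes with RPKM strictly
#'   above this (default 10).
#' @param window Downstream window in bp (default 1000).
#' @param d_grid Candidate spacings in bp (default `120:250`, covering
#'   the plausible nucleosome repeat lengths).
#' @return List with `mean_spacing`, `sd_spacing`, `n_genes` (genes
#'   contributing an estimate), `n_skipped` (passing genes with < 2
#'   calls in the window), `spacings` (per-gene vector).
#' @export
estimate_spacing <- function(calls, tss, rpkm_min = 10, window = 1000L,
                             d_grid = 120:250) {
  if (inherits(calls, "nf_callset")) calls <- calls$calls
  tss <- as.data.frame(tss)
  tss <- tss[tss$rpkm > rpkm_min, , drop = FALSE]
  if (nrow(tss) == 0L) stop("no genes pass the expression filter")
  centers_mid <- calls$center_start + 15L
  by_chrom <- split(centers_mid, calls$chrom)
  spacings <- numeric(0)
  n_skipped <- 0L
  for (g in seq_len(nrow(tss))) {
    pos <- by_chrom[[tss$chrom[g]]]
    if (is.null(pos)) { n_skipped <- n_skipped + 1L; next }
    d0 <- if (tss$strand[g] == "-") tss$pos[g] - pos else pos - tss$pos[g]
    d0 <- sort(d0[d0 > 0 & d0 <= window])
    if (length(d0) < 2L) { n_skipped <- n_skipped + 1L; next }
    fit <- fit_spacing(d0, d_grid)
    if (!is.null(fit)) spacings <- c(spacings, fit$slope)
  }
  if (!length(spacings)) stop("no gene yielded a spacing estimate")
  list(mean_spacing = mean(spacings),
       sd_spacing = stats::sd(spacings),
       n_genes = length(spacings),
       n_skipped = n_skipped,
       spacings = spacings)
}

# Grid search over candidate spacings with non-consecutive integer
# numbering; returns the best candidate's refitted slope.
#
# Indices are anchored at the first observed call, k_i =
# round((c_i - c_1)/d): anchoring removes the array phase from the
# rounding, which would otherwise sit exactly at a rounding boundary
# for TSS-centred arrays and flip indices under positional jitter.
# Candidate spacings whose numbering duplicates an index are invalid.
# The candidate minimizing the OLS residual sum of squares wins; ties
# (always exact for two-call genes, where every valid numbering fits
# perfectly) are broken among self-consistent candidates (fitted slope
# within one grid step of the candidate spacing) by parsimony - the
# numbering postulating the fewest unobserved nucleosomes, i.e. the
# smallest index span - and finally by slope/spacing agreement.
fit_spacing <- function(centers, d_grid) {
  cands <- list()
  for (d in d_grid) {
    k <- floor((centers - centers[1L]) / d + 0.5)
    if (anyDuplicated(k)) next
    # OLS slope/RSS of centers ~ k in closed form
    kb <- mean(k); cb <- mean(centers)
    sxx <- sum((k - kb)^2)
    if (sxx == 0) next
    slope <- sum((k - kb) * (centers - cb)) / sxx
    rss <- sum((centers - cb - slope * (k - kb))^2)
    cands[[length(cands) + 1L]] <- list(d = d, slope = slope, rss = rss,
                                        span = max(k) - min(k),
                                        selfdist = abs(slope - d))
  }
  if (!length(cands)) return(NULL)
  rss <- vapply(cands, `[[`, numeric(1), "rss")
  cands <- cands[rss <= min(rss) + 1e-9]
  selfdist <- vapply(cands, `[[`, numeric(1), "selfdist")
  consistent <- selfdist <= 2
  if (any(consistent)) cands <- cands[consistent]
  span <- vapply(cands, `[[`, numeric(1), "span")
  cands <- cands[span == min(span)]
  selfdist <- vapply(cands, `[[`, numeric(1), "selfdist")
  cands[[which.min(selfdist)]]
}

#' AA/TT and GC dinucleotide signature at call centres
#'
#' Nucleosome cores favour G/C dinucleotides and deplete A/T
#' dinucleotides at their centre. For every call, the `span` bp sequence
#' centred on the call centre and its reverse complement (the dyad's
#' two-fold symmetry) are pooled; at each dinucleotide position the
#' frequency of {AA, TT} (optionally also TA) and of {GC} across the 2n
#' sequences is computed. The summary statistic is
#' `D = mean_central(f_GC) - mean_central(f_AA/TT)` over the central
#' 30 bp, with a Wald-type 95% CI of half-width
#' `sqrt(qchisq(0.95, 1)) * SE(D)`. The SE treats calls as the
#' independent sampling units: D is computed per call (from its pooled
#' strand pair over the `m` central dinucleotide positions) and the SE
#' is the empirical standard deviation of the per-call values divided
#' by `sqrt(n)`. A per-token binomial SE would be anti-conservative
#' here, since a sequence and its reverse complement duplicate the same
#' central-window dinucleotides, occurrences at adjacent positions are
#' dependent (they share a letter), and the two frequencies are
#' negatively correlated; the per-call SE absorbs all three.
#'
#' @param calls A calls `data.table` or `nf_callset`.
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes) or
#'   path to a FASTA file.
#' @param span Window width in bp around the call centre (default 150).
#' @param center_width Central window for D in bp (default 30).
#' @param include_ta Also count TA in the A/T-motif class (default
#'   FALSE: {AA, TT}).
#' @return List with `positions` (dinucleotide start offsets relative to
#'   the call centre), `f_at`, `f_gc` (per-position frequencies), `D`,
#'   `ci_low`, `ci_high`, `n` (calls used), `m` (central dinucleotide
#'   positions).
#' @export
dinucleotide_profile <- function(calls, genome, span = 150L,
                                 center_width = 30L, include_ta = FALSE) {
  if (inherits(calls, "nf_callset")) calls <- calls$calls
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (nrow(calls) == 0L) stop("no calls")
  span <- as.integer(span)
  half <- span %/% 2L
  center_mid <- calls$center_start + 15L
  chr_len <- Biostrings::width(genome)[match(calls$chrom, names(genome))]
  if (any(is.na(chr_len))) stop("genome does not cover all call chromosomes")
  start1 <- center_mid - half + 1L  # 1-based
  ok <- start1 >= 1L & (start1 + span - 1L) <= chr_len
  if (any(!ok)) message(sum(!ok), " calls near contig edges dropped")
  calls <- calls[ok]
  start1 <- start1[ok]
  n <- nrow(calls)
  if (n == 0L) stop("all calls dropped at contig edges")

  seqs <- Biostrings::DNAStringSet(lapply(seq_len(n), function(i) {
    Biostrings::subseq(genome[[calls$chrom[i]]], start1[i], width = span)
  }))
  both <- c(seqs, Biostrings::reverseComplement(seqs))
  mat <- t(vapply(as.character(both),
                  function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(span), USE.NAMES = FALSE))

  at_set <- if (include_ta) c("AA", "TT", "TA") else c("AA", "TT")
  P <- span - 1L
  f_at <- f_gc <- numeric(P)
  valid_n <- integer(P)
  for (p in seq_len(P)) {
    a <- mat[, p]; b <- mat[, p + 1L]
    valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    dn <- paste0(a[valid], b[valid])
    valid_n[p] <- sum(valid)
    if (valid_n[p] > 0L) {
      f_at[p] <- mean(dn %in% at_set)
      f_gc[p] <- mean(dn == "GC")
    }
  }
  # dinucleotide p spans letters p, p+1; offset of letter p from centre:
  positions <- seq_len(P) - 1L - half
  central <- which(positions >= -(center_width %/% 2L) &
                     (positions + 1L) <= (center_width %/% 2L) - 1L)
  m <- length(central)
  # per-call D over the central window, pooling the call's strand pair
  D_call <- vapply(seq_len(n), function(i) {
    rows <- c(i, i + n)
    sub <- mat[rows, , drop = FALSE]
    dn <- c(t(vapply(central, function(p) paste0(sub[, p], sub[, p + 1L]),
                     character(2))))
    dn <- dn[!grepl("[^ACGT]", dn)]
    if (!length(dn)) return(NA_real_)
    mean(dn == "GC") - mean(dn %in% at_set)
  }, numeric(1))
  D_call <- D_call[is.finite(D_call)]
  if (length(D_call) < 2L) stop("need >= 2 calls with usable sequence for a CI")
  D <- mean(D_call)
  se <- stats::sd(D_call) / sqrt(length(D_call))
  hw <- sqrt(stats::qchisq(0.95, df = 1)) * se
  list(positions = positions, f_at = f_at, f_gc = f_gc,
       D = D, ci_low = D - hw, ci_high = D + hw, n = n, m = m)
}
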