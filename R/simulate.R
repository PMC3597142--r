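# Synthetic MNase-Seq generator with known ground truth. Signal reads
# are drawn around planted, regularly spaced nucleosome centres with
# Gaussian positional jitter (phased nucleosomes concentrate read
# centres within ~15 bp of the dyad); background and control reads are
# uniform, optionally re-weighted towards AT-rich positions to mimic
# MNase sequence preference. Read 5' coordinates are recovered from the
# simulated centres by inverting the +/-75 bp shift on random strands.

#' Default simulation configuration
#'
#' The defaults describe a strongly phased array: 100 nucleosomes at a
#' 180 bp repeat with 15 bp positional jitter, 50 reads per nucleosome,
#' uniform background of 0.02 reads/bp in both signal and control.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Length in bp; by default `(n_nucleosomes + 1) *
#'   spacing`, i.e. the phased array with half a repeat length of
#'   padding beyond the first and last nucleosome. The default keeps
#'   the track statistically homogeneous (the background prior is
#'   fitted to the whole chromosome) while leaving room for the 150 bp
#'   window and profile flanks around the terminal nucleosomes.
#' @param n_nucleosomes Number of planted nucleosomes.
#' @param spacing Repeat length between planted centres (bp).
#' @param phasing_sd SD of the Gaussian read-centre jitter around each
#'   planted centre (bp); 0 gives perfectly phased reads.
#' @param reads_per_nucleosome Poisson mean of reads per nucleosome.
#' @param background_rate Uniform background read density (reads/bp) in
#'   the signal sample.
#' @param control_depth Control sample read density (reads/bp).
#' @param at_bias_strength Multiplier applied to the sampling weight of
#'   AT positions when a genome is supplied (1 = no bias).
#' @param gc_core_effect Increase of the per-letter G+C probability
#'   inside planted core centres of the simulated genome (see
#'   [simulate_genome()]).
#' @param read_length Read length written to BED (bp).
#' @param seed Integer seed.
#' @return Named list of class `nf_sim_config`.
#' @export
sim_config <- function(chrom = "chrSim",
                       chrom_length = NULL,
                       n_nucleosomes = 100L,
                       spacing = 180L,
                       phasing_sd = 15,
                       reads_per_nucleosome = 50,
                       background_rate = 0.02,
                       control_depth = 0.02,
                       at_bias_strength = 1,
                       gc_core_effect = 0.1,
                       read_length = 25L,
                       seed = 1L) {
  if (is.null(chrom_length)) {
    chrom_length <- as.integer((n_nucleosomes + 1L) * spacing)
  }
  stopifnot(spacing > 0, phasing_sd >= 0, reads_per_nucleosome >= 0,
            background_rate >= 0, control_depth >= 0, at_bias_strength >= 0)
  structure(list(chrom = chrom, chrom_length = as.integer(chrom_length),
                 n_nucleosomes = as.integer(n_nucleosomes),
                 spacing = as.integer(spacing), phasing_sd = phasing_sd,
                 reads_per_nucleosome = reads_per_nucleosome,
                 background_rate = background_rate,
                 control_depth = control_depth,
                 at_bias_strength = at_bias_strength,
                 gc_core_effect = gc_core_effect,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "nf_sim_config")
}

# Planted centres: regular array centred in the chromosome, with the
# first centre snapped to the midpoint of a 30 bp measurement bin.
# MNase-Seq positional uncertainty fixes the 30 bp analysis grid; a
# centre on a bin boundary splits its reads between two bins, so an
# un-snapped fixture would measure grid-phase aliasing instead of the
# model's discrimination (arbitrary phases are the job of the caller's
# offset sweep).
planted_centers <- function(config) {
  first <- (config$chrom_length -
              (config$n_nucleosomes - 1L) * config$spacing) %/% 2L
  first <- (first %/% 30L) * 30L + 15L
  first + config$spacing * (seq_len(config$n_nucleosomes) - 1L)
}

# sample k uniform positions, optionally AT-biased by the genome
sample_positions <- function(k, config, genome_chars = NULL) {
  if (k == 0L) return(integer())
  if (is.null(genome_chars) || config$at_bias_strength == 1) {
    return(as.integer(floor(stats::runif(k) * config$chrom_length)))
  }
  w <- ifelse(genome_chars %in% c("A", "T"), config$at_bias_strength, 1)
  sample.int(config$chrom_length, k, replace = TRUE, prob = w) - 1L
}

# centre positions -> read table by inverting the +/- shift
centers_to_reads <- function(pos, chrom, shift = 75L) {
  if (!length(pos)) {
    return(data.table::data.table(chrom = character(),
                                  five_prime = integer(),
                                  strand = character()))
  }
  strand <- ifelse(stats::runif(length(pos)) < 0.5, "+", "-")
  data.table::data.table(
    chrom = chrom,
    five_prime = as.integer(ifelse(strand == "+", pos - shift, pos + shift)),
    strand = strand)
}

#' Simulate signal and control MNase-Seq reads
#'
#' For each planted centre, `Poisson(reads_per_nucleosome)` read centres
#' are drawn at `centre + Normal(0, phasing_sd)` (rounded); uniform
#' background centres are added at `background_rate` per bp. Control
#' centres are uniform at `control_depth` per bp. When a genome is
#' supplied and `at_bias_strength != 1`, background and control
#' positions are both drawn from the same AT-weighted distribution, so
#' the control models exactly the bias present in the signal
#' background. Centres whose implied read would need a negative
#' coordinate are reflected to the opposite strand.
#'
#' @param config An `nf_sim_config` from [sim_config()].
#' @param genome Optional `DNAStringSet` (used only for the AT bias).
#' @return List of class `nf_simulation`: `signal`, `control` (read
#'   tables as from [read_mapped_reads()]), `truth` (planted centres +
#'   config), `chrom_sizes`.
#' @export
simulate_reads <- function(config = sim_config(), genome = NULL) {
  set.seed(config$seed)
  centers <- planted_centers(config)
  gchars <- if (!is.null(genome)) {
    strsplit(as.character(genome[[config$chrom]]), "", fixed = TRUE)[[1L]]
  }

  n_per <- stats::rpois(config$n_nucleosomes, config$reads_per_nucleosome)
  nuc_pos <- rep(centers, n_per) +
    as.integer(round(stats::rnorm(sum(n_per), 0, config$phasing_sd)))
  n_bg <- stats::rpois(1L, config$background_rate * config$chrom_length)
  bg_pos <- sample_positions(n_bg, config, gchars)
  sig_pos <- c(nuc_pos, bg_pos)
  sig_pos <- sig_pos[sig_pos >= 0L & sig_pos < config$chrom_length]

  n_ctl <- stats::rpois(1L, config$control_depth * config$chrom_length)
  ctl_pos <- sample_positions(n_ctl, config, gchars)

  shift <- 75L
  fix_strand <- function(reads) {
    # a centre too close to an edge can only be reached from one strand
    flip_minus <- reads$strand == "-" &
      reads$five_prime >= config$chrom_length
    reads$strand[flip_minus] <- "+"
    reads$five_prime[flip_minus] <- reads$five_prime[flip_minus] - 2L * shift
    flip_plus <- reads$strand == "+" & reads$five_prime < 0L
    reads$strand[flip_plus] <- "-"
    reads$five_prime[flip_plus] <- reads$five_prime[flip_plus] + 2L * shift
    reads
  }
  signal <- fix_strand(centers_to_reads(sig_pos, config$chrom, shift))
  control <- fix_strand(centers_to_reads(ctl_pos, config$chrom, shift))

  structure(list(
    signal = signal, control = control,
    truth = list(centers = centers, config = config),
    chrom_sizes = stats::setNames(config$chrom_length, config$chrom)),
    class = "nf_simulation")
}

#' Write a read table as BED6
#'
#' Inverts the 5'-end convention of [read_mapped_reads()]: a `+` read
#' spans `[five_prime, five_prime + read_length)`, a `-` read
#' `[five_prime - read_length + 1, five_prime + 1)`. Rows are written
#' in deterministic (chrom, start) order.
#'
#' @param reads Read table (`chrom`, `five_prime`, `strand`).
#' @param path Output path.
#' @param read_length Read length in bp (default 25).
#' @export
write_reads_bed <- function(reads, path, read_length = 25L) {
  start <- ifelse(reads$strand == "+", reads$five_prime,
                  reads$five_prime - read_length + 1L)
  dt <- data.table::data.table(
    chrom = reads$chrom, start = as.integer(start),
    end = as.integer(start + read_length),
    name = "r", score = 0L, strand = reads$strand)
  data.table::setorder(dt, chrom, start, strand)
  dt[, name := paste0("r", .I)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Simulate a genome with GC-enriched nucleosome cores
#'
#' Letters are drawn independently: outside cores with
#' `P(G) = P(C) = base_gc/2`, inside the central `core_width` bp of each
#' planted nucleosome with `P(G) = P(C) = (base_gc + gc_core_effect)/2`
#' (A and T share the remainder equally). Under this generator the
#' expected dinucleotide frequencies are in closed form:
#' `E f_GC = (w/2)^2` and `E f_AA/TT = 2 ((1-w)/2)^2` with `w` the
#' local G+C probability; see [expected_dinucleotide_D()].
#'
#' @param config An `nf_sim_config`; uses `chrom_length`,
#'   `gc_core_effect`, planted centres and `seed` (offset so the genome
#'   stream is independent of the read stream).
#' @param base_gc Background per-letter G+C probability (default 0.5).
#' @param core_width Width of the boosted core centre (default 30 bp).
#' @return A `Biostrings::DNAStringSet` of one chromosome.
#' @export
simulate_genome <- function(config = sim_config(), base_gc = 0.5,
                            core_width = 30L) {
  set.seed(config$seed + 1000003L)
  L <- config$chrom_length
  w <- rep(base_gc, L)
  half <- core_width %/% 2L
  for (ctr in planted_centers(config)) {
    lo <- max(1L, ctr - half + 1L)          # 1-based letters
    hi <- min(L, ctr + half)
    w[lo:hi] <- base_gc + config$gc_core_effect
  }
  if (any(w >= 1) || any(w <= 0)) stop("gc_core_effect drives letter probabilities outside (0,1)")
  u <- stats::runif(L)
  # cumulative split: A, T, G, C with P(A)=P(T)=(1-w)/2, P(G)=P(C)=w/2
  letters <- ifelse(u < (1 - w) / 2, "A",
             ifelse(u < (1 - w), "T",
             ifelse(u < 1 - w / 2, "G", "C")))
  genome <- Biostrings::DNAStringSet(paste(letters, collapse = ""))
  names(genome) <- config$chrom
  genome
}

#' Expected dinucleotide difference D under the simulated genome
#'
#' Closed-form expectation of `D = f_GC - f_AA/TT` at core centres of a
#' genome from [simulate_genome()]: with local G+C probability
#' `w = base_gc + gc_core_effect`, letters iid, `E f_GC = (w/2)^2` and
#' `E f_AA/TT = 2 * ((1-w)/2)^2`.
#'
#' @param gc_core_effect Core G+C probability boost.
#' @param base_gc Background G+C probability.
#' @return Expected D (scalar).
#' @export
expected_dinucleotide_D <- function(gc_core_effect, base_gc = 0.5) {
  w <- base_gc + gc_core_effect
  (w / 2)^2 - 2 * ((1 - w) / 2)^2
}

#' Simulate a TSS table aligned with planted nucleosome arrays
#'
#' Places `n_genes` TSSs so that each has a phased array downstream:
#' gene g's TSS sits `first_offset` bp upstream of its first planted
#' nucleosome. Used to exercise the spacing estimator on reads
#' simulated per-gene, or on arbitrary call tables.
#'
#' @param centers_by_gene List of per-gene call/centre positions.
#' @param chrom Chromosome name.
#' @param first_offset Distance from TSS to first nucleosome centre.
#' @param rpkm RPKM assigned to every gene (default 50, passes the
#'   activity filter).
#' @return A `data.frame` with `chrom`, `pos`, `strand`, `rpkm`.
#' @keywords internal
tss_for_arrays <- function(centers_by_gene, chrom = "chrSim",
                           first_offset = 90L, rpkm = 50) {
  starts <- vapply(centers_by_gene, function(x) min(x) - first_offset,
                   numeric(1))
  data.frame(chrom = chrom, pos = as.integer(starts), strand = "+",
             rpkm = rpkm)
}
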