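#' Binding probability of a single candidate site
#'
#' Biophysical occupancy probability of one motif-width window given the
#' summed mismatch energy `E` of that window:
#' `p = R0 * exp(-E/lambda) / (1 + R0 * exp(-E/lambda))` with
#' `R0 = exp(ln_r0)`. The probability is 1/2 at `E = lambda * ln_r0`, tends
#' to `plogis(ln_r0)` as `E -> 0` and to 0 as `E -> Inf`.
#'
#' @param energy Non-negative summed mismatch energy of the window
#'   (vectorized).
#' @param lambda Positive scaling of the energy (dimensionless).
#' @param ln_r0 Log of the binding constant `R0`.
#' @return Probabilities in `(0, 1)`, strictly decreasing in `energy`.
#' @export
site_probability <- function(energy, lambda = 0.7, ln_r0 = 0) {
  if (any(energy < 0)) abort("energy must be >= 0")
  if (lambda <= 0) abort("lambda must be positive")
  stats::plogis(ln_r0 - energy / lambda)
}

#' Motif affinity of a sequence
#'
#' Expected number of bound TF molecules on a sequence: the sum of
#' [site_probability()] over every window of the motif width, scanning both
#' strand orientations of every window. Windows containing `N` contribute
#' zero; sequences shorter than the motif have affinity zero.
#'
#' @param sequence A DNA string over `A/C/G/T/N` (case-insensitive), or a
#'   `Biostrings::DNAString`.
#' @param psem A `psem` object (see [read_psem()]).
#' @return A single non-negative affinity.
#' @export
peak_affinity <- function(sequence, psem) {
  stopifnot(inherits(psem, "psem"))
  .trap_affinity_cpp(as.character(sequence), psem$energies,
                     psem$lambda, psem$ln_r0)
}

#' Annotate peaks with TF affinities
#'
#' Extracts each peak's sequence from the genome and computes its affinity
#' for every energy matrix. The result is a long table with one row per
#' (peak, TF) pair; `motif_width` is carried along because the
#' binding-site-count normalization of the `DN`/`DSN` variants needs it.
#'
#' @param peaks Peak tibble as returned by [read_peaks()] (0-based
#'   half-open `start`/`end`).
#' @param genome A named `Biostrings::DNAStringSet` (or path to a FASTA
#'   file) covering every peak's chromosome.
#' @param psems Named list of `psem` objects.
#' @return A tibble with columns `chrom`, `start`, `end`, `tf`, `affinity`,
#'   `motif_width`.
#' @export
annotate_peaks <- function(peaks, genome, psems) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (nrow(peaks) == 0 || length(psems) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  tf = character(), affinity = double(),
                  motif_width = integer()))
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr) > 0)
    abort(paste0("chromosome absent from genome: ", missing_chr[1]))
  lens <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  bad <- which(peaks$end > lens | peaks$start < 0)
  if (length(bad) > 0)
    abort(sprintf("peak %s:%d-%d extends beyond chromosome end",
                  peaks$chrom[bad[1]], peaks$start[bad[1]],
                  peaks$end[bad[1]]))

  seqs <- as.character(Biostrings::subseq(
    genome[peaks$chrom], start = peaks$start + 1L, end = peaks$end))
  aff <- matrix(0, nrow = nrow(peaks), ncol = length(psems))
  for (j in seq_along(psems)) {
    p <- psems[[j]]
    aff[, j] <- vapply(
      seqs, .trap_affinity_cpp, numeric(1),
      energies = p$energies, lambda = p$lambda, ln_r0 = p$ln_r0,
      USE.NAMES = FALSE)
  }
  tf_names <- vapply(psems, function(p) p$tf_name, character(1))
  widths <- vapply(psems, function(p) p$width, integer(1))
  tibble(
    chrom = rep(peaks$chrom, times = length(psems)),
    start = rep(peaks$start, times = length(psems)),
    end = rep(peaks$end, times = length(psems)),
    tf = rep(unname(tf_names), each = nrow(peaks)),
    affinity = as.vector(aff),
    motif_width = rep(unname(widths), each = nrow(peaks))
  )
}
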