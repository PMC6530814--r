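#' Configuration of the synthetic benchmark fixture
#'
#' The generator emulates the statistical structure that confounds TF-gene
#' scores in real data: open-chromatin peaks of log-normally distributed
#' length (longer peaks accumulate more candidate binding sites and hence
#' larger raw affinities), a per-gene regulatory activity that drives the
#' accessibility signal of all peaks of that gene, and an expression
#' response that mixes TF-specific binding signal with that shared
#' activity. The latent activity drives the number of peaks (Poisson
#' rate), their accessibility signal, and -- scaled by the
#' length-confounder dial `length_confounding` -- their length: at 0 peak
#' lengths are independent of activity and only `peak_length_sdlog`
#' spreads them, while larger dial values make active genes carry
#' systematically broader peaks, strengthening the correlation between raw
#' TF scores and the aggregate `Peak_Length` feature.
#'
#' Expression is linear on the log2 scale: the causal TFs contribute their
#' standardized, confounder-adjusted (residualized against the log
#' peak-count/length/signal aggregates) raw scores with weight
#' `causal_weight`; the shared chromatin activity contributes with weight
#' `confounder_weight`; Gaussian noise with sd equal to `noise_ratio` times
#' the sd of the systematic part is added.
#'
#' @param seed Integer seed; all outputs are reproducible from it.
#' @param n_genes,n_tfs,n_causal Number of genes, TF motifs, and causally
#'   expression-driving TFs.
#' @param chrom_length Length of each synthetic chromosome (bp); genes are
#'   laid out on as many chromosomes as needed, one non-overlapping scoring
#'   window per gene.
#' @param peak_density Mean number of open-chromatin peaks per gene window
#'   (Poisson).
#' @param peak_length_meanlog,peak_length_sdlog Baseline log-normal peak
#'   length parameters (bp).
#' @param length_confounding The length-confounder dial: contribution of
#'   `log(activity)` to the per-gene peak length mean (0 decouples length
#'   from activity).
#' @param activity_sdlog Log-sd of the per-gene regulatory activity.
#' @param signal_noise_sdlog Log-sd of per-peak noise around the gene
#'   activity in the accessibility signal.
#' @param motif_width Width of every synthetic motif (bp).
#' @param plant_prob Probability that a given TF's consensus site is
#'   planted into a given peak.
#' @param causal_weight,confounder_weight,noise_ratio Expression model
#'   weights (see above).
#' @param window,d0 Scoring window and decay scale (bp) used when deriving
#'   the expression response.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_genes = 2000L, n_tfs = 50L,
                           n_causal = 5L, chrom_length = 2e6,
                           peak_density = 4,
                           peak_length_meanlog = log(300),
                           peak_length_sdlog = 0.1,
                           length_confounding = 0.5,
                           activity_sdlog = 0.6,
                           signal_noise_sdlog = 0.4,
                           motif_width = 10L, plant_prob = 0.15,
                           causal_weight = 1, confounder_weight = 1.5,
                           noise_ratio = 0.5,
                           window = 50000, d0 = 5000) {
  stopifnot(n_genes >= 1, n_tfs >= 1, n_causal >= 0, n_causal <= n_tfs,
            peak_density >= 0, peak_length_sdlog >= 0,
            length_confounding >= 0, motif_width >= 2,
            plant_prob >= 0, plant_prob <= 1, noise_ratio >= 0,
            window > 0, d0 > 0)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_tfs = as.integer(n_tfs), n_causal = as.integer(n_causal),
         chrom_length = chrom_length, peak_density = peak_density,
         peak_length_meanlog = peak_length_meanlog,
         peak_length_sdlog = peak_length_sdlog,
         length_confounding = length_confounding,
         activity_sdlog = activity_sdlog,
         signal_noise_sdlog = signal_noise_sdlog,
         motif_width = as.integer(motif_width), plant_prob = plant_prob,
         causal_weight = causal_weight,
         confounder_weight = confounder_weight, noise_ratio = noise_ratio,
         window = window, d0 = d0),
    class = "fixture_config")
}

#' Plant consensus motif sites into a sequence
#'
#' Writes `n_sites` copies of the matrix's minimum-energy (consensus)
#' sequence at random non-overlapping positions, so the affinity of the
#' modified sequence strictly exceeds the original's.
#'
#' @param sequence DNA string.
#' @param psem A `psem` object.
#' @param n_sites Number of sites to plant.
#' @return A list with `sequence` (modified string) and `positions`
#'   (1-based start of each planted site).
#' @export
plant_motifs <- function(sequence, psem, n_sites) {
  sequence <- as.character(sequence)
  w <- psem$width
  len <- nchar(sequence)
  if (n_sites == 0) return(list(sequence = sequence, positions = integer()))
  if (n_sites * w > len) abort("sequence too short for requested sites")
  consensus <- paste(colnames(psem$energies)[apply(psem$energies, 1,
                                                   which.min)],
                     collapse = "")
  original <- sequence
  for (attempt in 1:40) {
    sequence <- original
    placed <- integer()
    tries <- 0
    while (length(placed) < n_sites && tries < 60 * n_sites) {
      tries <- tries + 1
      pos <- sample.int(len - w + 1L, 1)
      if (any(abs(placed - pos) < w)) next
      substr(sequence, pos, pos + w - 1L) <- consensus
      placed <- c(placed, pos)
    }
    if (length(placed) == n_sites)
      return(list(sequence = sequence, positions = sort(placed)))
  }
  abort("could not place non-overlapping sites")
}

random_psems <- function(n_tfs, motif_width) {
  lapply(seq_len(n_tfs), function(t) {
    e <- matrix(stats::runif(motif_width * 4, 0.3, 1.6), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    e[cbind(seq_len(motif_width), sample.int(4, motif_width, TRUE))] <- 0
    new_psem(sprintf("TF%03d", t), e, lambda = 0.7,
             ln_r0 = 0.584 * motif_width - 5.66)
  })
}

#' Generate a fully synthetic benchmark dataset
#'
#' Produces a genome, gene models, open-chromatin (DNase-like) peaks with
#' accessibility signal, per-TF ChIP-like peaks, energy matrices,
#' a gene expression table whose generative weights are known, and the
#' precomputed peak-TF affinities. See [fixture_config()] for the
#' generative model. When `out_dir` is given, all components are also
#' written in their standard file formats (FASTA, GTF, narrowPeak, PSEM
#' text, TSV, JSON) and byte-identical outputs are guaranteed for the same
#' seed.
#'
#' @param config A [fixture_config()].
#' @param out_dir Optional output directory.
#' @return A list: `genome` (DNAStringSet), `genes`, `dnase_peaks`,
#'   `chip_peaks`, `psems`, `affinities`, `expression`, `ground_truth`
#'   (causal TFs and weights), `params` ([decay_params()]) and `config`.
#' @export
generate_fixture <- function(config = fixture_config(), out_dir = NULL) {
  fx <- with_preserved_seed(config$seed, build_fixture(config))
  if (!is.null(out_dir)) write_fixture(fx, out_dir)
  fx
}

build_fixture <- function(cfg) {
  spacing <- cfg$window + 4000
  genes_per_chrom <- floor(cfg$chrom_length / spacing)
  if (genes_per_chrom < 1)
    abort("chrom_length too small for one gene window")
  n_chrom <- ceiling(cfg$n_genes / genes_per_chrom)
  gi <- seq_len(cfg$n_genes) - 1L
  slot <- gi %% genes_per_chrom
  chrom <- sprintf("chr%d", gi %/% genes_per_chrom + 1L)
  tss0 <- slot * spacing + as.integer(spacing / 2)
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = chrom, strand = sample(c("+", "-"), cfg$n_genes, TRUE),
    tss = as.integer(tss0 + 1L))

  psems <- random_psems(cfg$n_tfs, cfg$motif_width)
  names(psems) <- vapply(psems, `[[`, character(1), "tf_name")
  tf_names <- names(psems)
  causal <- sort(sample(tf_names, cfg$n_causal))

  # open-chromatin peaks: log-normal lengths, kept non-overlapping so the
  # genome islands can be pasted in directly; the latent per-gene
  # regulatory activity drives how many peaks a gene has (and, below,
  # their signal), which is what makes peak count/length/signal genuine
  # confounders of the TF scores
  half <- cfg$window / 2
  activity <- stats::rlnorm(cfg$n_genes, 0, cfg$activity_sdlog)
  rate <- cfg$peak_density * activity / exp(cfg$activity_sdlog^2 / 2)
  peak_rows <- vector("list", cfg$n_genes)
  min_len <- max(2L * cfg$motif_width, 30L)
  for (g in seq_len(cfg$n_genes)) {
    # every gene window keeps at least one accessible site so that a TF's
    # planted dose is never forced to zero by chromatin state
    n_p <- 1L + stats::rpois(1, max(rate[g] - 1, 0))
    meanlog_g <- cfg$peak_length_meanlog +
      cfg$length_confounding * log(activity[g])
    len <- pmin(pmax(round(stats::rlnorm(n_p, meanlog_g,
                                         cfg$peak_length_sdlog)),
                     min_len), floor(half / 2))
    mid <- tss0[g] + round(stats::runif(n_p, -(half - len - 1), half - len - 1))
    start <- as.integer(mid - floor(len / 2))
    o <- order(start)
    start <- start[o]; len <- len[o]
    keep <- rep(TRUE, n_p)
    last_end <- -1
    for (i in seq_len(n_p)) {
      if (start[i] <= last_end) keep[i] <- FALSE
      else last_end <- start[i] + len[i]
    }
    sig <- activity[g] * stats::rlnorm(sum(keep), 0, cfg$signal_noise_sdlog)
    p_start <- start[keep]
    p_end <- as.integer(p_start + len[keep])
    peak_rows[[g]] <- tibble(
      chrom = genes$chrom[g], start = p_start, end = p_end,
      gene = genes$gene_id[g], signal = sig)
  }
  pk <- bind_rows(peak_rows)
  if (nrow(pk) == 0) abort("no peaks generated; increase peak_density")
  pk$name <- sprintf("peak%05d", seq_len(nrow(pk)))

  # peak sequences with planted consensus sites; planting is per gene (one
  # Bernoulli draw per gene and TF, one randomly chosen peak of that gene)
  # so that a TF's true binding dose is independent of how many peaks a
  # gene happens to have. The decay-weighted affinity gained by planting is
  # recorded for the causal TFs -- it is their true contribution to
  # expression.
  seqs <- vapply(pk$end - pk$start, function(l)
    paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
    character(1))
  planted <- matrix(FALSE, nrow(pk), cfg$n_tfs,
                    dimnames = list(NULL, tf_names))
  u <- matrix(0, cfg$n_genes, length(causal),
              dimnames = list(genes$gene_id, causal))
  pk_mid <- floor((pk$start + pk$end) / 2)
  pk_dist <- abs(pk_mid - tss0[match(pk$gene, genes$gene_id)])
  # sites are planted into promoter-proximal peaks (within d0 of the TSS,
  # falling back to the closest peak) so that the planted dose is not
  # entangled with where a gene's peaks happen to lie
  plantable <- lapply(split(seq_len(nrow(pk)), pk$gene), function(idx) {
    prox <- idx[pk_dist[idx] <= cfg$d0]
    if (length(prox) > 0) prox else idx[which.min(pk_dist[idx])]
  })
  for (t in seq_len(cfg$n_tfs)) {
    tf <- tf_names[t]
    hit_genes <- which(stats::runif(cfg$n_genes) < cfg$plant_prob)
    for (g in hit_genes) {
      idx <- plantable[[genes$gene_id[g]]]
      if (is.null(idx)) next
      i <- if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
      n_sites <- min(1L + sample.int(3L, 1),
                     max(1L, nchar(seqs[i]) %/% (2L * cfg$motif_width)))
      if (tf %in% causal) {
        before <- peak_affinity(seqs[i], psems[[t]])
        seqs[i] <- plant_motifs(seqs[i], psems[[t]], n_sites)$sequence
        u[g, tf] <- u[g, tf] + peak_affinity(seqs[i], psems[[t]]) - before
      } else {
        seqs[i] <- plant_motifs(seqs[i], psems[[t]], n_sites)$sequence
      }
      planted[i, t] <- TRUE
    }
  }

  genome <- build_genome(pk, seqs, n_chrom, cfg$chrom_length)
  dnase_peaks <- tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                        name = pk$name, score = 0, signal = pk$signal)

  # ChIP-like peaks: planted sites are bound (intervals jittered around the
  # hosting open-chromatin peak), plus background calls at random genomic
  # positions that usually fall into closed chromatin
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  chip_rows <- vector("list", cfg$n_tfs)
  for (t in seq_len(cfg$n_tfs)) {
    idx <- which(planted[, t])
    jit <- matrix(sample.int(101L, 2 * length(idx), TRUE) - 1L, ncol = 2)
    true_calls <- tibble(
      chrom = pk$chrom[idx],
      start = pmax(pk$start[idx] - jit[, 1], 0L),
      end = pmin(pk$end[idx] + jit[, 2], as.integer(cfg$chrom_length)))
    n_bg <- max(1L, ceiling(0.25 * length(idx)))
    bg_len <- pmax(round(stats::rlnorm(n_bg, log(250), 0.3)), 50)
    bg_start <- floor(stats::runif(n_bg, 0, cfg$chrom_length - bg_len))
    bg_calls <- tibble(
      chrom = sample(chroms, n_bg, TRUE),
      start = as.integer(bg_start),
      end = as.integer(bg_start + bg_len))
    calls <- bind_rows(true_calls, bg_calls)
    chip_rows[[t]] <- calls |>
      mutate(name = sprintf("%s_p%04d", tf_names[t], dplyr::row_number()),
             score = stats::rlnorm(nrow(calls), log(10), 0.5),
             signal = NA_real_, tf = tf_names[t])
  }
  chip_peaks <- bind_rows(chip_rows)

  params <- decay_params(d0 = cfg$d0, window = cfg$window)
  affinities <- annotate_peaks(dnase_peaks, genome, psems)

  expr <- simulate_expression(genes, cfg, activity, u, causal)

  list(genome = genome, genes = genes, dnase_peaks = dnase_peaks,
       chip_peaks = chip_peaks, psems = psems, affinities = affinities,
       expression = expr$expression, ground_truth = expr$ground_truth,
       params = params, config = cfg)
}

build_genome <- function(pk, seqs, n_chrom, chrom_length) {
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  out <- lapply(chroms, function(cn) {
    x <- Biostrings::DNAString(strrep("N", chrom_length))
    idx <- which(pk$chrom == cn)
    if (length(idx) > 0)
      x <- Biostrings::replaceAt(
        x, IRanges::IRanges(start = pk$start[idx] + 1L, end = pk$end[idx]),
        Biostrings::DNAStringSet(seqs[idx]))
    x
  })
  stats::setNames(Biostrings::DNAStringSet(out), chroms)
}

simulate_expression <- function(genes, cfg, activity, u, causal) {
  zcol <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  causal_part <- if (length(causal) == 0) 0 else
    rowSums(vapply(causal, function(t) zcol(log2(1 + u[, t])),
                   numeric(cfg$n_genes)))
  act <- zcol(log(activity))
  systematic <- cfg$causal_weight * causal_part +
    cfg$confounder_weight * act
  noise_sd <- cfg$noise_ratio * stats::sd(systematic)
  log_expr <- 5 + systematic + stats::rnorm(cfg$n_genes, 0, noise_sd)
  list(
    expression = tibble(gene_id = genes$gene_id,
                        expression = unname(pmax(2^log_expr - 1, 0))),
    ground_truth = list(causal_tfs = causal,
                        causal_weight = cfg$causal_weight,
                        confounder_weight = cfg$confounder_weight,
                        noise_sd = noise_sd, seed = cfg$seed))
}

write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    ifelse(is.na(peaks$name), ".", peaks$name),
    format(peaks$score, digits = 15, trim = TRUE, scientific = FALSE), ".",
    ifelse(is.na(peaks$signal), "0",
           format(peaks$signal, digits = 15, trim = TRUE,
                  scientific = FALSE)),
    -1, -1, -1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_gtf <- function(genes, path, chrom_length) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      s <- g$tss; e <- min(g$tss + 999L, chrom_length)
    } else {
      e <- g$tss; s <- max(g$tss - 999L, 1L)
    }
    attr_gene <- sprintf('gene_id "%s";', g$gene_id)
    attr_tx <- sprintf('gene_id "%s"; transcript_id "%s.1";',
                       g$gene_id, g$gene_id)
    lines <- c(lines,
      paste(g$chrom, "regscore", "gene", s, e, ".", g$strand, ".",
            attr_gene, sep = "\t"),
      paste(g$chrom, "regscore", "transcript", s, e, ".", g$strand, ".",
            attr_tx, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(fx$genome, file.path(out_dir, "genome.fa"))
  write_gtf(fx$genes, file.path(out_dir, "genes.gtf"),
            fx$config$chrom_length)
  write_narrowpeak(fx$dnase_peaks, file.path(out_dir, "dnase.narrowPeak"))
  chip_dir <- file.path(out_dir, "chip")
  dir.create(chip_dir, showWarnings = FALSE)
  manifest <- fx$chip_peaks |>
    group_by(.data$tf) |>
    group_walk(~ write_narrowpeak(
      .x, file.path(chip_dir, paste0(.y$tf, ".narrowPeak")))) |>
    summarise() |>
    mutate(path = file.path("chip", paste0(.data$tf, ".narrowPeak")))
  readr::write_tsv(manifest, file.path(out_dir, "chip_manifest.tsv"))
  write_psem(fx$psems, file.path(out_dir, "motifs.psem"))
  readr::write_tsv(fx$expression, file.path(out_dir, "expression.tsv"))
  jsonlite::write_json(fx$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a per-TF ChIP peak manifest
#'
#' A manifest is a TSV with columns `tf` and `path` (relative to the
#' manifest's directory), one ChIP narrowPeak file per TF. Returns the
#' combined peak tibble with a `tf` column, as expected by [score_chip()].
#'
#' @param path Path to the manifest TSV.
#' @return A peak tibble with a `tf` column.
#' @export
read_chip_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  base <- dirname(path)
  purrr::map2_dfr(man$tf, man$path, function(tf, p) {
    read_peaks(file.path(base, p), format = "narrowPeak") |>
      mutate(tf = tf)
  })
}
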