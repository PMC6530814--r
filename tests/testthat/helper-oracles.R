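# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain R loops, textbook formulas.

BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Logistic site probability, scalar form
oracle_site_prob <- function(energy, lambda, ln_r0) {
  r0 <- exp(ln_r0)
  v <- r0 * exp(-energy / lambda)
  v / (1 + v)
}

# Window-enumeration TRAP affinity: every window of width w, both strands
oracle_affinity <- function(seq, psem) {
  w <- psem$width
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < w) return(0)
  total <- 0
  for (i in seq_len(L - w + 1)) {
    win <- chars[i:(i + w - 1)]
    if (any(!win %in% BASES)) next
    e_fwd <- sum(vapply(seq_len(w),
                        function(j) psem$energies[j, win[j]], numeric(1)))
    rc <- strsplit(revcomp_chr(paste(win, collapse = "")), "")[[1]]
    e_rev <- sum(vapply(seq_len(w),
                        function(j) psem$energies[j, rc[j]], numeric(1)))
    total <- total + oracle_site_prob(e_fwd, psem$lambda, psem$ln_r0) +
      oracle_site_prob(e_rev, psem$lambda, psem$ln_r0)
  }
  total
}

random_psem_fixture <- function(width, name = "TFX") {
  e <- matrix(runif(width * 4, 0, 2.5), ncol = 4,
              dimnames = list(NULL, BASES))
  regscore:::new_psem(name, e, lambda = runif(1, 0.4, 1.2),
                      ln_r0 = runif(1, -2, 1))
}

random_seq <- function(len, n_prob = 0) {
  alphabet <- if (n_prob > 0) c(BASES, "N") else BASES
  p <- if (n_prob > 0) c(rep((1 - n_prob) / 4, 4), n_prob) else rep(0.25, 4)
  paste(sample(alphabet, len, TRUE, prob = p), collapse = "")
}

# --- brute-force gene scoring (all nine variants) -------------------------

# peak assigned to gene iff [start, end) overlaps [tss0-w/2, tss0+w/2);
# d = |floor((start+end)/2) - tss0|
oracle_assigned <- function(gene, peak, window) {
  tss0 <- gene$tss - 1
  lo <- tss0 - window / 2
  hi <- tss0 + window / 2
  gene$chrom == peak$chrom && peak$start < hi && peak$end > lo
}

oracle_weight <- function(gene, peak, d0) {
  exp(-abs(floor((peak$start + peak$end) / 2) - (gene$tss - 1)) / d0)
}

# chip_peaks: data frame with chrom/start/end/score/tf
oracle_chip <- function(genes, chip_peaks, d0, window, variant) {
  tfs <- sort(unique(chip_peaks$tf))
  a <- matrix(0, nrow(genes), length(tfs),
              dimnames = list(genes$gene_id, tfs))
  cc <- ll <- numeric(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    for (pi in seq_len(nrow(chip_peaks))) {
      p <- chip_peaks[pi, ]
      if (!oracle_assigned(g, p, window)) next
      w <- oracle_weight(g, p, d0)
      a[gi, p$tf] <- a[gi, p$tf] + p$score * w
      cc[gi] <- cc[gi] + w
      ll[gi] <- ll[gi] + (p$end - p$start) * w
    }
  }
  switch(variant,
    C = cbind(a),
    CN = {
      ab <- a / ifelse(cc > 0, cc, 1)
      ab[cc == 0, ] <- 0
      cbind(ab, Peak_Count = cc, Peak_Length = ll)
    },
    CPF = cbind(Peak_Count = cc, Peak_Length = ll))
}

# dnase peaks: chrom/start/end/signal; aff: function(peak_index, tf) and
# widths: named motif widths
oracle_dnase <- function(genes, peaks, aff, widths, d0, window, variant) {
  tfs <- sort(names(widths))
  a <- matrix(0, nrow(genes), length(tfs),
              dimnames = list(genes$gene_id, tfs))
  cc <- ll <- ff <- numeric(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    for (pi in seq_len(nrow(peaks))) {
      p <- peaks[pi, ]
      if (!oracle_assigned(g, p, window)) next
      w <- oracle_weight(g, p, d0)
      cc[gi] <- cc[gi] + w
      ll[gi] <- ll[gi] + (p$end - p$start) * w
      ff[gi] <- ff[gi] + p$signal * w
      for (tf in tfs) {
        v <- switch(variant,
          D = aff(pi, tf),
          DS = aff(pi, tf) * p$signal,
          DN = ,
          DSN = aff(pi, tf) /
            max(p$end - p$start - widths[[tf]] + 1, 1),
          0)
        a[gi, tf] <- a[gi, tf] + v * w
      }
    }
  }
  switch(variant,
    D = cbind(a),
    DS = cbind(a),
    DN = cbind(a, Peak_Count = cc, Peak_Length = ll),
    DSN = cbind(a, Peak_Count = cc, Peak_Length = ll, Peak_Signal = ff),
    DPF = cbind(Peak_Count = cc, Peak_Length = ll),
    DPFS = cbind(Peak_Count = cc, Peak_Length = ll, Peak_Signal = ff))
}

# --- AUPR by numeric integration of the interpolated PR curve -------------

# tp/fp: cumulative counts at the tie-grouped operating points
oracle_aupr <- function(tp, fp, n_pos, steps = 20000) {
  tp <- c(0, tp); fp <- c(0, fp)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    tt <- seq(tp[i], tp[i + 1], length.out = steps)
    ffp <- fp[i] + (fp[i + 1] - fp[i]) * (tt - tp[i]) / dtp
    prec <- tt / (tt + ffp)
    # 0/0 at the origin: use the segment's limiting precision
    prec[tt + ffp == 0] <- dtp / (dtp + (fp[i + 1] - fp[i]))
    area <- area + sum((prec[-1] + prec[-steps]) / 2 * diff(tt))
  }
  area / n_pos
}

# random toy gene/peak sets for scoring-oracle comparisons
random_toy_genes <- function(n) {
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = sample(c("chrA", "chrB"), n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    tss = sample.int(60000, n))
}

random_toy_peaks <- function(n, tfs = NULL) {
  start <- sample.int(80000, n)
  out <- tibble::tibble(
    chrom = sample(c("chrA", "chrB"), n, TRUE),
    start = start,
    end = start + sample.int(2000, n),
    name = NA_character_,
    score = round(runif(n, 0, 10), 3),
    signal = round(runif(n, 0, 5), 3))
  if (!is.null(tfs)) out$tf <- sample(tfs, n, TRUE)
  out
}

toy_affinities <- function(peaks, widths) {
  tidyr::expand_grid(
    peaks[c("chrom", "start", "end")],
    tf = names(widths)) |>
    dplyr::mutate(affinity = round(runif(dplyr::n(), 0, 2), 4),
                  motif_width = unname(widths[tf]))
}

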