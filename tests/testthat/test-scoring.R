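pm <- decay_params(d0 = 5000, window = 50000)

gene1 <- tibble::tibble(gene_id = "g1", chrom = "chrA", strand = "+",
                        tss = 30001L)  # tss0 = 30000

peak_at <- function(dist, len = 100, score = 1, signal = 1, tf = NULL,
                    chrom = "chrA") {
  mid <- 30000 + dist
  out <- tibble::tibble(chrom = chrom, start = as.integer(mid - len / 2),
                        end = as.integer(mid + len / 2),
                        name = NA_character_, score = score, signal = signal)
  if (!is.null(tf)) out$tf <- tf
  out
}

test_that("decay weight is exp(-d/d0) with d0 defaulting to 5000", {
  expect_equal(decay_weight(0, pm), 1)
  expect_equal(decay_weight(5000, pm), exp(-1))
  expect_equal(decay_weight(5000, pm), 0.3678794, tolerance = 1e-6)
  expect_equal(decay_params()$d0, 5000)
  expect_equal(decay_params()$window, 50000)
  expect_error(decay_weight(-1, pm), ">= 0")
})

test_that("window assignment uses any-overlap and midpoint distance", {
  p0 <- peak_at(0)
  asn <- assign_windows(gene1, p0, pm)
  expect_equal(asn$distance, 0)
  expect_equal(asn$weight, 1)

  # peak straddling the right window edge is admitted
  edge <- tibble::tibble(chrom = "chrA", start = 30000L + 24990L,
                         end = 30000L + 25010L, name = NA,
                         score = 1, signal = 1)
  expect_equal(nrow(assign_windows(gene1, edge, pm)), 1L)
  # peak fully beyond the edge is not
  out <- tibble::tibble(chrom = "chrA", start = 30000L + 25000L,
                        end = 30000L + 25100L, name = NA,
                        score = 1, signal = 1)
  expect_equal(nrow(assign_windows(gene1, out, pm)), 0L)
})

test_that("window assignment matches a brute-force interval oracle", {
  set.seed(21)
  for (i in 1:20) {
    genes <- random_toy_genes(3)
    peaks <- random_toy_peaks(5)
    asn <- assign_windows(genes, peaks, pm)
    for (gi in seq_len(nrow(genes))) {
      for (pi in seq_len(nrow(peaks))) {
        hit <- oracle_assigned(genes[gi, ], peaks[pi, ], pm$window)
        found <- any(asn$gene_id == genes$gene_id[gi] &
                     asn$start == peaks$start[pi] &
                     asn$chrom == peaks$chrom[pi] &
                     asn$end == peaks$end[pi])
        expect_equal(found, hit)
      }
    }
  }
})

test_that("ChIP scores reproduce hand-computed decay sums", {
  one <- peak_at(0, score = 3.5, tf = "T1")
  expect_equal(score_chip(gene1, one, pm, "C")$T1, 3.5)

  two <- dplyr::bind_rows(peak_at(5000, score = 2, tf = "T1"),
                          peak_at(0, score = 1, tf = "T1"))
  expect_equal(score_chip(gene1, two, pm, "C")$T1, 2 * exp(-1) + 1,
               tolerance = 1e-12)
  expect_equal(score_chip(gene1, two, pm, "C")$T1, 1.735759,
               tolerance = 1e-6)

  none <- peak_at(0, tf = "T1", chrom = "chrZ")
  expect_equal(score_chip(gene1, none, pm, "C")$T1, 0)
})

test_that("ChIP peak features count every peak of every TF", {
  one <- peak_at(0, len = 100, tf = "T1")
  cpf <- score_chip(gene1, one, pm, "CPF")
  expect_equal(cpf$Peak_Count, 1)
  expect_equal(cpf$Peak_Length, 100)
  expect_equal(variant_of(cpf), "CPF")

  two_tfs <- dplyr::bind_rows(peak_at(5000, tf = "T1"),
                              peak_at(5000, tf = "T2"))
  cpf <- score_chip(gene1, two_tfs, pm, "CPF")
  expect_equal(cpf$Peak_Count, 2 * exp(-1), tolerance = 1e-12)
  expect_equal(cpf$Peak_Count, 0.735759, tolerance = 1e-6)

  empty <- peak_at(0, tf = "T1", chrom = "chrZ")
  cpf <- score_chip(gene1, empty, pm, "CPF")
  expect_equal(cpf$Peak_Count, 0)
  expect_equal(cpf$Peak_Length, 0)
})

test_that("CN normalizes by the aggregate count and keeps both features", {
  # single peak with weight 1 -> denominator 1, score unchanged
  one <- peak_at(0, score = 4, tf = "T1")
  cn <- score_chip(gene1, one, pm, "CN")
  expect_equal(cn$T1, 4)
  expect_named(cn, c("gene_id", "T1", "Peak_Count", "Peak_Length"))

  # two peaks of one TF: a = 2e^-1 + 1, c = e^-1 + 1
  peaks <- dplyr::bind_rows(peak_at(5000, score = 2, tf = "T1"),
                            peak_at(0, score = 1, tf = "T1"))
  cn <- score_chip(gene1, peaks, pm, "CN")
  expect_equal(cn$T1, (2 * exp(-1) + 1) / (exp(-1) + 1), tolerance = 1e-12)

  # gene with no peaks: all features zero, not NaN
  g2 <- tibble::tibble(gene_id = "g2", chrom = "chrB", strand = "+",
                       tss = 30001L)
  cn <- score_chip(dplyr::bind_rows(gene1, g2), one, pm, "CN")
  expect_equal(cn$T1[cn$gene_id == "g2"], 0)
})

test_that("CN times the count reconstructs C wherever the count is > 0", {
  set.seed(22)
  for (i in 1:10) {
    genes <- random_toy_genes(6)
    peaks <- random_toy_peaks(15, tfs = c("T1", "T2", "T3"))
    cm <- score_chip(genes, peaks, pm, "C")
    cn <- score_chip(genes, peaks, pm, "CN")
    for (tf in c("T1", "T2", "T3")) {
      ok <- cn$Peak_Count > 0
      expect_equal(cn[[tf]][ok] * cn$Peak_Count[ok], cm[[tf]][ok],
                   tolerance = 1e-9)
      expect_equal(cn[[tf]][!ok], rep(0, sum(!ok)))
    }
  }
})

test_that("DNase variants reproduce hand-computed values", {
  p <- peak_at(0, len = 60, signal = 2)
  aff <- tibble::tibble(chrom = p$chrom, start = p$start, end = p$end,
                        tf = "T1", affinity = 0.5, motif_width = 11L)
  expect_equal(score_dnase(gene1, p, aff, pm, "D")$T1, 0.5)
  expect_equal(score_dnase(gene1, p, aff, pm, "DS")$T1, 1.0)
  dn <- score_dnase(gene1, p, aff, pm, "DN")
  expect_equal(dn$T1, 0.5 / 50)
  expect_equal(dn$T1, 0.01)
  expect_named(dn, c("gene_id", "T1", "Peak_Count", "Peak_Length"))
  dsn <- score_dnase(gene1, p, aff, pm, "DSN")
  expect_named(dsn, c("gene_id", "T1", "Peak_Count", "Peak_Length",
                      "Peak_Signal"))
  expect_equal(dsn$Peak_Signal, 2)
  expect_named(score_dnase(gene1, p, NULL, pm, "DPF"),
               c("gene_id", "Peak_Count", "Peak_Length"))
  expect_named(score_dnase(gene1, p, NULL, pm, "DPFS"),
               c("gene_id", "Peak_Count", "Peak_Length", "Peak_Signal"))

  # short peak: binding-site divisor clamps at 1
  short <- peak_at(0, len = 8)
  aff2 <- aff
  aff2$start <- short$start; aff2$end <- short$end
  expect_equal(score_dnase(gene1, short, aff2, pm, "DN")$T1, 0.5)

  expect_error(score_dnase(gene1, p, aff, pm, "XX"))
  expect_error(score_dnase(gene1, p, aff[0, ], pm, "D"), "affinity missing")
})

test_that("peak features are TF-blind", {
  set.seed(23)
  genes <- random_toy_genes(5)
  peaks <- random_toy_peaks(12, tfs = c("T1", "T2"))
  a <- score_chip(genes, peaks, pm, "CPF")
  shuffled <- peaks
  shuffled$tf <- sample(shuffled$tf)
  b <- score_chip(genes, shuffled, pm, "CPF")
  expect_equal(a, b, ignore_attr = TRUE)

  dpeaks <- random_toy_peaks(12)
  w1 <- c(T1 = 5L, T2 = 9L)
  w2 <- c(T1 = 11L, T2 = 3L)
  f1 <- score_dnase(genes, dpeaks, toy_affinities(dpeaks, w1), pm, "DPFS")
  f2 <- score_dnase(genes, dpeaks, toy_affinities(dpeaks, w2), pm, "DPFS")
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("decay and window limits behave as expected", {
  set.seed(24)
  genes <- random_toy_genes(4)
  peaks <- random_toy_peaks(10, tfs = "T1")
  flat <- decay_params(d0 = 1e12, window = 50000)
  cf <- score_chip(genes, peaks, flat, "C")
  # unweighted sum over window peaks
  manual <- vapply(seq_len(nrow(genes)), function(gi) {
    s <- 0
    for (pi in seq_len(nrow(peaks)))
      if (oracle_assigned(genes[gi, ], peaks[pi, ], 50000))
        s <- s + peaks$score[pi]
    s
  }, numeric(1))
  expect_equal(cf$T1, manual, tolerance = 1e-6)

  tiny <- decay_params(d0 = 5000, window = 1e-9)
  expect_true(all(score_chip(genes, peaks, tiny, "C")$T1 == 0))
})

test_that("design building log-transforms and aligns on sorted shared ids", {
  feats <- tibble::tibble(gene_id = c("g3", "g1", "g2", "g5", "g4"),
                          T1 = c(0, 7, 1, 2, 3))
  expr <- tibble::tibble(gene_id = c("g2", "g9", "g1", "g3"),
                         expression = c(7, 5, 0, 3))
  d <- build_design(feats, expr)
  expect_equal(d$genes, c("g1", "g2", "g3"))
  expect_equal(unname(d$x[, "T1"]), log2(c(7, 1, 0) + 1))
  expect_equal(unname(d$x["g1", "T1"]), 3)
  expect_equal(unname(d$y), log2(c(0, 7, 3) + 1))
  expect_equal(unname(d$y["g2"]), 3)
  expect_error(build_design(feats, tibble::tibble(gene_id = "zz",
                                                  expression = 1)),
               "no shared")
})
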