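#' Pairwise Spearman correlation between gene score columns
#'
#' High pairwise correlation between TF-gene scores is the signature of
#' shared (confounded or biological) structure; the median off-diagonal
#' value summarizes it.
#'
#' @param features Feature matrix tibble with at least 2 columns in scope
#'   and 3 genes.
#' @param subset `"tf_columns"` (default) correlates only TF columns;
#'   `"all"` includes the aggregate peak-feature columns.
#' @return A list with `correlations` (symmetric matrix, unit diagonal) and
#'   `median_off_diagonal` (median over the strictly upper triangle,
#'   undefined pairs from constant columns excluded with a warning).
#' @export
pairwise_correlation <- function(features, subset = c("tf_columns", "all")) {
  subset <- match.arg(subset)
  cols <- if (subset == "tf_columns") tf_columns(features)
          else setdiff(names(features), "gene_id")
  if (length(cols) < 2) abort("need >= 2 columns")
  m <- as.matrix(features[cols])
  if (nrow(m) < 3) abort("need >= 3 genes")
  cm <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(cm) <- 1
  up <- cm[upper.tri(cm)]
  if (anyNA(up))
    warn(sprintf("%d undefined correlation(s) from constant columns excluded",
                 sum(is.na(up))))
  list(correlations = cm,
       median_off_diagonal = stats::median(up, na.rm = TRUE))
}

#' Correlation of TF scores with the aggregate chromatin confounders
#'
#' Spearman correlation of every TF column against each available
#' peak-feature column (`Peak_Count`, `Peak_Length`, `Peak_Signal`). Large
#' values flag TF scores dominated by open-chromatin characteristics rather
#' than TF-specific binding.
#'
#' @param features Feature matrix tibble whose TF columns are to be tested.
#' @param confounders Optional tibble carrying `gene_id` plus peak-feature
#'   columns (e.g. a `DPFS` matrix); defaults to the peak-feature columns
#'   of `features` itself.
#' @return A tibble with columns `tf`, `confounder`, `spearman`.
#' @export
feature_confounder_correlation <- function(features, confounders = NULL) {
  tfs <- tf_columns(features)
  if (is.null(confounders)) {
    pcols <- intersect(PEAK_FEATURE_COLS, names(features))
    if (length(pcols) == 0)
      abort("no peak-feature columns found; supply `confounders`")
    conf <- features[c("gene_id", pcols)]
  } else {
    pcols <- intersect(PEAK_FEATURE_COLS, names(confounders))
    if (length(pcols) == 0) abort("`confounders` has no peak-feature columns")
    conf <- confounders[c("gene_id", pcols)]
  }
  joined <- inner_join(features[c("gene_id", tfs)], conf, by = "gene_id")
  tidyr::expand_grid(tf = tfs, confounder = pcols) |>
    mutate(spearman = purrr::map2_dbl(
      .data$tf, .data$confounder,
      ~ suppressWarnings(stats::cor(joined[[.x]], joined[[.y]],
                                    method = "spearman"))))
}

# Area under the precision-recall curve with nonlinear interpolation
# between tie-grouped operating points: between (tp_a, fp_a) and
# (tp_b, fp_b), fp grows linearly in tp, so precision tp/(tp + fp(tp)) is
# integrated in closed form.
aupr_interpolated <- function(tp, fp, n_pos) {
  tp <- c(0, tp); fp <- c(0, fp)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    s <- (fp[i + 1] - fp[i]) / dtp
    k <- 1 + s
    cc <- fp[i] - s * tp[i]
    seg <- if (abs(cc) < 1e-12) {
      dtp / k
    } else {
      f <- function(t) t / k - (cc / k^2) * log(k * t + cc)
      f(tp[i + 1]) - f(tp[i])
    }
    area <- area + seg
  }
  area / n_pos
}

#' Precision-recall evaluation of a regulator ranking
#'
#' TFs with nonzero coefficients are ranked (descending signed coefficient
#' by default, or by absolute value) and compared against a gold-standard
#' set of regulators. A true positive is a retrieved TF contained in the
#' gold standard, a false positive a retrieved TF outside it, and a false
#' negative a gold-standard TF not retrieved. Tied coefficients are grouped
#' at a single operating point, and the area under the precision-recall
#' curve uses nonlinear interpolation between operating points.
#'
#' @param coefficients Named numeric vector of per-TF coefficients (e.g.
#'   [mean_coefficients()]).
#' @param gold_standard Character vector of gold-standard TF names
#'   (non-empty).
#' @param absolute Rank by `|coefficient|` instead of the signed value.
#' @return A `regscore_pr` object: `points` (tibble with `depth`, `tp`,
#'   `fp`, `precision`, `recall`), `aupr`, and full-depth `tp`, `fp`, `fn`.
#' @export
gold_standard_eval <- function(coefficients, gold_standard,
                               absolute = FALSE) {
  gold_standard <- unique(gold_standard)
  if (length(gold_standard) == 0) abort("empty gold standard")
  coefficients <- coefficients[coefficients != 0]
  key <- if (absolute) abs(coefficients) else coefficients
  ord <- order(key, decreasing = TRUE)
  ranked <- names(coefficients)[ord]
  key <- key[ord]
  pos <- ranked %in% gold_standard
  n_pos <- length(gold_standard)

  if (length(ranked) == 0) {
    pts <- tibble(depth = integer(), tp = double(), fp = double(),
                  precision = double(), recall = double())
    return(structure(list(points = pts, aupr = 0, tp = 0, fp = 0,
                          fn = n_pos, absolute = absolute),
                     class = "regscore_pr"))
  }
  # tie groups: cumulative counts at the last member of each tied block
  grp_end <- unname(which(c(key[-1] != key[-length(key)], TRUE)))
  tp <- unname(cumsum(pos)[grp_end])
  fp <- grp_end - tp
  pts <- tibble(
    depth = grp_end, tp = as.double(tp), fp = as.double(fp),
    precision = tp / grp_end, recall = tp / n_pos)
  structure(
    list(points = pts,
         aupr = aupr_interpolated(pts$tp, pts$fp, n_pos),
         tp = sum(pos), fp = sum(!pos), fn = n_pos - sum(pos),
         absolute = absolute),
    class = "regscore_pr")
}

#' @export
print.regscore_pr <- function(x, ...) {
  cat(sprintf("<regscore_pr> AUPR %.4f  (TP %d, FP %d, FN %d; ranked by %s)\n",
              x$aupr, x$tp, x$fp, x$fn,
              if (x$absolute) "|coefficient|" else "signed coefficient"))
  invisible(x)
}

#' Gold standard from an expression table
#'
#' TFs whose gene can be found in the expression table at or above the
#' threshold (default 5, e.g. TPM) are considered true regulators.
#'
#' @param expression Expression tibble.
#' @param tfs Character vector of candidate TF names; each is looked up as
#'   a gene id in the table (unmappable TFs are treated as not expressed).
#' @param threshold Minimum expression.
#' @return A character vector of gold-standard TF names.
#' @export
gold_standard_from_expression <- function(expression, tfs, threshold = 5) {
  ex <- expression$expression[match(tfs, expression$gene_id)]
  ex[is.na(ex)] <- 0
  tfs[ex >= threshold]
}

#' Are the model's top regulators expressed?
#'
#' Maps the top-k TFs (by absolute coefficient, nonzero only) from a model
#' on original data and from its permuted-input counterpart to their
#' expression values (unmappable TFs count as 0) and compares the two
#' samples with a two-sided Wilcoxon rank-sum test. On sound data the
#' original model's picks should be markedly more expressed.
#'
#' @param coef_original,coef_permuted Named coefficient vectors.
#' @param expression Expression tibble.
#' @param k Number of top TFs (default 100). If fewer than `k` are selected
#'   on the original data, the same reduced number is drawn from the
#'   permuted model.
#' @return A list with `original` and `permuted` expression tibbles, the
#'   effective `k`, and `p_value`.
#' @export
expressed_top_tf_check <- function(coef_original, coef_permuted, expression,
                                   k = 100L) {
  if (k < 1) abort("k must be >= 1")
  top <- function(co, kk) {
    co <- co[co != 0]
    names(co)[order(abs(co), decreasing = TRUE)][seq_len(min(kk, length(co)))]
  }
  nz_orig <- sum(coef_original != 0)
  nz_perm <- sum(coef_permuted != 0)
  if (nz_orig == 0 || nz_perm == 0)
    abort("no nonzero coefficients in one of the models")
  k_eff <- min(k, nz_orig)
  lookup <- function(tfs) {
    ex <- expression$expression[match(tfs, expression$gene_id)]
    tibble(tf = tfs, expression = ifelse(is.na(ex), 0, ex))
  }
  orig <- lookup(top(coef_original, k_eff))
  perm <- lookup(top(coef_permuted, k_eff))
  p <- if (identical(orig$expression, perm$expression)) 1 else
    suppressWarnings(stats::wilcox.test(orig$expression, perm$expression,
                                        alternative = "two.sided"))$p.value
  list(original = orig, permuted = perm, k = k_eff, p_value = p)
}

#' Gene windows as plain intervals
#'
#' 0-based half-open windows of `params$window` bp centered at each gene's
#' most 5' TSS, for use with [overlap_fraction()].
#'
#' @inheritParams assign_windows
#' @return A tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
gene_windows <- function(genes, params = decay_params()) {
  half <- params$window / 2
  tss0 <- genes$tss - 1L
  tibble(chrom = genes$chrom,
         start = as.integer(tss0 - half), end = as.integer(tss0 + half),
         gene_id = genes$gene_id)
}

#' Fraction of peaks covered by a reference peak set
#'
#' Fraction of `query_peaks` having at least 1 bp overlap with any
#' `reference_peaks` interval; optionally the query is first restricted to
#' peaks overlapping any of the supplied gene windows (e.g. to ask how many
#' TSS-proximal ChIP peaks fall into open chromatin).
#'
#' @param query_peaks,reference_peaks Peak tibbles (0-based half-open).
#' @param windows Optional interval tibble from [gene_windows()].
#' @return A fraction in `[0, 1]` (`NaN` for an empty query).
#' @export
overlap_fraction <- function(query_peaks, reference_peaks, windows = NULL) {
  as_gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end))
  q <- as_gr(query_peaks)
  if (!is.null(windows)) {
    keep <- suppressWarnings(
      GenomicRanges::countOverlaps(q, as_gr(windows))) > 0
    q <- q[keep]
  }
  if (length(q) == 0) return(NaN)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(q, as_gr(reference_peaks)))
  mean(hits > 0)
}
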