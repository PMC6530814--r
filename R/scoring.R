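#' Distance-decay parameters for gene windows
#'
#' Peaks are collected in a window of `window` bp centered at each gene's
#' most 5' TSS and weighted by `exp(-d / d0)` where `d` is the distance of
#' the peak midpoint to the TSS. The defaults (50 kb window, `d0 = 5000`)
#' are the values commonly used for promoter-proximal TF-gene scoring.
#'
#' @param d0 Decay scale in bp; larger values flatten the weighting.
#' @param window Total window size in bp (the window spans
#'   `tss - window/2` to `tss + window/2`).
#' @return A `decay_params` list.
#' @export
decay_params <- function(d0 = 5000, window = 50000) {
  if (d0 <= 0) abort("d0 must be positive")
  if (window <= 0) abort("window must be positive")
  structure(list(d0 = d0, window = window), class = "decay_params")
}

#' Exponential distance decay weight
#'
#' @param d Distance(s) to the TSS in bp, `>= 0`.
#' @param params A [decay_params()] object.
#' @return `exp(-d / d0)`, in `(0, 1]`.
#' @export
decay_weight <- function(d, params = decay_params()) {
  if (any(d < 0)) abort("distance must be >= 0")
  exp(-d / params$d0)
}

#' Assign peaks to gene windows
#'
#' A peak is assigned to a gene when its interval overlaps the window
#' `[tss - window/2, tss + window/2)` around the gene's most 5' TSS by at
#' least one bp (any-overlap rule, so long peaks straddling the window
#' boundary are kept). The peak-TSS distance is
#' `|floor((start + end) / 2) - tss0|` with `tss0` the 0-based TSS.
#'
#' @param genes Gene tibble from [read_genes()].
#' @param peaks Peak tibble (0-based half-open); extra columns such as a
#'   `tf` label are carried through.
#' @param params A [decay_params()] object.
#' @return A tibble with one row per (gene, peak) assignment: `gene_id`,
#'   all peak columns, `distance` and the decay `weight`.
#' @export
assign_windows <- function(genes, peaks, params = decay_params()) {
  empty <- bind_cols(
    tibble(gene_id = character()),
    peaks[0, , drop = FALSE],
    tibble(distance = double(), weight = double())
  )
  if (nrow(genes) == 0 || nrow(peaks) == 0) return(empty)
  half <- params$window / 2
  tss0 <- genes$tss - 1L
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = tss0 - half + 1L, end = tss0 + half))
  pk <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, win))
  if (length(hits) == 0) return(empty)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  mid <- floor((peaks$start[pi] + peaks$end[pi]) / 2)
  d <- abs(mid - tss0[gi])
  bind_cols(
    tibble(gene_id = genes$gene_id[gi]),
    peaks[pi, , drop = FALSE],
    tibble(distance = as.double(d), weight = decay_weight(d, params))
  )
}

complete_wide <- function(long, genes, value_cols, feature_col = "tf") {
  # long: gene_id, <feature_col>, value; wide over all genes with 0 fill
  wide <- tidyr::pivot_wider(long, id_cols = "gene_id",
                             names_from = dplyr::all_of(feature_col),
                             values_from = "value", values_fill = 0,
                             names_sort = TRUE)
  out <- tibble(gene_id = genes$gene_id) |>
    left_join(wide, by = "gene_id")
  out[is.na(out)] <- 0
  # genes with no assignments at all
  for (cn in setdiff(value_cols, names(out))) out[[cn]] <- 0
  out[, c("gene_id", value_cols), drop = FALSE]
}

#' ChIP-seq TF-gene scores
#'
#' Aggregates per-TF ChIP peaks into gene-level features under the three
#' ChIP-based scoring variants:
#' \describe{
#'   \item{C}{`a_{g,t} = sum_p score_p * exp(-d/d0)` over the window peaks
#'     of TF `t` -- one column per TF.}
#'   \item{CN}{`a` divided per gene by the distance-weighted total peak
#'     count `c_g` (0 when `c_g = 0`), plus the aggregate columns
#'     `Peak_Count` (`c_g`) and `Peak_Length` (`l_g`, distance-weighted
#'     total peak length over all TFs).}
#'   \item{CPF}{only `Peak_Count` and `Peak_Length`.}
#' }
#' Every peak of every TF counts once in `c_g`/`l_g` (presence indicator,
#' independent of the score value).
#'
#' @param genes Gene tibble.
#' @param chip_peaks Peak tibble with an additional `tf` column naming the
#'   ChIP-ed factor of each peak.
#' @param params A [decay_params()] object.
#' @param variant `"C"`, `"CN"` or `"CPF"`.
#' @return A feature matrix tibble (`gene_id` + feature columns), tagged
#'   with the variant.
#' @export
score_chip <- function(genes, chip_peaks, params = decay_params(),
                       variant = c("C", "CN", "CPF")) {
  variant <- match.arg(variant)
  if (!"tf" %in% names(chip_peaks)) abort("chip_peaks needs a 'tf' column")
  check_unique_genes(genes$gene_id)
  asn <- assign_windows(genes, chip_peaks, params)
  tfs <- sort(unique(chip_peaks$tf))

  agg <- asn |>
    group_by(.data$gene_id) |>
    summarise(
      Peak_Count = sum(.data$weight),
      Peak_Length = sum((.data$end - .data$start) * .data$weight)
    )
  pf <- tibble(gene_id = genes$gene_id) |>
    left_join(agg, by = "gene_id") |>
    mutate(across(-"gene_id", ~ tidyr::replace_na(.x, 0)))

  if (variant == "CPF")
    return(set_variant(pf, "CPF"))

  a <- asn |>
    group_by(.data$gene_id, .data$tf) |>
    summarise(value = sum(.data$score * .data$weight), .groups = "drop") |>
    complete_wide(genes, tfs)

  if (variant == "C")
    return(set_variant(a, "C"))

  denom <- pf$Peak_Count
  if (any(denom < 0)) abort("negative peak count")
  scaled <- as.matrix(a[tfs]) / ifelse(denom > 0, denom, 1)
  scaled[denom == 0, ] <- 0
  out <- bind_cols(tibble(gene_id = a$gene_id), as_tibble(scaled),
                   pf[PEAK_FEATURE_COLS[1:2]])
  set_variant(out, "CN")
}

#' DNase (open chromatin) TF-gene scores
#'
#' Aggregates motif affinities in open-chromatin peaks into gene-level
#' features under the six DNase-based scoring variants:
#' \describe{
#'   \item{D}{`sum_p a_{p,t} * exp(-d/d0)` -- raw decay-weighted affinity.}
#'   \item{DS}{`sum_p a_{p,t} * s_p * exp(-d/d0)` -- affinity scaled by the
#'     per-peak accessibility signal `s_p`.}
#'   \item{DN}{affinities normalized per peak by the number of possible
#'     binding sites `max(|p| - |m| + 1, 1)` (with `|m|` the motif width),
#'     plus `Peak_Count` and `Peak_Length`.}
#'   \item{DSN}{as DN plus `Peak_Signal` (the decay-weighted total signal)
#'     as a separate feature.}
#'   \item{DPF}{`Peak_Count` and `Peak_Length` only.}
#'   \item{DPFS}{`Peak_Count`, `Peak_Length` and `Peak_Signal`.}
#' }
#' The aggregate columns are `Peak_Count = sum_p exp(-d/d0)`,
#' `Peak_Length = sum_p |p| exp(-d/d0)`,
#' `Peak_Signal = sum_p s_p exp(-d/d0)`.
#'
#' @param genes Gene tibble.
#' @param dnase_peaks Peak tibble; `signal` must be non-missing for the
#'   signal-aware variants (DS, DSN, DPFS).
#' @param affinities Long affinity table from [annotate_peaks()]; may be
#'   `NULL` for the affinity-free variants (DPF, DPFS).
#' @param params A [decay_params()] object.
#' @param variant One of `"D"`, `"DS"`, `"DN"`, `"DSN"`, `"DPF"`, `"DPFS"`.
#' @return A feature matrix tibble tagged with the variant.
#' @export
score_dnase <- function(genes, dnase_peaks, affinities = NULL,
                        params = decay_params(),
                        variant = c("D", "DS", "DN", "DSN", "DPF", "DPFS")) {
  variant <- match.arg(variant)
  check_unique_genes(genes$gene_id)
  needs_tf <- variant %in% c("D", "DS", "DN", "DSN")
  needs_signal <- variant %in% c("DS", "DSN", "DPFS")
  if (needs_signal && (!"signal" %in% names(dnase_peaks) ||
                       anyNA(dnase_peaks$signal)))
    abort(paste0("variant ", variant, " needs a per-peak signal"))
  asn <- assign_windows(genes, dnase_peaks, params)

  agg <- asn |>
    group_by(.data$gene_id) |>
    summarise(
      Peak_Count = sum(.data$weight),
      Peak_Length = sum((.data$end - .data$start) * .data$weight),
      Peak_Signal = if (needs_signal) sum(.data$signal * .data$weight)
                    else NA_real_
    )
  pf <- tibble(gene_id = genes$gene_id) |>
    left_join(agg, by = "gene_id") |>
    mutate(across(-"gene_id", ~ tidyr::replace_na(.x, 0)))

  if (variant == "DPF")
    return(set_variant(pf[c("gene_id", "Peak_Count", "Peak_Length")], "DPF"))
  if (variant == "DPFS")
    return(set_variant(pf, "DPFS"))

  if (is.null(affinities)) abort(paste0("variant ", variant,
                                        " needs an affinity table"))
  tfs <- sort(unique(affinities$tf))
  if (length(tfs) == 0 && nrow(asn) > 0)
    abort("affinity missing for an assigned peak")
  joined <- asn |>
    inner_join(affinities, by = c("chrom", "start", "end"),
               relationship = "many-to-many")
  n_expected <- nrow(asn) * length(tfs)
  if (nrow(joined) != n_expected)
    abort("affinity missing for an assigned peak")

  val <- switch(variant,
    D = joined$affinity * joined$weight,
    DS = joined$affinity * joined$signal * joined$weight,
    DN = ,
    DSN = joined$affinity /
      pmax(joined$end - joined$start - joined$motif_width + 1, 1) *
      joined$weight
  )
  a <- joined |>
    mutate(value = val) |>
    group_by(.data$gene_id, .data$tf) |>
    summarise(value = sum(.data$value), .groups = "drop") |>
    complete_wide(genes, tfs)

  out <- switch(variant,
    D = a,
    DS = a,
    DN = bind_cols(a, pf[c("Peak_Count", "Peak_Length")]),
    DSN = bind_cols(a, pf[PEAK_FEATURE_COLS])
  )
  set_variant(out, variant)
}

#' Align a feature matrix with an expression table into a model design
#'
#' Restricts both tables to their shared gene ids (sorted), applies
#' `log2(value + 1)` to every feature and to the expression response, and
#' returns a numeric design ready for [fit_evaluate()]. Centering and
#' scaling are deliberately left to the model fit, which standardizes per
#' training fold to avoid leakage.
#'
#' @param features Feature matrix tibble.
#' @param expression Expression tibble from [read_expression()].
#' @return A list with `x` (numeric matrix, genes in rownames), `y` (named
#'   response vector) and `genes`.
#' @export
build_design <- function(features, expression) {
  shared <- sort(intersect(features$gene_id, expression$gene_id))
  if (length(shared) == 0) abort("no shared gene ids")
  if (length(shared) < 2) abort("need at least 2 shared genes")
  x <- feature_matrix(features)[shared, , drop = FALSE]
  y <- expression$expression[match(shared, expression$gene_id)]
  list(x = log2(x + 1), y = stats::setNames(log2(y + 1), shared),
       genes = shared)
}
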