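#' Run the full scoring / permutation / modeling experiment
#'
#' Chains the framework end to end for one or more scoring variants:
#' obtain inputs (either generated by [generate_fixture()] or read from
#' files), build the gene-by-feature matrix, create its per-gene permuted
#' counterpart, fit the elastic-net expression model on both, and summarize
#' original-versus-permuted performance with a paired two-sided Wilcoxon
#' signed-rank test across outer folds. All intermediates are written under
#' `out_dir` together with `summary.json` and `manifest.json`.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   \describe{
#'     \item{fixture}{arguments for [fixture_config()], or}
#'     \item{inputs}{paths: `genes` (GTF), `dnase_peaks` (narrowPeak),
#'       `genome` (FASTA), `psems`, `chip_manifest`, `expression`.}
#'     \item{variants}{character vector of scoring variants (default
#'       `c("D", "DN")`).}
#'     \item{model}{arguments for [model_config()].}
#'     \item{permutation}{`seed` and `scope` (`"auto"` picks
#'       `tf_columns_only` when aggregate columns are present, otherwise
#'       `all_columns`).}
#'     \item{out_dir}{output directory (default `tempfile()`).}
#'   }
#' @return Invisibly, a list with per-variant fits and the summary (also
#'   written to `summary.json`).
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  out_dir <- config$out_dir %||% tempfile("regscore_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  variants <- config$variants %||% c("D", "DN")
  bad <- setdiff(variants, VARIANTS)
  if (length(bad) > 0) abort(paste0("unknown variant: ", bad[1]))
  mc <- do.call(model_config, config$model %||% list())
  perm_seed <- config$permutation$seed %||% (mc$seed + 1L)
  perm_scope <- config$permutation$scope %||% "auto"

  inputs <- load_inputs(config, out_dir)
  need_aff <- any(variants %in% c("D", "DS", "DN", "DSN"))
  if (need_aff && is.null(inputs$affinities)) {
    message("* computing peak affinities")
    inputs$affinities <- annotate_peaks(inputs$dnase_peaks, inputs$genome,
                                        inputs$psems)
  }

  fits <- list()
  rows <- list()
  artifacts <- character()
  for (v in variants) {
    message("* variant ", v)
    feats <- if (v %in% c("C", "CN", "CPF")) {
      if (is.null(inputs$chip_peaks))
        abort(paste0("variant ", v, " needs ChIP peaks"))
      score_chip(inputs$genes, inputs$chip_peaks, inputs$params, v)
    } else {
      score_dnase(inputs$genes, inputs$dnase_peaks, inputs$affinities,
                  inputs$params, v)
    }
    scope <- if (perm_scope != "auto") perm_scope
             else if (any(PEAK_FEATURE_COLS %in% names(feats)) &&
                      length(tf_columns(feats)) > 0) "tf_columns_only"
             else "all_columns"
    perm <- permute_rows(feats, permutation_scheme(perm_seed, scope))

    fo <- file.path(out_dir, paste0("features_", v, ".tsv"))
    fp <- file.path(out_dir, paste0("features_", v, "_permuted.tsv"))
    write_feature_matrix(feats, fo)
    write_feature_matrix(perm, fp)
    artifacts <- c(artifacts, fo, fp)

    fit_o <- fit_expression_model(feats, inputs$expression, mc)
    fit_p <- fit_expression_model(perm, inputs$expression, mc)
    co <- file.path(out_dir, paste0("coefficients_", v, ".tsv"))
    readr::write_tsv(fit_o$coefficients, co)
    artifacts <- c(artifacts, co)
    fits[[v]] <- list(original = fit_o, permuted = fit_p,
                      features = feats, permuted_features = perm)

    wp <- stats::wilcox.test(fit_o$folds$spearman, fit_p$folds$spearman,
                             paired = TRUE, alternative = "two.sided",
                             exact = FALSE)$p.value
    rows[[v]] <- tibble(
      variant = v, scope = scope,
      mean_spearman_original = mean(fit_o$folds$spearman),
      sd_spearman_original = stats::sd(fit_o$folds$spearman),
      mean_spearman_permuted = mean(fit_p$folds$spearman),
      sd_spearman_permuted = stats::sd(fit_p$folds$spearman),
      mean_nonzero_original = mean(fit_o$folds$n_nonzero),
      mean_nonzero_permuted = mean(fit_p$folds$n_nonzero),
      wilcoxon_p = wp)
  }
  summary_tbl <- bind_rows(rows)
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_tbl, sj, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(out_dir = out_dir, variants = variants,
         artifacts = basename(c(artifacts, sj))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(list(summary = summary_tbl, fits = fits, out_dir = out_dir,
                 inputs = inputs))
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

load_inputs <- function(config, out_dir) {
  if (!is.null(config$inputs)) {
    p <- config$inputs
    genes <- read_genes(p$genes)
    dnase <- if (!is.null(p$dnase_peaks))
      read_peaks(p$dnase_peaks, "narrowPeak") else NULL
    chip <- if (!is.null(p$chip_manifest))
      read_chip_manifest(p$chip_manifest) else NULL
    psems <- if (!is.null(p$psems)) read_psem(p$psems) else NULL
    genome <- p$genome
    expression <- read_expression(p$expression)
    params <- decay_params(d0 = config$d0 %||% 5000,
                           window = config$window %||% 50000)
    list(genes = genes, dnase_peaks = dnase, chip_peaks = chip,
         psems = psems, genome = genome, expression = expression,
         affinities = NULL, params = params)
  } else {
    fc <- do.call(fixture_config, config$fixture %||% list())
    message("* generating fixture (seed ", fc$seed, ")")
    fx <- generate_fixture(fc)
    fx[c("genes", "dnase_peaks", "chip_peaks", "psems", "genome",
         "expression", "affinities", "params", "ground_truth")]
  }
}
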