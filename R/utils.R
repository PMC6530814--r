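#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp sourceCpp
#' @useDynLib regscore, .registration = TRUE
NULL

# Reserved aggregate (peak-feature) column names; everything else in a
# feature matrix is a TF column.
PEAK_FEATURE_COLS <- c("Peak_Count", "Peak_Length", "Peak_Signal")

VARIANTS <- c("C", "CN", "CPF", "D", "DS", "DN", "DSN", "DPF", "DPFS")

#' TF columns of a feature matrix
#'
#' Feature matrices mix per-TF columns with up to three aggregate
#' peak-feature columns (`Peak_Count`, `Peak_Length`, `Peak_Signal`).
#' This returns the names of the TF columns only.
#'
#' @param features A feature matrix tibble (first column `gene_id`).
#' @return Character vector of TF column names.
#' @export
tf_columns <- function(features) {
  setdiff(names(features), c("gene_id", PEAK_FEATURE_COLS))
}

#' Scoring variant tag of a feature matrix
#'
#' @param features A feature matrix tibble.
#' @return The variant string (e.g. `"DN"`), or `NA` if untagged.
#' @export
variant_of <- function(features) {
  attr(features, "variant") %||% NA_character_
}

set_variant <- function(features, variant) {
  attr(features, "variant") <- variant
  features
}

# Feature tibble (gene_id + numeric columns) -> numeric matrix with
# gene_id rownames.
feature_matrix <- function(features) {
  stopifnot("gene_id" %in% names(features))
  m <- as.matrix(features[setdiff(names(features), "gene_id")])
  rownames(m) <- features$gene_id
  storage.mode(m) <- "double"
  m
}

check_unique_genes <- function(ids, what = "gene ids") {
  if (anyDuplicated(ids))
    abort(paste0("duplicate ", what, ": ",
                 paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
  invisible(ids)
}
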