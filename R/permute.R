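#' Per-gene permutation scheme
#'
#' Row-wise shuffling destroys TF identity while preserving every per-gene
#' (row-level) property of the scores -- the diagnostic null used to expose
#' confounders shared by all features of a gene. With scope
#' `"tf_columns_only"` the aggregate peak-feature columns (`Peak_Count`,
#' `Peak_Length`, `Peak_Signal`) are left untouched and only TF columns are
#' shuffled within each row; `"all_columns"` shuffles every feature column.
#'
#' @param seed Integer seed; the permutation is deterministic given it.
#' @param scope `"tf_columns_only"` or `"all_columns"`.
#' @return A `permutation_scheme` list.
#' @export
permutation_scheme <- function(seed = 1L,
                               scope = c("tf_columns_only", "all_columns")) {
  structure(list(seed = as.integer(seed), scope = match.arg(scope)),
            class = "permutation_scheme")
}

#' Row-wise permutation of a feature matrix
#'
#' For each gene (row) independently, the in-scope values are replaced by a
#' uniformly random permutation of themselves. Row sums, minima, maxima and
#' multisets are exactly conserved; column marginals in general are not.
#'
#' @param features Feature matrix tibble.
#' @param scheme A [permutation_scheme()].
#' @return The permuted feature matrix, same shape and column names, same
#'   variant tag.
#' @export
permute_rows <- function(features, scheme = permutation_scheme()) {
  if (nrow(features) == 0) abort("empty feature matrix")
  cols <- if (scheme$scope == "tf_columns_only") tf_columns(features)
          else setdiff(names(features), "gene_id")
  if (length(cols) == 0) abort("no columns in permutation scope")
  m <- as.matrix(features[cols])
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(scheme$seed)
  for (i in seq_len(nrow(m)))
    m[i, ] <- m[i, sample.int(ncol(m))]
  out <- features
  out[cols] <- as_tibble(m)
  set_variant(out, variant_of(features))
}
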