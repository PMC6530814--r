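#' Read peak calls from narrowPeak or BED files
#'
#' Peaks are returned in 0-based half-open coordinates, as stored in both
#' formats. For narrowPeak, column 5 is the peak score (the ChIP peak score
#' used by the ChIP-based gene scores) and column 7 (signalValue) is the
#' accessibility signal used by the signal-aware DNase variants. For plain
#' BED, column 5 (when present) is the score and the signal is `NA`.
#'
#' @param path Path to a tab-separated peak file. Lines starting with `#`
#'   are ignored.
#' @param format `"narrowPeak"` or `"bed"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `signal`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), signal = double()))
  if (ncol(df) < 3) abort("peak file needs >= 3 tab-separated columns")

  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != ".")
    if (length(bad) > 0)
      abort(sprintf("malformed %s at line %d: '%s'", col, bad[1], x[bad[1]]))
    v
  }
  start <- num(df[[2]], "start")
  end <- num(df[[3]], "end")
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) abort(sprintf("missing coordinates at line %d", bad[1]))
  bad <- which(start >= end)
  if (length(bad) > 0)
    abort(sprintf("start >= end at line %d (%s:%s-%s)", bad[1],
                  df[[1]][bad[1]], start[bad[1]], end[bad[1]]))

  name <- if (ncol(df) >= 4) df[[4]] else NA_character_
  score <- if (ncol(df) >= 5) num(df[[5]], "score") else 0
  score <- ifelse(is.na(score), 0, score)
  signal <- if (format == "narrowPeak" && ncol(df) >= 7)
    num(df[[7]], "signalValue") else NA_real_
  if (any(score < 0, na.rm = TRUE)) abort("negative peak score")
  if (any(signal < 0, na.rm = TRUE)) abort("negative signalValue")

  tibble(chrom = df[[1]], start = as.integer(start), end = as.integer(end),
         name = name, score = as.double(score), signal = as.double(signal))
}

#' Read gene models from a GTF file
#'
#' Each gene is reduced to a single representative transcription start
#' site: the most 5' transcript start across all of its transcripts
#' (minimum start on the + strand, maximum end on the - strand). Genes
#' without transcript records fall back to their remaining records (e.g.
#' the gene line itself). GTF coordinates are 1-based inclusive; the
#' returned `tss` is a 1-based position.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  gene_id <- as.character(md$gene_id)
  if (is.null(md$gene_id)) gene_id <- rep(NA_character_, length(gr))
  keep <- !is.na(gene_id) & gene_id != ""
  if (any(!keep)) {
    warn(sprintf("skipping %d record(s) without gene_id", sum(!keep)))
    gr <- gr[keep]
    gene_id <- gene_id[keep]
  }
  if (length(gr) == 0)
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tss = integer()))

  type <- as.character(S4Vectors::mcols(gr)$type)
  recs <- tibble(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    is_tx = !is.na(type) & type %in% c("transcript", "mRNA")
  )
  bad_strand <- recs |>
    group_by(.data$gene_id) |>
    summarise(n_strands = dplyr::n_distinct(.data$strand)) |>
    filter(.data$n_strands > 1)
  if (nrow(bad_strand) > 0)
    abort(paste0("gene on conflicting strands: ", bad_strand$gene_id[1]))

  recs |>
    group_by(.data$gene_id) |>
    filter(if (any(.data$is_tx)) .data$is_tx else TRUE) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      tss = if (.data$strand[1] == "-") max(.data$end) else min(.data$start)
    ) |>
    ungroup() |>
    mutate(tss = as.integer(.data$tss))
}

#' Read position-specific energy matrices (PSEMs)
#'
#' The file holds one record per matrix: a header line
#' `>NAME [lambda=<x>] [ln_r0=<x>]` followed by one row of four
#' tab/space-separated non-negative mismatch energies (A C G T) per motif
#' position. When the header omits the binding parameters, the reference
#' TRAP defaults are used: `lambda = 0.7` and
#' `ln_r0 = 0.584 * width - 5.66`.
#'
#' @param path Path to a PSEM text file. `#` lines are comments.
#' @return A named list of `psem` objects (fields `tf_name`, `width`,
#'   `energies`, `lambda`, `ln_r0`).
#' @export
read_psem <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) return(structure(list(), names = character()))
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0 || starts[1] != 1)
    abort("PSEM file must start with a '>' header line")
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>", "", lines[bounds[i]])
    toks <- strsplit(header, "[ \t]+")[[1]]
    tf_name <- toks[1]
    if (is.na(tf_name) || tf_name == "") abort("PSEM header without a name")
    kv <- toks[-1][grepl("=", toks[-1])]
    opts <- stats::setNames(
      as.numeric(sub(".*=", "", kv)),
      sub("=.*", "", kv)
    )
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) < 1) abort(paste0("PSEM '", tf_name, "' has no rows"))
    rows <- lapply(body, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[ \t]+")[[1]]))
      if (length(v) != 4 || anyNA(v))
        abort(paste0("PSEM '", tf_name, "': row must hold 4 numbers: ", l))
      if (any(v < 0))
        abort(paste0("PSEM '", tf_name, "': negative energy"))
      v
    })
    energies <- do.call(rbind, rows)
    colnames(energies) <- c("A", "C", "G", "T")
    width <- nrow(energies)
    out[[i]] <- new_psem(
      tf_name, energies,
      lambda = unname(opts["lambda"] %|na|% 0.7),
      ln_r0 = unname(opts["ln_r0"] %|na|% (0.584 * width - 5.66))
    )
  }
  stats::setNames(out, vapply(out, function(p) p$tf_name, character(1)))
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

new_psem <- function(tf_name, energies, lambda, ln_r0) {
  stopifnot(ncol(energies) == 4, nrow(energies) >= 1, all(energies >= 0),
            lambda > 0)
  structure(
    list(tf_name = tf_name, width = nrow(energies), energies = energies,
         lambda = lambda, ln_r0 = ln_r0),
    class = "psem"
  )
}

#' @export
print.psem <- function(x, ...) {
  cat(sprintf("<psem> %s  width=%d  lambda=%g  ln_r0=%g\n",
              x$tf_name, x$width, x$lambda, x$ln_r0))
  invisible(x)
}

#' Write PSEMs in the text format read by [read_psem()]
#'
#' @param psems A list of `psem` objects.
#' @param path Output path.
#' @export
write_psem <- function(psems, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in psems) {
    writeLines(sprintf(">%s lambda=%.15g ln_r0=%.15g",
                       p$tf_name, p$lambda, p$ln_r0), con)
    utils::write.table(format(p$energies, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column expression table
#'
#' @param path TSV with columns gene id and expression value (e.g. TPM).
#'   A header line is detected and skipped automatically.
#' @return A tibble with columns `gene_id`, `expression`.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2) abort("expression table needs 2 columns")
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df[[2]][1]))))
    df <- df[-1, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(vals)) abort("non-numeric expression value")
  if (any(vals < 0)) abort("negative expression value")
  check_unique_genes(df[[1]])
  tibble(gene_id = df[[1]], expression = vals)
}

#' Write / read a gene-by-feature matrix as TSV
#'
#' The scoring variant tag travels in a `# variant=<tag>` comment line so
#' that matrices can be re-loaded without losing their provenance.
#'
#' @param features Feature matrix tibble (first column `gene_id`).
#' @param path Output path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the tibble with its variant attribute
#'   restored.
#' @export
write_feature_matrix <- function(features, path) {
  feats <- names(features)[names(features) != "gene_id"]
  if (anyDuplicated(feats))
    abort("duplicate feature names in matrix")
  con <- file(path, "w")
  on.exit(close(con))
  v <- variant_of(features)
  if (!is.na(v)) writeLines(paste0("# variant=", v), con)
  writeLines(paste(c("gene_id", feats), collapse = "\t"), con)
  m <- feature_matrix(features)
  fmt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  body <- apply(fmt, 1, paste, collapse = "\t")
  writeLines(paste(features$gene_id, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, n = 10)
  variant <- NA_character_
  vline <- grep("^# variant=", lines, value = TRUE)
  if (length(vline) > 0) variant <- sub("^# variant=", "", vline[1])
  header <- grep("^[^#]", lines, value = TRUE)[1]
  cols <- strsplit(header, "\t")[[1]]
  if (anyDuplicated(cols)) abort("duplicate column in feature matrix file")
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(
                          gene_id = "c", .default = "d"),
                        progress = FALSE)
  set_variant(as_tibble(df), variant)
}
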