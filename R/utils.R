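#' Derive a stage-specific RNG seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a 31-bit integer
#' seed, so each pipeline stage draws from an independent, reproducible
#' stream. The derivation is a splitmix-style integer hash of the master seed
#' combined with a character hash of the label; all arithmetic stays below
#' 2^53 so it is exact in double precision.
#'
#' @param master integer master seed.
#' @param stage character label of the stage (e.g. "counts", "permutation").
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- (abs(master) %% 2147483647)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  # splitmix-like scrambling round (kept within exact-double range)
  h <- (h * 2654435761) %% 2147483647
  h <- (h * 40503 + 30269) %% 2147483647
  as.integer(h)
}

#' Read a feature-by-sample count table
#'
#' First column holds feature identifiers, remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a feature-by-sample count table
#'
#' @param counts integer matrix with rownames (features) and colnames
#'   (samples).
#' @param path output TSV path.
#' @param id_col name for the feature id column.
#' @export
write_counts_tsv <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `time_h`, `replicate`.
#'
#' @param path TSV file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "replicate")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "))
  md$time_h <- as.numeric(md$time_h)
  md$replicate <- as.integer(md$replicate)
  md
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
check_counts_meta <- function(counts, meta) {
  if (is.null(colnames(counts))) stop("count matrix must have sample colnames")
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("samples without metadata: ",
         paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "))
  meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
}
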