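#' Reads-per-million-mapped (RPMM) normalization
#'
#' Scales each sample column so it sums to one million.
#'
#' @param counts miRNA x sample count matrix.
#' @return RPMM matrix with the same dimnames.
#' @export
rpmm_normalize <- function(counts) {
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, tot, `/`) * 1e6
}

#' Filter expressed miRNAs
#'
#' Keeps miRNAs whose mean RPMM across all samples is at least `min_mean`.
#'
#' @param rpmm RPMM matrix from [rpmm_normalize()].
#' @param min_mean expression threshold (default 50 RPMM).
#' @return character vector of retained miRNA ids.
#' @export
filter_expressed <- function(rpmm, min_mean = 50) {
  rownames(rpmm)[rowMeans(rpmm) >= min_mean]
}

#' Fold change of each miRNA versus the time-zero mean
#'
#' Expression at each timepoint (mean over replicates) divided by the mean
#' of the time-zero replicates. A pseudocount replaces a zero denominator or
#' numerator mean so fold changes stay finite and positive.
#'
#' @param rpmm RPMM matrix.
#' @param meta sample metadata.
#' @param pseudocount RPMM value substituted for zero group means.
#' @return miRNA x timepoint matrix of fold changes (timepoint 0 column is
#'   identically 1).
#' @export
fold_change_vs_t0 <- function(rpmm, meta, pseudocount = 1) {
  meta <- check_counts_meta(rpmm, meta)
  if (!any(meta$time_h == 0)) stop("time-zero replicates are required")
  tps <- sort(unique(meta$time_h))
  gm <- matrix(NA_real_, nrow(rpmm), length(tps),
               dimnames = list(rownames(rpmm), as.character(tps)))
  for (j in seq_along(tps))
    gm[, j] <- rowMeans(rpmm[, meta$time_h == tps[j], drop = FALSE])
  base <- gm[, "0"]
  base[base == 0] <- pseudocount
  gm[gm == 0] <- pseudocount
  sweep(gm, 1, base, `/`)
}

#' Identify estrogen-responsive miRNAs
#'
#' Per miRNA and timepoint, a Welch two-sample t-test compares replicate
#' RPMM values at `t` against time zero (pooled-variance t optional). A
#' miRNA is responsive at threshold `theta` when some timepoint shows a fold
#' change of at least `theta` (or at most `1/theta`) with uncorrected
#' p <= `alpha`; no multiple-testing correction is applied.
#'
#' @param rpmm RPMM matrix.
#' @param meta sample metadata.
#' @param thresholds fold-change thresholds flagged (default 1.5 and 2).
#' @param alpha uncorrected p-value threshold.
#' @param min_mean expression filter passed to [filter_expressed()].
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param pseudocount see [fold_change_vs_t0()].
#' @return list of class `mirna_response`: `table` (mirna x timepoint rows
#'   with `fc`, `p`), `fold_change` matrix, `expressed`, and responsive id
#'   sets `responsive_1p5`, `responsive_2` (named after the default
#'   thresholds; one entry per threshold in `thresholds`).
#' @export
test_mirna_response <- function(rpmm, meta, thresholds = c(1.5, 2),
                                alpha = 0.05, min_mean = 50,
                                var_equal = FALSE, pseudocount = 1) {
  meta <- check_counts_meta(rpmm, meta)
  if (min(table(meta$time_h)) < 2) stop("need >= 2 replicates per timepoint")
  expressed <- filter_expressed(rpmm, min_mean)
  fc <- fold_change_vs_t0(rpmm, meta, pseudocount)
  tps <- sort(unique(meta$time_h))
  tps <- tps[tps > 0]
  x0 <- rpmm[, meta$time_h == 0, drop = FALSE]
  rows <- list()
  for (t in tps) {
    xt <- rpmm[, meta$time_h == t, drop = FALSE]
    p <- vapply(seq_len(nrow(rpmm)), function(i) {
      a <- xt[i, ]; b <- x0[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      }
      tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
               error = function(e) 1)
    }, numeric(1))
    rows[[as.character(t)]] <- data.frame(
      mirna = rownames(rpmm), time_h = t, fc = fc[, as.character(t)],
      p = p, row.names = NULL, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  resp_at <- function(theta) {
    hit <- tab$p <= alpha & (tab$fc >= theta | tab$fc <= 1 / theta) &
      tab$mirna %in% expressed
    sort(unique(tab$mirna[hit]))
  }
  resp <- lapply(thresholds, resp_at)
  names(resp) <- paste0("responsive_", sub("\\.", "p", as.character(thresholds)))
  out <- c(list(table = tab, fold_change = fc, expressed = expressed), resp)
  class(out) <- "mirna_response"
  out
}
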