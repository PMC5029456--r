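#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' strictly positive counts in every sample, of the ratio of each count to
#' the gene's geometric mean across samples. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts integer gene x sample matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in all samples; prefilter the matrix")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  f <- exp(apply(lc - geo, 2, stats::median))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts gene x sample matrix.
#' @param factors per-sample positive factors (e.g. from [size_factors()]).
#' @return matrix of normalized counts `count / factor`.
#' @export
normalize_counts <- function(counts, factors) {
  if (any(factors <= 0)) stop("size factors must be positive")
  if (length(factors) != ncol(counts))
    stop("need one size factor per sample")
  sweep(counts, 2, factors, `/`)
}

#' Method-of-moments NB dispersion per gene
#'
#' Estimates the dispersion alpha of `Var = mu + alpha * mu^2` as
#' `max(floor, (pooled within-group variance - mean) / mean^2)`, pooling the
#' within-group variance across all timepoint groups.
#'
#' @param normalized normalized gene x sample matrix.
#' @param groups factor/vector assigning each sample to a group (timepoint).
#' @param floor lower bound for the estimate.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(normalized, groups, floor = 1e-8) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs >= 2 replicates")
  ss <- 0
  for (g in levels(groups)) {
    sub <- normalized[, groups == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ss / (ncol(normalized) - nlevels(groups))
  m <- rowMeans(normalized)
  a <- ifelse(m > 0, (s2 - m) / m^2, 0)
  stats::setNames(pmax(floor, a), rownames(normalized))
}

#' NB Wald test of one timepoint against time zero
#'
#' For each gene, compares the mean normalized expression of the samples at
#' time `t` with the time-zero samples using a Wald statistic whose standard
#' error comes from the NB variance function evaluated at the pooled
#' (null) mean: `SE^2 = (m + alpha * m^2) * (1/n0 + 1/nt)`. The fold change
#' is `log2((mean_t + c) / (mean_0 + c))` with pseudocount `c`.
#'
#' @param normalized normalized gene x sample matrix.
#' @param meta sample metadata (`sample_id`, `time_h`, `replicate`).
#' @param dispersions per-gene NB dispersion (see [estimate_dispersion()]).
#' @param t timepoint (hours) to test against 0.
#' @param pseudocount added to both group means in the fold change.
#' @return data.frame with columns `gene`, `time_h`, `log2fc`, `p_raw`.
#' @export
test_vs_t0 <- function(normalized, meta, dispersions, t, pseudocount = 0.5) {
  meta <- check_counts_meta(normalized, meta)
  i0 <- meta$time_h == 0
  it <- meta$time_h == t
  if (sum(i0) < 2 || sum(it) < 2)
    stop("need >= 2 replicates at time 0 and time ", t)
  m0 <- rowMeans(normalized[, i0, drop = FALSE])
  mt <- rowMeans(normalized[, it, drop = FALSE])
  mp <- rowMeans(normalized[, i0 | it, drop = FALSE])
  a <- dispersions[rownames(normalized)]
  se <- sqrt((mp + a * mp^2) * (1 / sum(i0) + 1 / sum(it)))
  z <- ifelse(se > 0, (mt - m0) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  lfc <- log2((mt + pseudocount) / (m0 + pseudocount))
  dead <- m0 == 0 & mt == 0
  p[dead] <- 1
  lfc[dead] <- 0
  data.frame(gene = rownames(normalized), time_h = t, log2fc = lfc,
             p_raw = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of one vector of raw p-values (one timepoint
#' contrast).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, elementwise `>= p` and bounded by 1.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression table versus time zero
#'
#' Runs [size_factors()], [estimate_dispersion()] (with light moderation of
#' the per-gene estimates toward the across-gene median, stabilizing the
#' Wald standard errors at 3 replicates) and [test_vs_t0()] for every
#' timepoint `t > 0`, adjusting p-values within each timepoint contrast.
#'
#' @param counts raw integer gene x sample matrix.
#' @param meta sample metadata.
#' @param pseudocount fold-change pseudocount (normalized counts).
#' @param moderation weight of the per-gene dispersion estimate; `1 - w`
#'   goes to the across-gene median.
#' @return list of class `de_result` with `table` (gene x timepoint rows:
#'   `log2fc`, `p_raw`, `p_adj`), `mean_norm_expr` (per gene),
#'   `normalized`, `size_factors`, `dispersions`, `timepoints`.
#' @export
de_table <- function(counts, meta, pseudocount = 0.5, moderation = 0.3) {
  meta <- check_counts_meta(counts, meta)
  if (sum(meta$time_h == 0) < 2) stop("need >= 2 replicates at time 0")
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  disp <- estimate_dispersion(norm, meta$time_h)
  disp <- moderation * disp + (1 - moderation) * stats::median(disp)
  tps <- sort(unique(meta$time_h))
  tps <- tps[tps > 0]
  tabs <- lapply(tps, function(t) {
    d <- test_vs_t0(norm, meta, disp, t, pseudocount)
    d$p_adj <- adjust_bh(d$p_raw)
    d
  })
  out <- list(table = do.call(rbind, tabs),
              mean_norm_expr = rowMeans(norm),
              normalized = norm,
              size_factors = sf,
              dispersions = disp,
              timepoints = tps)
  class(out) <- "de_result"
  out
}

#' Select estrogen-responsive genes
#'
#' A gene is responsive when its mean normalized expression across the whole
#' series is at least `min_mean` and it shows a significant (BH-adjusted
#' p < `alpha`) change of at least `min_abs_log2fc` in magnitude versus time
#' zero at one or more timepoints.
#'
#' @param de a `de_result` from [de_table()].
#' @param min_mean minimum mean normalized expression across all samples.
#' @param min_abs_log2fc minimum |log2 fold change| (1 = twofold).
#' @param alpha adjusted p-value threshold.
#' @return data.frame of class `responsive_set` with columns `gene` and
#'   `n_timepoints_2fold` (number of timepoints with a significant change of
#'   at least the magnitude threshold).
#' @export
select_responsive_genes <- function(de, min_mean = 500, min_abs_log2fc = 1,
                                    alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$table
  hit <- tab$p_adj < alpha & abs(tab$log2fc) >= min_abs_log2fc
  n_hit <- tapply(hit, tab$gene, sum)
  genes <- names(n_hit)[n_hit >= 1]
  genes <- genes[de$mean_norm_expr[genes] >= min_mean]
  out <- data.frame(gene = sort(genes),
                    n_timepoints_2fold = as.integer(n_hit[sort(genes)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("responsive_set", class(out))
  out
}

#' Timepoint census of responsive genes
#'
#' For each responsive gene, counts the timepoints at which it reaches a
#' significant change of at least the magnitude threshold, and tabulates the
#' histogram of those counts (optionally broken down by temporal class).
#'
#' @param de a `de_result`.
#' @param responsive a `responsive_set` from [select_responsive_genes()].
#' @param classes optional named vector gene -> class label for a per-class
#'   breakdown.
#' @param min_abs_log2fc,alpha thresholds as in [select_responsive_genes()].
#' @return list with `per_gene` (named counts), `histogram` (table over
#'   1..n timepoints) and, if classes were given, `by_class`.
#' @export
census_timepoints <- function(de, responsive, classes = NULL,
                              min_abs_log2fc = 1, alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  if (nrow(responsive) == 0) stop("responsive set is empty")
  tab <- de$table[de$table$gene %in% responsive$gene, ]
  hit <- tab$p_adj < alpha & abs(tab$log2fc) >= min_abs_log2fc
  per_gene <- tapply(hit, tab$gene, sum)
  per_gene <- per_gene[responsive$gene]
  lev <- seq_along(de$timepoints)
  histo <- table(factor(per_gene, levels = lev))
  out <- list(per_gene = per_gene, histogram = histo)
  if (!is.null(classes)) {
    cl <- classes[names(per_gene)]
    out$by_class <- tapply(per_gene, cl, function(x)
      table(factor(x, levels = lev)))
  }
  out
}
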