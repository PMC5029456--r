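#' Shape-preserving interpolation of a temporal profile
#'
#' Piecewise cubic Hermite interpolating polynomial (PCHIP) evaluation on a
#' grid. The interpolant passes exactly through the observed values and does
#' not overshoot local data extremes between knots.
#'
#' @param times observed timepoints (strictly increasing).
#' @param values observed values.
#' @param grid evaluation grid within `[min(times), max(times)]`.
#' @return interpolated values on `grid`.
#' @export
interpolate_profile <- function(times, values, grid = seq(0, 24, by = 1)) {
  if (length(times) < 2) stop("need at least 2 observed timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values contain NaN/NA")
  if (min(grid) < min(times) || max(grid) > max(times))
    stop("grid must lie within the observed time range")
  pracma::pchip(times, values, grid)
}

#' Per-gene temporal profiles for clustering
#'
#' Builds the clustered signal: the replicate-mean log2 fold change of each
#' gene versus time zero, standardized to unit maximum absolute value per
#' gene, then PCHIP-interpolated onto a uniform hourly grid. The
#' unstandardized fold-change-scale trajectories (baseline 1 at t = 0) are
#' kept for class labeling.
#'
#' @param normalized normalized gene x sample expression matrix.
#' @param meta sample metadata.
#' @param genes genes to profile (default all rows).
#' @param grid interpolation grid (hours).
#' @param pseudocount fold-change pseudocount.
#' @return list of class `temporal_profiles` with `signal` (standardized
#'   interpolated gene x grid matrix), `fold` (interpolated fold-change
#'   scale), `log2fc` (observed gene x timepoint), `grid`, `timepoints`.
#' @export
temporal_profiles <- function(normalized, meta, genes = rownames(normalized),
                              grid = seq(0, 24, by = 1), pseudocount = 0.5) {
  meta <- check_counts_meta(normalized, meta)
  tps <- sort(unique(meta$time_h))
  gm <- matrix(NA_real_, length(genes), length(tps),
               dimnames = list(genes, as.character(tps)))
  for (j in seq_along(tps))
    gm[, j] <- rowMeans(normalized[genes, meta$time_h == tps[j],
                                   drop = FALSE])
  lfc <- log2(sweep(gm + pseudocount, 1, gm[, "0"] + pseudocount, `/`))
  scale <- apply(abs(lfc), 1, max)
  scale[scale == 0] <- 1
  std <- sweep(lfc, 1, scale, `/`)
  interp <- function(m) t(apply(m, 1, function(r)
    interpolate_profile(tps, r, grid)))
  signal <- interp(std)
  fold <- interp(2^lfc)
  colnames(signal) <- colnames(fold) <- as.character(grid)
  out <- list(signal = signal, fold = fold, log2fc = lfc, grid = grid,
              timepoints = tps)
  class(out) <- "temporal_profiles"
  out
}

#' Hierarchical clustering of wavelet feature vectors
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by
#' default) of per-gene wavelet coefficient vectors, cut into exactly `k`
#' clusters.
#'
#' @param features gene x coefficient matrix (see [wavelet_features()]).
#' @param k number of clusters.
#' @param linkage linkage passed to [stats::hclust()].
#' @return list of class `cluster_assignment` with `cluster` (named integer
#'   vector), `tree` (the hclust object) and `k`.
#' @export
cluster_profiles <- function(features, k = 3, linkage = "ward.D2") {
  if (nrow(features) < k) stop("fewer genes than clusters requested")
  hc <- stats::hclust(stats::dist(features), method = linkage)
  cl <- stats::cutree(hc, k = k)
  # canonical cluster numbering: by first gene id in each cluster, so the
  # partition is invariant to input row order
  ord <- order(vapply(seq_len(k), function(i)
    min(rownames(features)[cl == i]), character(1)))
  relab <- match(cl, ord)
  out <- list(cluster = stats::setNames(relab, rownames(features)),
              tree = hc, k = k)
  class(out) <- "cluster_assignment"
  out
}

#' Label clusters as transient / induced / repressed
#'
#' Each cluster centroid (mean fold-change-scale trajectory on the grid) is
#' summarized by its start `b`, end `f` and maximum `m`. A centroid is
#' `repressed` when `f < b * (1 - delta)`, `transient` when
#' `m > max(b, f) * (1 + delta)` (and not repressed), `induced` otherwise.
#' If the heuristic does not yield three distinct labels, labels are
#' assigned by ranking: lowest `f / b` is repressed, largest peak excess
#' `m - max(b, f)` among the rest is transient, the remainder induced.
#'
#' @param assignment a `cluster_assignment` with `k = 3`.
#' @param profiles a `temporal_profiles` object for the same genes.
#' @param delta relative tolerance of the heuristic.
#' @return list with `labels` (cluster index -> semantic label), `gene_labels`
#'   (per gene) and `centroids` (label-named matrix on the grid,
#'   fold-change scale).
#' @export
label_classes <- function(assignment, profiles, delta = 0.1) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(profiles, "temporal_profiles"))
  if (assignment$k != 3) stop("semantic labeling expects exactly 3 clusters")
  cl <- assignment$cluster
  cent <- t(vapply(1:3, function(i)
    colMeans(profiles$fold[names(cl)[cl == i], , drop = FALSE]),
    numeric(ncol(profiles$fold))))
  b <- cent[, 1]
  f <- cent[, ncol(cent)]
  m <- apply(cent, 1, max)
  lab <- ifelse(f < b * (1 - delta), "repressed",
                ifelse(m > pmax(b, f) * (1 + delta), "transient", "induced"))
  if (anyDuplicated(lab)) {
    lab <- rep(NA_character_, 3)
    lab[which.min(f / b)] <- "repressed"
    rest <- which(is.na(lab))
    peak <- (m - pmax(b, f))[rest]
    lab[rest[which.max(peak)]] <- "transient"
    lab[which(is.na(lab))] <- "induced"
  }
  rownames(cent) <- lab
  list(labels = stats::setNames(lab, 1:3),
       gene_labels = stats::setNames(lab[cl], names(cl)),
       centroids = cent)
}

#' Cluster responsive-gene trajectories into temporal classes
#'
#' Convenience wrapper chaining [temporal_profiles()],
#' [wavelet_features()], [cluster_profiles()] and [label_classes()].
#'
#' @inheritParams temporal_profiles
#' @inheritParams cluster_profiles
#' @inheritParams label_classes
#' @return list of class `temporal_clustering` combining the pieces:
#'   `profiles`, `features`, `assignment`, `labels`, `gene_labels`,
#'   `centroids`.
#' @export
temporal_clustering <- function(normalized, meta,
                                genes = rownames(normalized), k = 3,
                                grid = seq(0, 24, by = 1),
                                linkage = "ward.D2", delta = 0.1) {
  prof <- temporal_profiles(normalized, meta, genes, grid)
  feat <- wavelet_features(prof$signal)
  asg <- cluster_profiles(feat, k = k, linkage = linkage)
  lab <- if (k == 3) label_classes(asg, prof, delta) else NULL
  out <- list(profiles = prof, features = feat, assignment = asg,
              labels = lab$labels, gene_labels = lab$gene_labels,
              centroids = lab$centroids)
  class(out) <- "temporal_clustering"
  out
}

#' Opposite-profile (GATA3-like versus mirror) gene groups
#'
#' Correlates each standardized gene trajectory with a drop-then-recover
#' template. Genes with Pearson r at least `r_threshold` form the
#' GATA3-like group; genes with r at most `-r_threshold` the opposite
#' (anti) group; others are unassigned. When no template is supplied, the
#' repressed-class genes are split in two and the subcentroid showing the
#' larger recovery (end value above minimum) is used.
#'
#' @param signal standardized gene x grid trajectory matrix (e.g.
#'   `temporal_profiles()$signal`), typically restricted to the repressed
#'   and transient classes.
#' @param template template trajectory on the same grid, or `NULL`.
#' @param repressed_genes gene ids used to derive the default template.
#' @param r_threshold correlation threshold.
#' @return list with `template`, `gata3_like`, `anti`, and `r` (per-gene
#'   correlations).
#' @export
opposite_profile_groups <- function(signal, template = NULL,
                                    repressed_genes = rownames(signal),
                                    r_threshold = 0.7) {
  if (is.null(template)) {
    sub <- signal[intersect(repressed_genes, rownames(signal)), ,
                  drop = FALSE]
    if (nrow(sub) < 2)
      stop("need a template or >= 2 repressed genes to derive one")
    cl <- stats::cutree(stats::hclust(stats::dist(sub), "ward.D2"), k = 2)
    cents <- lapply(1:2, function(i)
      colMeans(sub[cl == i, , drop = FALSE]))
    recov <- vapply(cents, function(ce)
      ce[length(ce)] - min(ce), numeric(1))
    template <- cents[[which.max(recov)]]
  }
  sds <- apply(signal, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("excluding zero-variance profile(s): ",
            paste(rownames(signal)[flat], collapse = ", "))
    signal <- signal[!flat, , drop = FALSE]
  }
  r <- apply(signal, 1, stats::cor, y = template)
  list(template = template,
       gata3_like = sort(rownames(signal)[r >= r_threshold]),
       anti = sort(rownames(signal)[r <= -r_threshold]),
       r = r)
}
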