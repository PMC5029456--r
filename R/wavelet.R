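# Daubechies-3 orthonormal scaling filter (low-pass synthesis coefficients);
# the detail filter is the alternating-flip quadrature mirror.
db3_scaling <- c(0.33267055295008263, 0.80689150931109250, 0.45987750211849154,
                 -0.13501102001025458, -0.08544127388202666, 0.03522629188570953)

dwt_filters <- function() {
  h <- db3_scaling
  L <- length(h)
  list(h = h, g = rev(h) * (-1)^(0:(L - 1)), L = L)
}

# one periodized analysis step; odd-length inputs are extended by repeating
# the last sample (the extension is removed again on reconstruction)
dwt_step <- function(x) {
  f <- dwt_filters()
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  ks <- seq(0, n - 2, by = 2)
  idx <- (outer(0:(f$L - 1), ks - 2, "+") %% n) + 1
  xm <- matrix(x[idx], nrow = f$L)
  list(cA = as.vector(f$h %*% xm), cD = as.vector(f$g %*% xm))
}

# inverse of dwt_step; n_out trims the odd-length extension
idwt_step <- function(cA, cD, n_out) {
  f <- dwt_filters()
  n <- 2 * length(cA)
  x <- numeric(n)
  for (k in seq_along(cA)) {
    pos <- ((0:(f$L - 1)) + 2 * (k - 1) - 2) %% n + 1
    x[pos] <- x[pos] + cA[k] * f$h + cD[k] * f$g
  }
  x[seq_len(n_out)]
}

#' Multilevel Daubechies-3 wavelet decomposition
#'
#' Full-depth discrete wavelet transform with periodized boundaries. With an
#' even-length (in particular dyadic) input the transform is orthonormal:
#' coefficient energy equals signal energy and reconstruction is exact.
#' Odd lengths at any level are handled by repeating the final sample, which
#' preserves exact reconstruction.
#'
#' @param x numeric series (length >= filter length, 6).
#' @param level decomposition depth; default `floor(log2(n / 5))`, the
#'   conventional maximum for a 6-tap filter.
#' @return list of class `dwt` with `coefficients` (list `cA`, then detail
#'   vectors coarsest first), `lengths` (input length per level) and
#'   `level`.
#' @export
wavelet_decompose <- function(x, level = NULL) {
  if (any(!is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  f <- dwt_filters()
  if (n < f$L) stop("series shorter than the wavelet support (", f$L, ")")
  max_lev <- max(1L, floor(log2(n / (f$L - 1))))
  if (is.null(level)) level <- max_lev
  level <- min(level, max_lev)
  details <- vector("list", level)
  lengths <- integer(level)
  cur <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(cur)
    s <- dwt_step(cur)
    details[[l]] <- s$cD
    cur <- s$cA
  }
  out <- list(coefficients = c(list(cA = cur), rev(details)),
              lengths = lengths, level = level)
  class(out) <- "dwt"
  out
}

#' Inverse multilevel wavelet transform
#'
#' @param d a `dwt` object from [wavelet_decompose()].
#' @return the reconstructed series.
#' @export
wavelet_reconstruct <- function(d) {
  stopifnot(inherits(d, "dwt"))
  cur <- d$coefficients$cA
  dets <- d$coefficients[-1]
  for (l in seq_len(d$level)) {
    cD <- dets[[l]]
    n_out <- d$lengths[d$level - l + 1]
    cur <- idwt_step(cur, cD, n_out)
  }
  cur
}

#' Wavelet feature vector of one or more series
#'
#' Concatenates the approximation and detail coefficients (coarsest first)
#' of the full-depth Daubechies-3 decomposition into a fixed-length feature
#' vector, identical in layout across genes.
#'
#' @param x numeric series, or a gene x grid matrix (one series per row).
#' @return numeric vector, or a gene x coefficient matrix.
#' @export
wavelet_features <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(r)
      unlist(wavelet_decompose(r)$coefficients, use.names = FALSE)))
    rownames(out) <- rownames(x)
    return(out)
  }
  unlist(wavelet_decompose(x)$coefficients, use.names = FALSE)
}
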