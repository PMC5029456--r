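# Independent oracles and small fixtures shared across tests.

# Small, fast simulation config for unit tests.
tiny_config <- function(...) {
  defaults <- list(n_genes = 80, n_mirnas = 6, n_targets = 6,
                   utr_length_range = c(120, 200), seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Dense gene-space characteristic-direction oracle: explicit shrunken
# covariance inversion, independent of the subspace implementation.
dense_chardir_oracle <- function(x_a, x_b, gamma) {
  mu_a <- colMeans(x_a); mu_b <- colMeans(x_b)
  delta <- mu_b - mu_a
  r <- rbind(sweep(x_a, 2, mu_a), sweep(x_b, 2, mu_b))
  n <- nrow(r)
  sigma <- crossprod(r) / n
  d <- qr(r)$rank
  lambda <- (1 - gamma) * sum(diag(sigma)) / d
  b <- solve(gamma * sigma + lambda * diag(ncol(sigma)), delta)
  b <- b / sqrt(sum(b^2))
  if (sum(b * delta) < 0) b <- -b
  b
}

# Brute-force seed-site oracle: slides a window over the UTR and compares
# substrings directly against the three canonical patterns.
brute_seed_sites <- function(utr, seed) {
  utr <- chartr("U", "T", toupper(utr))
  rc <- function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  seed_dna <- chartr("U", "T", toupper(seed))
  m8 <- rc(seed_dna)                       # revcomp of nt 2-8
  p8 <- paste0(m8, "A")                    # 8mer
  p1a <- paste0(rc(substr(seed_dna, 1, 6)), "A")  # revcomp(nt2-7) + A
  n <- nchar(utr)
  # enumerate every window start and compare substrings directly
  w8 <- if (n >= 8) substring(utr, 1:(n - 7), 8:n) else character(0)
  w7 <- if (n >= 7) substring(utr, 1:(n - 6), 7:n) else character(0)
  starts8 <- which(w8 == p8)                     # 1-based
  starts_m8 <- setdiff(which(w7 == m8), starts8)
  starts_1a <- setdiff(which(w7 == p1a), starts8 + 1)
  out <- data.frame(
    site_type = c(rep("8mer", length(starts8)),
                  rep("7mer-m8", length(starts_m8)),
                  rep("7mer-1A", length(starts_1a))),
    start0 = as.integer(c(starts8, starts_m8, starts_1a) - 1L),
    stringsAsFactors = FALSE)
  out[order(out$start0, out$site_type), , drop = FALSE]
}

# Random RNA mature sequence (22 nt).
random_mature <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
    character(1))
}

# Adjusted Rand index between two labelings (independent of mclust),
# computed from the pair-counting formula.
pair_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
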