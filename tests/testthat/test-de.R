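make_meta <- function(tps = c(0, 1, 2, 3, 4, 5, 6, 8, 12, 24), nrep = 3) {
  data.frame(sample_id = sprintf("t%g_r%d", rep(tps, each = nrep),
                                 rep(seq_len(nrep), length(tps))),
             time_h = rep(tps, each = nrep),
             replicate = rep(seq_len(nrep), length(tps)),
             stringsAsFactors = FALSE)
}

test_that("median-of-ratios size factors match the hand-computed example", {
  # genes (2,4) and (4,8): geometric means sqrt(8), sqrt(32); every ratio in
  # column 1 is 1/sqrt(2) and in column 2 sqrt(2)
  m <- matrix(c(2, 4, 4, 8), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  # identical columns give unit factors
  m2 <- matrix(c(5, 9, 5, 9, 5, 9), 2, 3,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # all-zero gene only: error instructing prefilter
  m3 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(m3), "prefilter")
})

test_that("size factors are scale-equivariant and geometric-mean centered", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rpois(20 * 6, 200), 20, 6,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%d", 1:6)))
    f <- size_factors(m)
    expect_equal(exp(mean(log(f))), 1)
    # scaling one column by c scales its factor by c (after re-centering)
    c_scale <- 3
    m2 <- m
    m2[, 2] <- m2[, 2] * c_scale
    f2 <- size_factors(m2)
    ratio <- f2 / f
    # all factors shift by the re-centering constant except column 2,
    # which additionally gains the factor c
    expect_equal(unname(ratio[2] / ratio[1]), c_scale, tolerance = 1e-10)
  }
})

test_that("normalization divides by factors", {
  m <- matrix(c(10, 20), 1, 2, dimnames = list("g", c("a", "b")))
  expect_equal(unname(normalize_counts(m, c(a = 2, b = 1))[1, ]), c(5, 20))
  expect_equal(normalize_counts(m, c(a = 1, b = 1)), m)
  expect_error(normalize_counts(m, c(a = -1, b = 1)), "positive")
})

test_that("dispersion estimation recovers the simulated alpha", {
  set.seed(5)
  meta <- make_meta()
  n <- 300
  counts <- matrix(rnbinom(n * 30, size = 1 / 0.05, mu = 1000), n, 30,
                   dimnames = list(sprintf("g%03d", 1:n), meta$sample_id))
  a <- estimate_dispersion(counts, meta$time_h)
  expect_gte(median(a), 0.02)
  expect_lte(median(a), 0.10)
  # Poisson gene: estimate near zero; constant gene: floored
  pois <- matrix(rpois(30 * 50, 500), 50, 30,
                 dimnames = list(sprintf("p%02d", 1:50), meta$sample_id))
  ap <- estimate_dispersion(pois, meta$time_h)
  expect_lt(median(ap), 0.005)
  const <- matrix(7, 2, 30,
                  dimnames = list(c("c1", "c2"), meta$sample_id))
  expect_equal(unname(estimate_dispersion(const, meta$time_h)),
               c(1e-8, 1e-8))
})

test_that("Wald test behaves at the degenerate and doubling contracts", {
  meta <- make_meta(c(0, 24), 3)
  norm <- rbind(gene_double = c(100, 110, 90, 210, 190, 200),
                gene_zero = rep(0, 6))
  colnames(norm) <- meta$sample_id
  disp <- c(gene_double = 0.05, gene_zero = 0.05)
  res <- test_vs_t0(norm, meta, disp, 24)
  expect_equal(res$log2fc[res$gene == "gene_double"], 1, tolerance = 0.05)
  expect_equal(res$log2fc[res$gene == "gene_zero"], 0)
  expect_equal(res$p_raw[res$gene == "gene_zero"], 1)
})

test_that("Wald test is calibrated under the NB null", {
  set.seed(31)
  meta <- make_meta()
  n <- 2000
  counts <- matrix(rnbinom(n * 30, size = 1 / 0.05, mu = 1000), n, 30,
                   dimnames = list(sprintf("g%04d", 1:n), meta$sample_id))
  de <- de_table(counts, meta)
  p <- de$table$p_raw[de$table$time_h == 24]
  frac <- mean(p < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), band)
  # and p-values are large on average when nothing changes
  expect_gt(mean(p), 0.4)
})

test_that("BH adjustment matches the worked example and its properties", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(8)
  for (i in 1:5) {
    p <- runif(50)
    q <- adjust_bh(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone: order of q follows order of p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("responsiveness filters apply both conditions and are monotone", {
  meta <- make_meta()
  ds <- simulate_dataset(tiny_config(n_genes = 120, n_targets = 10))
  de <- de_table(ds$mrna_counts, ds$meta)
  # abundance condition: raising min_mean can only shrink the set
  r1 <- select_responsive_genes(de, min_mean = 500)
  r2 <- select_responsive_genes(de, min_mean = 1200)
  expect_true(all(r2$gene %in% r1$gene))
  # effect-size condition: raising min_abs_log2fc can only shrink the set
  r3 <- select_responsive_genes(de, min_abs_log2fc = 1.5)
  expect_true(all(r3$gene %in% r1$gene))
  # a gene just under the abundance threshold is excluded even when
  # strongly significant
  fake <- de
  g1 <- r1$gene[1]
  fake$mean_norm_expr[g1] <- 499
  expect_false(g1 %in% select_responsive_genes(fake, min_mean = 500)$gene)
  # every member shows at least one qualifying timepoint
  expect_true(all(r1$n_timepoints_2fold >= 1))
})

test_that("timepoint census counts qualifying timepoints and conserves genes", {
  ds <- simulate_dataset(tiny_config(n_genes = 120, n_targets = 10))
  de <- de_table(ds$mrna_counts, ds$meta)
  resp <- select_responsive_genes(de)
  cen <- census_timepoints(de, resp, classes = ds$truth$classes)
  expect_equal(sum(cen$histogram), nrow(resp))
  expect_true(all(cen$per_gene >= 1 & cen$per_gene <= 9))
  # direct count for one gene: census equals the table's qualifying rows
  g <- resp$gene[1]
  tab <- de$table[de$table$gene == g, ]
  expect_equal(unname(cen$per_gene[g]),
               sum(tab$p_adj < 0.05 & abs(tab$log2fc) >= 1))
  # census is invariant to gene order in the responsive set
  resp_rev <- resp[rev(seq_len(nrow(resp))), ]
  cen2 <- census_timepoints(de, resp_rev)
  expect_equal(cen2$per_gene[names(cen$per_gene)], cen$per_gene)
})
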