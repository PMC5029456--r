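test_that("configuration invariants are enforced", {
  expect_error(simulation_config(class_fractions = c(transient = 0.5,
                                                     induced = 0.5,
                                                     repressed = 0.2,
                                                     null = 0)),
               "sum to 1")
  expect_error(simulation_config(timepoints = c(1, 2, 3)), "include 0")
  expect_error(simulation_config(timepoints = c(0, 2, 2, 4)), "increasing")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
  expect_error(simulation_config(baseline_mean = 0), "positive")
  expect_error(simulation_config(n_master_mirnas = 10, n_mirnas = 5),
               "exceed")
})

test_that("archetype latent profiles have the stated limits", {
  cfg <- tiny_config()
  gp <- generate_gene_profiles(cfg)
  tr <- gp$truth
  tp <- cfg$timepoints

  # null genes are constant at baseline, at every timepoint
  nulls <- names(tr$classes)[tr$classes == "null"]
  expect_true(all(gp$means[nulls, ] == cfg$baseline_mean))

  # transient pulse vanishes at both ends (well-separated peak)
  prof <- 1 + 2 * exp(-(c(0, 1e6) - 12)^2 / (2 * 2^2))
  expect_equal(prof, c(1, 1), tolerance = 1e-6)

  # induced genes reach exactly baseline * (1 + effect) at the last
  # timepoint (planted targets carry the boosted effect)
  ind <- names(tr$classes)[tr$classes == "induced"]
  expect_equal(gp$means[ind, length(tp)],
               cfg$baseline_mean * (1 + tr$effect[ind]))

  # all latent means positive, start at baseline
  expect_true(all(gp$means > 0))
  expect_equal(unname(gp$means[, 1]),
               rep(cfg$baseline_mean, cfg$n_genes), tolerance = 0.35)
})

test_that("repressed archetype recovers to the configured plateau", {
  # amplitude 0.5, recovery 0.6: plateau = 1 - a(1 - r) = 0.8
  expect_equal(repressed_profile(1e6, amplitude = 0.5, recovery = 0.6), 0.8)
  # monotone repression floors at 1 - a
  expect_equal(repressed_profile(1e6, amplitude = 0.5, recovery = 0), 0.5)
  # starts at baseline
  expect_equal(repressed_profile(0, amplitude = 0.5, recovery = 0.6), 1)
  # GATA3-like fixture: plateau exactly 60% of time zero
  g <- gata3_archetype(plateau = 0.6)
  expect_equal(repressed_profile(1e6, g$amplitude, g$recovery), 0.6)
  expect_error(repressed_profile(1, amplitude = 1.2), "amplitude")
})

test_that("class apportionment is within one of the target fractions", {
  for (n in c(60, 101, 600)) {
    cfg <- tiny_config(n_genes = n)
    gp <- generate_gene_profiles(cfg)
    tab <- table(gp$truth$classes)
    for (cl in names(tab)) {
      expect_lte(abs(tab[[cl]] - cfg$class_fractions[[cl]] * n), 1)
    }
    expect_equal(sum(tab), n)
  }
})

test_that("NB sampling matches the stated variance function", {
  cfg <- tiny_config(n_genes = 1, n_targets = 1, dispersion = 0.05,
                     library_size_factors = rep(1, 30))
  means <- matrix(1000, 1, 10,
                  dimnames = list("gene0001",
                                  as.character(cfg$timepoints)))
  # Monte-Carlo check: 1e4 draws, Var = mu + alpha mu^2 = 51000
  set.seed(99)
  draws <- stats::rnbinom(1e4, size = 1 / 0.05, mu = 1000)
  expect_lt(abs(var(draws) - 51000) / 51000, 0.10)

  # alpha = 0 degenerates to Poisson: variance close to mean
  set.seed(99)
  pd <- stats::rpois(1e4, 1000)
  cfg0 <- tiny_config(dispersion = 0)
  sc0 <- sample_counts(means, cfg0)
  expect_true(all(sc0$counts >= 0))
  expect_lt(abs(var(pd) - 1000) / 1000, 0.1)

  # determinism: identical config gives bit-identical matrices
  a <- sample_counts(means, cfg)
  b <- sample_counts(means, cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
})

test_that("whole datasets are deterministic given the seed", {
  d1 <- simulate_dataset(tiny_config())
  d2 <- simulate_dataset(tiny_config())
  expect_identical(d1$mrna_counts, d2$mrna_counts)
  expect_identical(d1$mirna_counts, d2$mirna_counts)
  expect_identical(as.character(d1$utrs), as.character(d2$utrs))
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(tiny_config(seed = 43))
  expect_false(identical(d1$mrna_counts, d3$mrna_counts))
})

test_that("master miRNA reaches the configured latent fold exactly", {
  cfg <- tiny_config()
  mp <- generate_mirna_profiles(cfg)
  m <- mp$means[mp$truth$master_mirnas[1], ]
  expect_equal(unname(m[length(m)] / m[1]), cfg$mirna_master_fold)
  # non-master miRNAs are flat
  others <- setdiff(rownames(mp$means), mp$truth$master_mirnas)
  expect_true(all(apply(mp$means[others, ], 1, function(r)
    all(r == r[1]))))
  # fold 1 makes the master indistinguishable from flat
  mp1 <- generate_mirna_profiles(tiny_config(mirna_master_fold = 1))
  m1 <- mp1$means[1, ]
  expect_true(all(m1 == m1[1]))
})

test_that("planted UTRs carry master sites exactly where recorded", {
  ds <- simulate_dataset(tiny_config())
  master_seed <- substr(ds$seed_table$mature_sequence[1], 2, 8)
  for (g in ds$truth$planted_targets) {
    hits <- seed_sites(as.character(ds$utrs[[g]]), master_seed)
    expect_setequal(hits$start0[hits$site_type == "8mer"],
                    ds$truth$planted_sites[[g]])
  }
  # scrubbed non-target UTRs have no site of any configured family
  non_targets <- setdiff(names(ds$utrs), ds$truth$planted_targets)
  for (g in sample(non_targets, 10)) {
    for (i in seq_len(nrow(ds$seed_table))) {
      s <- substr(ds$seed_table$mature_sequence[i], 2, 8)
      expect_equal(nrow(seed_sites(as.character(ds$utrs[[g]]), s)), 0)
    }
  }
  # lengths within the configured range
  lens <- Biostrings::width(ds$utrs)
  expect_true(all(lens >= 120 & lens <= 200))
})

test_that("background base composition is approximately uniform", {
  u <- random_utrs(40, length_range = c(250, 250), seed = 5)
  counts <- colSums(Biostrings::alphabetFrequency(u)[, c("A", "C", "G", "T")])
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("datasets round-trip through disk exactly", {
  ds <- simulate_dataset(tiny_config())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$mrna_counts, ds$mrna_counts)
  expect_identical(back$mirna_counts, ds$mirna_counts)
  expect_equal(back$meta, ds$meta)
  expect_identical(as.character(back$utrs), as.character(ds$utrs))
  # FASTA headers match count-matrix gene ids
  expect_setequal(names(back$utrs), rownames(back$mrna_counts))
  # truth JSON lists exactly the planted targets
  expect_setequal(names(back$truth$planted_targets),
                  ds$truth$planted_targets)
})
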