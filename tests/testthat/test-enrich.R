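test_that("family grouping keys on nucleotides 2-8", {
  tab <- data.frame(
    mirna_id = c("mir-a", "mir-b", "mir-c"),
    family_id = c("famA", "famA", "famB"),
    mature_sequence = c("UAGCAGCGGGAACAGUUCUGCA",   # shares nt2-8 with b
                        "CAGCAGCGGGUUUUUUUUUUUU",
                        "UUUUCCCGGGAACAGUUCUGCA"),
    stringsAsFactors = FALSE)
  fams <- group_families(tab)
  expect_equal(nrow(fams), 2)
  two <- fams[fams$n_members == 2, ]
  expect_equal(two$seed, "AGCAGCG")
  expect_equal(two$members, "mir-a,mir-b")
  # expression filter: best member mean below threshold drops the family
  expr <- c("mir-a" = 20, "mir-b" = 49, "mir-c" = 60)
  fams2 <- group_families(tab, expr, min_mean = 50)
  expect_equal(fams2$members, "mir-c")
  # empty table and malformed sequences
  expect_equal(nrow(group_families(tab[0, ])), 0)
  tab$mature_sequence[1] <- "UAGCAGCGGGAACAGTXCUGCA"
  expect_error(group_families(tab), "non-RNA")
})

test_that("seed scanner reproduces the hand-worked site example", {
  # miRNA 5'-UAGCAGCGGG...: seed (nt 2-8) AGCAGCG, revcomp CGCTGCT
  hits <- seed_sites("AACGCTGCTAAA", "AGCAGCG")
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$start0, 2L)
  # destroying the 3' A leaves a bare 7mer-m8
  hits2 <- seed_sites("AACGCTGCTGAA", "AGCAGCG")
  expect_equal(hits2$site_type, "7mer-m8")
  expect_equal(hits2$start0, 2L)
  # no pattern present
  expect_equal(nrow(seed_sites("ACACACACACAC", "AGCAGCG")), 0)
  # a 7mer-1A match without the m8 base
  hits3 <- seed_sites("TTGCTGCTATT", "AGCAGCG")
  expect_equal(hits3$site_type, "7mer-1A")
  expect_equal(hits3$start0, 2L)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(51)
  utrs <- random_utrs(60, c(200, 200), seed = 52)
  fams <- random_mature(8)
  for (f in fams) {
    seed <- substr(f, 2, 8)
    for (i in sample(length(utrs), 15)) {
      s <- as.character(utrs[[i]])
      got <- seed_sites(s, seed)
      want <- brute_seed_sites(s, seed)
      expect_equal(got[, c("site_type", "start0")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("site-count matrix agrees with the per-UTR scanner", {
  utrs <- random_utrs(40, c(150, 300), seed = 53)
  st <- data.frame(mirna_id = sprintf("m%d", 1:5),
                   family_id = sprintf("f%d", 1:5),
                   mature_sequence = random_mature(5),
                   stringsAsFactors = FALSE)
  fams <- group_families(st)
  sc <- target_site_counts(utrs, fams)
  for (j in seq_len(nrow(fams))) {
    for (i in sample(length(utrs), 10)) {
      expect_equal(sc[names(utrs)[i], fams$family_id[j]],
                   nrow(seed_sites(as.character(utrs[[i]]), fams$seed[j])))
    }
  }
})

test_that("target scores follow their definitions", {
  sc <- matrix(c(0, 1, 3, 0, 2, 0), 6, 1,
               dimnames = list(sprintf("g%d", 1:6), "famX"))
  expect_equal(target_score(sprintf("g%d", 1:6), "famX", sc, "binary"), 3)
  expect_equal(target_score(sprintf("g%d", 1:6), "famX", sc, "site_count"), 6)
  # site_count always >= binary
  expect_gte(target_score(sprintf("g%d", 1:6), "famX", sc, "site_count"),
             target_score(sprintf("g%d", 1:6), "famX", sc, "binary"))
  expect_error(target_score(character(0), "famX", sc), "empty")
  expect_warning(target_score(c("g1", "g2", "nope"), "famX", sc),
                 "without UTR")
})

test_that("empirical p-values hit the formula floor and ceiling", {
  set.seed(54)
  sc <- matrix(rbinom(500, 1, 0.05), 500, 1,
               dimnames = list(sprintf("g%03d", 1:500), "famX"))
  bg <- rownames(sc)
  # observed exceeding every null score: p = 1/(N+1)
  r <- empirical_pvalue(999, 10, "famX", bg, sc, n_perm = 999, seed = 1)
  expect_equal(r$p, 1 / 1000)
  # observed zero: every null >= 0, p = 1
  r0 <- empirical_pvalue(0, 10, "famX", bg, sc, n_perm = 200, seed = 1)
  expect_equal(r0$p, 1)
  expect_warning(empirical_pvalue(1, 5, "famX", bg, sc, n_perm = 50),
                 "coarse")
  expect_error(empirical_pvalue(1, 600, "famX", bg, sc, n_perm = 200),
               "larger")
  # determinism
  a <- empirical_pvalue(3, 20, "famX", bg, sc, n_perm = 500, seed = 7)
  b <- empirical_pvalue(3, 20, "famX", bg, sc, n_perm = 500, seed = 7)
  expect_identical(a, b)
})

test_that("enrichment is monotone in planted targets", {
  set.seed(55)
  sc <- matrix(rbinom(400, 1, 0.08), 400, 1,
               dimnames = list(sprintf("g%03d", 1:400), "famX"))
  bg <- rownames(sc)
  targets <- rownames(sc)[sc[, 1] > 0]
  nont <- setdiff(bg, targets)
  base_set <- c(targets[1:3], nont[1:17])
  more_set <- c(targets[1:4], nont[1:16])
  p1 <- empirical_pvalue(target_score(base_set, "famX", sc), 20, "famX",
                         bg, sc, n_perm = 500, seed = 3)$p
  p2 <- empirical_pvalue(target_score(more_set, "famX", sc), 20, "famX",
                         bg, sc, n_perm = 500, seed = 3)$p
  expect_lte(p2, p1)
})

test_that("enrichment matrix has the right shape and determinism", {
  utrs <- random_utrs(120, c(200, 350), seed = 56)
  st <- data.frame(mirna_id = sprintf("m%d", 1:10),
                   family_id = sprintf("f%02d", 1:10),
                   mature_sequence = random_mature(10),
                   stringsAsFactors = FALSE)
  fams <- group_families(st)
  sc <- target_site_counts(utrs, fams)
  bg <- names(utrs)
  sets <- lapply(1:9, function(i) sample(bg, 15))
  names(sets) <- sprintf("s%d", 1:9)
  em <- enrichment_matrix(fams, sets, bg, sc, n_perm = 200, seed = 9)
  expect_equal(dim(em$neglog10_p), c(nrow(fams), 9))
  em2 <- enrichment_matrix(fams, sets, bg, sc, n_perm = 200, seed = 9)
  expect_identical(em$p, em2$p)
  expect_true(all(em$p > 0 & em$p <= 1))
  expect_true(all(em$p >= 1 / 201))
})

test_that("master ranking sums significance and breaks ties by id", {
  m <- rbind(famB = c(1, 2, 1), famA = c(2, 1, 1), famC = c(5, 5, 5))
  r <- rank_master_regulators(m)
  expect_equal(r$family_id, c("famC", "famA", "famB"))
  expect_equal(r$rank, 1:3)
  # adding a constant to every cell preserves the ordering
  r2 <- rank_master_regulators(m + 0.7)
  expect_equal(r2$family_id, r$family_id)
  # single family ranks first trivially
  expect_equal(rank_master_regulators(m[1, , drop = FALSE])$rank, 1)
})

test_that("predicted targets intersect sets with site carriers", {
  sc <- matrix(c(2, 0, 1, 0), 4, 1,
               dimnames = list(c("g1", "g2", "g3", "g4"), "famX"))
  sets <- list(`0->1` = c("g1", "g2"), `1->2` = c("g1", "g4"))
  out <- predicted_targets_in_sets("famX", sets, sc)
  expect_equal(out$gene, "g1")
  expect_equal(out$intervals, "0->1,1->2")
  # gene with a site but never characteristic is excluded; containment holds
  expect_false("g3" %in% out$gene)
  expect_true(all(out$gene %in% unlist(sets)))
})

test_that("length-matched null draws preserve decile composition", {
  utrs <- random_utrs(200, c(100, 1000), seed = 61)
  lens <- stats::setNames(Biostrings::width(utrs), names(utrs))
  sc <- matrix(rbinom(200, 1, 0.1), 200, 1,
               dimnames = list(names(utrs), "famX"))
  bg <- names(utrs)
  # pick an observed set concentrated in the longest decile
  long <- names(sort(lens, decreasing = TRUE))[1:20]
  r <- empirical_pvalue(5, 20, "famX", bg, sc, n_perm = 200, seed = 2,
                        utr_lengths = lens, length_match = TRUE,
                        gene_set = long)
  expect_true(r$p > 0 && r$p <= 1)
  expect_error(empirical_pvalue(5, 20, "famX", bg, sc, n_perm = 200,
                                length_match = TRUE, utr_lengths = lens),
               "gene_set")
  expect_error(empirical_pvalue(5, 20, "famX", bg, sc, n_perm = 200,
                                length_match = TRUE, gene_set = long),
               "utr_lengths")
})
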