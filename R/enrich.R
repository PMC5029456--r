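#' Group miRNAs into seed families
#'
#' Families are keyed by the extended seed (mature nucleotides 2-8).
#' Family-level expression is the maximum (or sum) of the member means;
#' families below the expression threshold are dropped.
#'
#' @param seed_table data.frame with `mirna_id`, `family_id`,
#'   `mature_sequence` (RNA alphabet).
#' @param mean_rpmm optional named per-miRNA mean RPMM vector; `NULL` skips
#'   the expression filter.
#' @param min_mean family expression threshold (default 50 RPMM).
#' @param member_stat `"max"` or `"sum"` of member means.
#' @return data.frame with one row per family: `family_id`, `seed`
#'   (nt 2-8, RNA), `members` (comma-separated), `n_members`, `mean_expr`.
#' @export
group_families <- function(seed_table, mean_rpmm = NULL, min_mean = 50,
                           member_stat = c("max", "sum")) {
  member_stat <- match.arg(member_stat)
  seqs <- toupper(seed_table$mature_sequence)
  if (any(nchar(seqs) < 8)) stop("mature sequences must be >= 8 nt")
  if (any(grepl("[^ACGU]", seqs)))
    stop("mature sequences contain non-RNA characters: ",
         paste(seed_table$mirna_id[grepl("[^ACGU]", seqs)], collapse = ", "))
  seed <- substr(seqs, 2, 8)
  fams <- split(seq_len(nrow(seed_table)), seed)
  rows <- lapply(names(fams), function(s) {
    i <- fams[[s]]
    expr <- if (is.null(mean_rpmm)) NA_real_ else {
      v <- mean_rpmm[seed_table$mirna_id[i]]
      if (member_stat == "max") max(v) else sum(v)
    }
    data.frame(family_id = sort(unique(seed_table$family_id[i]))[1],
               seed = s,
               members = paste(sort(seed_table$mirna_id[i]), collapse = ","),
               n_members = length(i),
               mean_expr = expr,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(family_id = character(0), seed = character(0),
                      members = character(0), n_members = integer(0),
                      mean_expr = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (!is.null(mean_rpmm)) out <- out[out$mean_expr >= min_mean, ,
                                      drop = FALSE]
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a 3'-UTR for canonical seed-match sites
#'
#' Reports all 8mer, 7mer-m8 and 7mer-1A matches of a family seed in a UTR
#' (given 5' to 3', DNA alphabet; U is mapped to T). An 8mer is reported
#' once and suppresses the 7mer-m8 and 7mer-1A matches it contains;
#' overlapping distinct sites are all reported.
#'
#' @param utr UTR sequence (character or [Biostrings::DNAString]).
#' @param seed extended seed, mature nt 2-8 (7 nt, RNA or DNA alphabet).
#' @param family_id label copied into the result.
#' @return data.frame with `family_id`, `site_type`, `start0` (0-based
#'   start of the site on the UTR).
#' @export
seed_sites <- function(utr, seed, family_id = NA_character_) {
  s <- toupper(as.character(utr))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) stop("UTR contains non-ACGT/U characters")
  p <- seed_patterns(chartr("T", "U", toupper(seed)))
  d <- Biostrings::DNAString(s)
  st8 <- Biostrings::start(Biostrings::matchPattern(p$eight, d))
  stm8 <- Biostrings::start(Biostrings::matchPattern(p$m8, d))
  st1a <- Biostrings::start(Biostrings::matchPattern(p$one_a, d))
  stm8 <- setdiff(stm8, st8)           # 7mer-m8 not extended by the 3' A
  st1a <- setdiff(st1a, st8 + 1)       # 7mer-1A not inside an 8mer
  n_hits <- length(st8) + length(stm8) + length(st1a)
  out <- data.frame(
    family_id = rep(family_id, n_hits),
    site_type = c(rep("8mer", length(st8)), rep("7mer-m8", length(stm8)),
                  rep("7mer-1A", length(st1a))),
    start0 = as.integer(c(st8, stm8, st1a) - 1L),
    stringsAsFactors = FALSE)
  out[order(out$start0, out$site_type), , drop = FALSE]
}

#' Per-gene seed-site counts for a set of families
#'
#' Fast scanner over a whole UTR collection: for each family, counts the
#' distinct canonical sites (8mer counted once) per gene.
#'
#' @param utrs named [Biostrings::DNAStringSet] of UTRs.
#' @param families family table from [group_families()] (needs `family_id`
#'   and `seed`).
#' @return integer gene x family matrix of site counts.
#' @export
target_site_counts <- function(utrs, families) {
  out <- matrix(0L, length(utrs), nrow(families),
                dimnames = list(names(utrs), families$family_id))
  for (j in seq_len(nrow(families))) {
    p <- seed_patterns(families$seed[j])
    n8 <- Biostrings::vcountPattern(p$eight, utrs)
    nm8 <- Biostrings::vcountPattern(p$m8, utrs)
    n1a <- Biostrings::vcountPattern(p$one_a, utrs)
    # every 8mer is counted inside both 7mer tallies; keep it once
    out[, j] <- nm8 + n1a - n8
  }
  out
}

#' Target score of a gene set for one family
#'
#' `binary` mode counts genes carrying at least one site; `site_count` mode
#' sums all distinct sites over the set.
#'
#' @param gene_set character vector of gene ids.
#' @param family_id column of the site-count matrix to use.
#' @param site_counts gene x family matrix from [target_site_counts()].
#' @param mode `"binary"` or `"site_count"`.
#' @return numeric score.
#' @export
target_score <- function(gene_set, family_id, site_counts,
                         mode = c("binary", "site_count")) {
  mode <- match.arg(mode)
  if (length(gene_set) == 0) stop("gene set is empty")
  missing <- setdiff(gene_set, rownames(site_counts))
  if (length(missing)) {
    warning("gene(s) without UTR excluded from scoring: ",
            paste(missing, collapse = ", "))
    gene_set <- setdiff(gene_set, missing)
    if (!length(gene_set)) stop("no gene in the set has a UTR")
  }
  v <- site_counts[gene_set, family_id]
  if (mode == "binary") sum(v > 0) else sum(v)
}

#' Monte-Carlo empirical enrichment p-value
#'
#' Draws `n_perm` random gene sets of the observed size (without
#' replacement, optionally stratified by UTR-length decile) from the
#' background, scores each against the family, and returns the add-one
#' empirical p-value `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param observed observed target score.
#' @param set_size size of the observed gene set.
#' @param family_id family column of `site_counts`.
#' @param background character vector of background gene ids.
#' @param site_counts gene x family site-count matrix.
#' @param n_perm number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @param mode scoring mode (see [target_score()]).
#' @param utr_lengths optional named UTR lengths enabling length-decile
#'   matching of the null sets.
#' @param length_match draw null sets stratified by UTR-length decile.
#' @param gene_set the observed gene ids; required when `length_match` is
#'   set (the null draws reproduce the observed set's decile composition).
#' @return list of class `enrichment_result`: `observed`, `p`,
#'   `neglog10_p`, `n_perm`, `n_ge`, `null_mean`, `null_sd`.
#' @export
empirical_pvalue <- function(observed, set_size, family_id, background,
                             site_counts, n_perm = 1000, seed = 1,
                             mode = "binary", utr_lengths = NULL,
                             length_match = FALSE, gene_set = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values coarse")
  if (length(background) <= set_size)
    stop("background must be larger than the gene set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- site_counts[background, family_id]
  hit <- if (mode == "binary") as.numeric(v > 0) else as.numeric(v)
  null_scores <- numeric(n_perm)
  if (!length_match) {
    for (i in seq_len(n_perm))
      null_scores[i] <- sum(hit[sample.int(length(background), set_size)])
  } else {
    if (is.null(utr_lengths)) stop("length matching needs utr_lengths")
    if (is.null(gene_set)) stop("length matching needs the observed gene_set")
    strata <- ceiling(10 * rank(utr_lengths[background],
                                ties.method = "first") / length(background))
    names(strata) <- background
    # preserve the observed set's decile composition in every null draw
    want <- table(strata[gene_set])
    idx_by <- split(seq_along(background), strata)
    for (i in seq_len(n_perm)) {
      pick <- unlist(lapply(names(want), function(s)
        sample(idx_by[[s]], want[[s]])), use.names = FALSE)
      null_scores[i] <- sum(hit[pick])
    }
  }
  n_ge <- sum(null_scores >= observed)
  p <- (1 + n_ge) / (1 + n_perm)
  out <- list(observed = observed, p = p, neglog10_p = -log10(p),
              n_perm = n_perm, n_ge = n_ge,
              null_mean = mean(null_scores), null_sd = stats::sd(null_scores))
  class(out) <- "enrichment_result"
  out
}

#' Family x interval enrichment matrix
#'
#' Runs the Monte-Carlo enrichment of every family against every interval
#' gene set. Null sets are drawn once per interval (they depend only on the
#' set size) and scored against all families, which keeps the computation
#' linear in `n_perm`.
#'
#' @param families family table from [group_families()].
#' @param interval_sets named list of character gene-id vectors (or
#'   `char_gene_set` objects).
#' @param background character vector of background gene ids.
#' @param site_counts gene x family matrix from [target_site_counts()].
#' @param n_perm Monte-Carlo draws per cell.
#' @param seed master seed (per-interval seeds derived from it).
#' @param mode scoring mode.
#' @return list of class `enrichment_matrix` with `neglog10_p` and `p`
#'   (family x interval matrices), `observed`, and the inputs' labels.
#' @export
enrichment_matrix <- function(families, interval_sets, background,
                              site_counts, n_perm = 1000, seed = 1,
                              mode = "binary") {
  if (nrow(families) < 1 || length(interval_sets) < 1)
    stop("need at least one family and one interval set")
  sets <- lapply(interval_sets, function(s)
    if (inherits(s, "char_gene_set")) s$genes else s)
  if (!all(unlist(sets) %in% background))
    stop("interval sets must be contained in the background")
  fam_ids <- families$family_id
  hit <- site_counts[background, fam_ids, drop = FALSE]
  if (mode == "binary") hit <- (hit > 0) + 0
  pm <- om <- matrix(NA_real_, length(fam_ids), length(sets),
                     dimnames = list(fam_ids, names(sets)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (k in seq_along(sets)) {
    gs <- sets[[k]]
    obs <- colSums(hit[gs, , drop = FALSE])
    set.seed(derive_seed(seed, paste0("perm_", names(sets)[k])))
    ge <- numeric(length(fam_ids))
    for (i in seq_len(n_perm)) {
      null_s <- colSums(hit[sample.int(length(background), length(gs)), ,
                            drop = FALSE])
      ge <- ge + (null_s >= obs)
    }
    pm[, k] <- (1 + ge) / (1 + n_perm)
    om[, k] <- obs
  }
  out <- list(neglog10_p = -log10(pm), p = pm, observed = om,
              n_perm = n_perm, mode = mode)
  class(out) <- "enrichment_matrix"
  out
}

#' Rank candidate master-regulator families
#'
#' Families are ordered by their summed `-log10` enrichment p-value across
#' all intervals (descending); ties are broken lexicographically by family
#' id.
#'
#' @param em an `enrichment_matrix`, or a bare family x interval
#'   `-log10(p)` matrix.
#' @return data.frame with `family_id`, `sum_neglog10_p`, `rank`.
#' @export
rank_master_regulators <- function(em) {
  m <- if (inherits(em, "enrichment_matrix")) em$neglog10_p else em
  if (any(!is.finite(m))) stop("enrichment matrix contains non-finite values")
  s <- rowSums(m)
  ord <- order(-s, rownames(m))
  data.frame(family_id = rownames(m)[ord], sum_neglog10_p = s[ord],
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Predicted targets of a family among the characteristic gene sets
#'
#' Returns the genes that appear in at least one interval set and carry at
#' least one seed site of the family, annotated with the intervals in which
#' they occur.
#'
#' @param family_id family column of `site_counts`.
#' @param interval_sets named list of gene-id vectors or `char_gene_set`s.
#' @param site_counts gene x family site-count matrix.
#' @return data.frame with `gene`, `n_sites`, `intervals`
#'   (comma-separated).
#' @export
predicted_targets_in_sets <- function(family_id, interval_sets,
                                      site_counts) {
  sets <- lapply(interval_sets, function(s)
    if (inherits(s, "char_gene_set")) s$genes else s)
  genes <- sort(unique(unlist(sets)))
  genes <- intersect(genes, rownames(site_counts))
  n_sites <- site_counts[genes, family_id]
  keep <- n_sites > 0
  genes <- genes[keep]
  ivs <- vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = ","), character(1))
  data.frame(gene = genes, n_sites = as.integer(n_sites[keep]),
             intervals = ivs, row.names = NULL, stringsAsFactors = FALSE)
}
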