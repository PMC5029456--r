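#' Configuration for the synthetic estrogen time-course generator
#'
#' Builds and validates the parameter set for a ground-truthed synthetic
#' dataset emulating a 10-timepoint (0-24 h), 3-replicate estrogen
#' stimulation experiment: negative-binomial mRNA and miRNA counts driven by
#' latent temporal archetypes (transient pulse, sustained induction,
#' repression with optional partial recovery, flat nulls), an induced master
#' miRNA, and 3'-UTR sequences with seed sites planted in the master's
#' target genes.
#'
#' @param n_genes number of mRNA genes.
#' @param class_fractions named fractions for the four gene classes
#'   (`transient`, `induced`, `repressed`, `null`); must sum to 1.
#' @param n_mirnas number of miRNAs (each its own seed family by default).
#' @param n_master_mirnas number of induced master miRNAs (first ids).
#' @param timepoints hours post stimulation; strictly increasing, contains 0.
#' @param n_replicates replicates per timepoint.
#' @param baseline_mean expected baseline count per gene.
#' @param dispersion NB dispersion alpha with `Var = mu + alpha * mu^2`.
#' @param effect_size maximum relative change of the responsive archetypes:
#'   induced genes reach `baseline * (1 + effect_size)` at the final
#'   timepoint, transient genes at their peak, and repressed genes drop to
#'   `baseline / (1 + effect_size)` (log-symmetric with induction).
#' @param library_size_factors per-sample depth multipliers, or `NULL` to
#'   draw log-normal(0, 0.15) multipliers from the seed.
#' @param utr_length_range min/max 3'-UTR length (nt).
#' @param sites_per_target planted master seed sites per target gene.
#' @param n_targets number of planted master-miRNA target genes (spread
#'   over the three responsive classes).
#' @param target_amplitude_boost multiplier on `effect_size` for planted
#'   target genes, making them rank among the strongest movers (master
#'   miRNA targets are enriched among interval-discriminating genes).
#' @param gata3_fraction fraction of repressed genes given a partial-recovery
#'   ("GATA3-like") trajectory instead of monotone repression.
#' @param recovery_fraction plateau recovery fraction for GATA3-like genes.
#' @param mirna_baseline_mean expected baseline miRNA count.
#' @param mirna_master_fold latent ratio of master miRNA expression at the
#'   final timepoint versus time zero.
#' @param scrub_background if `TRUE`, background UTR sequence is
#'   rejection-sampled so no unplanned seed site of any configured family
#'   occurs anywhere.
#' @param seed master RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              class_fractions = c(transient = 0.25,
                                                  induced = 0.25,
                                                  repressed = 0.25,
                                                  null = 0.25),
                              n_mirnas = 30,
                              n_master_mirnas = 1,
                              timepoints = c(0, 1, 2, 3, 4, 5, 6, 8, 12, 24),
                              n_replicates = 3,
                              baseline_mean = 2000,
                              dispersion = 0.05,
                              effect_size = 2,
                              library_size_factors = NULL,
                              utr_length_range = c(300, 500),
                              sites_per_target = 1,
                              n_targets = 30,
                              target_amplitude_boost = 1.5,
                              gata3_fraction = 0.3,
                              recovery_fraction = 0.6,
                              mirna_baseline_mean = 2000,
                              mirna_master_fold = 6,
                              scrub_background = TRUE,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_fractions = class_fractions,
              n_mirnas = as.integer(n_mirnas),
              n_master_mirnas = as.integer(n_master_mirnas),
              timepoints = as.numeric(timepoints),
              n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              effect_size = effect_size,
              library_size_factors = library_size_factors,
              utr_length_range = as.integer(utr_length_range),
              sites_per_target = as.integer(sites_per_target),
              n_targets = as.integer(n_targets),
              target_amplitude_boost = target_amplitude_boost,
              gata3_fraction = gata3_fraction,
              recovery_fraction = recovery_fraction,
              mirna_baseline_mean = mirna_baseline_mean,
              mirna_master_fold = mirna_master_fold,
              scrub_background = isTRUE(scrub_background),
              seed = as.integer(seed))
  nm <- c("transient", "induced", "repressed", "null")
  if (!all(nm %in% names(cfg$class_fractions)))
    stop("class_fractions must name: ", paste(nm, collapse = ", "))
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8)
    stop("class fractions must sum to 1")
  tp <- cfg$timepoints
  if (any(diff(tp) <= 0) || !(0 %in% tp))
    stop("timepoints must be strictly increasing and include 0")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$baseline_mean <= 0 || cfg$mirna_baseline_mean <= 0)
    stop("baseline means must be positive")
  if (cfg$effect_size <= 0) stop("effect_size must be positive")
  if (min(cfg$n_genes, cfg$n_mirnas, cfg$n_replicates,
          cfg$sites_per_target) < 1)
    stop("all counts must be >= 1")
  if (cfg$n_master_mirnas > cfg$n_mirnas)
    stop("n_master_mirnas cannot exceed n_mirnas")
  if (cfg$n_targets > cfg$n_genes) stop("n_targets cannot exceed n_genes")
  if (cfg$utr_length_range[1] < 30)
    stop("minimum UTR length must leave room for a planted site plus margin")
  class(cfg) <- "sim_config"
  cfg
}

# largest-remainder apportionment: realized class sizes within +/-1 of
# fraction * n and summing to n exactly
apportion_classes <- function(fracs, n) {
  raw <- fracs * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Latent repressed-gene trajectory with optional recovery
#'
#' Relative (baseline = 1) expression of a repressed gene: a fast initial
#' drop of amplitude `amplitude` followed, after `lag` hours, by partial
#' recovery toward a plateau of `1 - amplitude * (1 - recovery)`. With
#' `recovery = 0` the repression is monotone; `amplitude = 2/3,
#' recovery = 0.4` gives a GATA3-like profile settling at 60% of baseline.
#'
#' @param t hours.
#' @param amplitude fractional drop depth in (0, 1).
#' @param recovery fraction of the drop that is recovered, in \[0, 1\].
#' @param tau_drop time constant (h) of the initial drop.
#' @param tau_rec time constant (h) of the recovery.
#' @param lag hours before recovery begins.
#' @return numeric vector of relative expression values.
#' @export
repressed_profile <- function(t, amplitude, recovery = 0, tau_drop = 0.6,
                              tau_rec = 6, lag = 2) {
  if (amplitude >= 1 || amplitude <= 0)
    stop("repressed amplitude must lie in (0, 1): got ", amplitude)
  drop <- 1 - exp(-t / tau_drop)
  rec <- 1 - exp(-pmax(0, t - lag) / tau_rec)
  1 - amplitude * drop * (1 - recovery * rec)
}

#' GATA3-like archetype parameters for a given recovery plateau
#'
#' Picks the `(amplitude, recovery)` pair of [repressed_profile()] whose
#' asymptotic plateau equals `plateau` times baseline.
#'
#' @param plateau asymptotic relative expression (default 0.6, an initial
#'   drop recovering to 60% of time-zero expression).
#' @param amplitude drop amplitude in (plateau complement, 1).
#' @return list with `amplitude` and `recovery`.
#' @export
gata3_archetype <- function(plateau = 0.6, amplitude = 2 / 3) {
  if (plateau <= 0 || plateau >= 1) stop("plateau must be in (0,1)")
  if (amplitude < 1 - plateau)
    stop("amplitude too small to reach the requested plateau")
  list(amplitude = amplitude, recovery = 1 - (1 - plateau) / amplitude)
}

# normalized Hill activation: 0 at t=0, exactly 1 at t = t_end
hill_rise <- function(t, half_time, n, t_end) {
  (t^n / (t^n + half_time^n)) / (t_end^n / (t_end^n + half_time^n))
}

# relative latent trajectory for one gene
rel_trajectory <- function(class, t, effect, pars, t_end) {
  switch(class,
    null = rep(1, length(t)),
    transient = 1 + effect *
      exp(-(t - pars$peak_time)^2 / (2 * pars$width^2)),
    induced = 1 + effect * hill_rise(t, pars$half_time, pars$hill_n, t_end),
    repressed = repressed_profile(t, amplitude = effect / (1 + effect),
                                  recovery = pars$recovery,
                                  tau_drop = pars$tau_drop,
                                  tau_rec = pars$tau_rec,
                                  lag = pars$lag),
    stop("unknown archetype class: ", class))
}

#' Generate latent gene expression profiles and the ground truth
#'
#' Assigns each gene to one of the four archetype classes (deterministic
#' apportionment by the configured fractions), draws per-gene archetype
#' parameters, selects the planted master-miRNA target genes among the
#' responsive classes (with an amplitude boost so targets rank among the
#' strongest movers), and evaluates the latent mean expression of every gene
#' at every configured timepoint.
#'
#' @param config a [simulation_config()].
#' @return list with `means` (gene x timepoint latent matrix, columns named
#'   by hour) and `truth` (classes, archetype parameters, responsive flags,
#'   planted target ids).
#' @export
generate_gene_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints
  t_end <- max(tp)
  nm <- c("transient", "induced", "repressed", "null")
  sizes <- apportion_classes(config$class_fractions[nm], config$n_genes)
  classes <- rep(nm, sizes)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  names(classes) <- genes

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "gene_profiles"))

  pars <- data.frame(gene = genes, class = classes,
                     peak_time = NA_real_, width = NA_real_,
                     half_time = NA_real_, hill_n = NA_real_,
                     recovery = NA_real_, tau_drop = NA_real_,
                     tau_rec = NA_real_, lag = NA_real_,
                     stringsAsFactors = FALSE)
  itr <- classes == "transient"
  pars$peak_time[itr] <- stats::runif(sum(itr), 3, 6)
  pars$width[itr] <- stats::runif(sum(itr), 0.8, 1.3)
  iin <- classes == "induced"
  pars$half_time[iin] <- stats::runif(sum(iin), 2, 8)
  pars$hill_n[iin] <- 2
  irp <- classes == "repressed"
  nrp <- sum(irp)
  pars$tau_drop[irp] <- 0.6
  pars$tau_rec[irp] <- stats::runif(nrp, 4, 8)
  pars$lag[irp] <- 2
  n_gata <- round(config$gata3_fraction * nrp)
  rec <- rep(0, nrp)
  if (n_gata > 0) rec[sample.int(nrp, n_gata)] <- config$recovery_fraction
  pars$recovery[irp] <- rec

  responsive <- classes != "null"
  resp_ids <- genes[responsive]
  n_targets <- min(config$n_targets, length(resp_ids))
  # spread targets evenly over the three responsive classes
  targets <- character(0)
  if (n_targets > 0) {
    by_class <- split(resp_ids, classes[resp_ids])
    quota <- apportion_classes(rep(1 / length(by_class), length(by_class)),
                               n_targets)
    targets <- unlist(lapply(seq_along(by_class), function(i) {
      pool <- by_class[[i]]
      sample(pool, min(quota[i], length(pool)))
    }), use.names = FALSE)
  }

  effect <- rep(config$effect_size, config$n_genes)
  names(effect) <- genes
  effect[targets] <- config$effect_size * config$target_amplitude_boost

  means <- matrix(NA_real_, config$n_genes, length(tp),
                  dimnames = list(genes, as.character(tp)))
  for (i in seq_len(config$n_genes)) {
    means[i, ] <- config$baseline_mean *
      rel_trajectory(classes[i], tp, effect[i], pars[i, ], t_end)
  }
  if (any(means < 0)) stop("negative latent mean generated; check config")

  truth <- list(classes = classes,
                params = pars,
                responsive = responsive,
                planted_targets = sort(targets),
                effect = effect)
  list(means = means, truth = truth)
}

# save/restore the global RNG state so generator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample negative-binomial counts from latent means
#'
#' Draws independent NB counts with `Var = m + alpha * m^2` around
#' `m = sf_s * mu_g(t_s)`; `alpha = 0` falls back to Poisson sampling.
#' Sample columns follow the metadata layout `t<time>_r<replicate>`.
#'
#' @param means gene x timepoint latent mean matrix (columns named by hour).
#' @param config a [simulation_config()]; its `dispersion`,
#'   `library_size_factors`, `n_replicates` and `seed` are used.
#' @param seed_label stream label so mRNA and miRNA draws are independent.
#' @return list with `counts` (integer matrix), `meta` (sample metadata) and
#'   `size_factors` (true per-sample depth multipliers).
#' @export
sample_counts <- function(means, config, seed_label = "counts") {
  stopifnot(all(means >= 0))
  tp <- as.numeric(colnames(means))
  nrep <- config$n_replicates
  ns <- length(tp) * nrep
  meta <- data.frame(
    time_h = rep(tp, each = nrep),
    replicate = rep(seq_len(nrep), length(tp)),
    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("t%g_r%d", meta$time_h,
                                         meta$replicate),
                     meta, stringsAsFactors = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, paste0(seed_label, "_sf")))
  sf <- config$library_size_factors
  if (is.null(sf)) sf <- exp(stats::rnorm(ns, 0, 0.15))
  if (length(sf) != ns) stop("need one library size factor per sample")

  set.seed(derive_seed(config$seed, seed_label))
  mu <- means[, rep(seq_along(tp), each = nrep), drop = FALSE]
  mu <- sweep(mu, 2, sf, `*`)
  n <- length(mu)
  x <- if (config$dispersion > 0) {
    stats::rnbinom(n, size = 1 / config$dispersion, mu = as.vector(mu))
  } else {
    stats::rpois(n, as.vector(mu))
  }
  counts <- matrix(as.integer(x), nrow(means), ns,
                   dimnames = list(rownames(means), meta$sample_id))
  list(counts = counts, meta = meta, size_factors = sf)
}

#' Generate latent miRNA profiles and the miRNA ground truth
#'
#' The first `n_master_mirnas` miRNAs follow a saturating induction reaching
#' exactly `mirna_master_fold` times their baseline at the final timepoint;
#' all remaining miRNAs are flat, with baselines drawn log-normally around
#' the configured mean so the expression filter is exercised.
#'
#' @param config a [simulation_config()].
#' @return list with `means` (miRNA x timepoint) and `truth` (master ids,
#'   responsive flags).
#' @export
generate_mirna_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints
  t_end <- max(tp)
  ids <- sprintf("mir-%03d", seq_len(config$n_mirnas))
  masters <- ids[seq_len(config$n_master_mirnas)]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "mirna_profiles"))
  base <- exp(stats::rnorm(config$n_mirnas, log(config$mirna_baseline_mean), 1))
  base[seq_along(masters)] <- config$mirna_baseline_mean

  means <- matrix(rep(base, length(tp)), config$n_mirnas, length(tp),
                  dimnames = list(ids, as.character(tp)))
  fold <- config$mirna_master_fold
  if (fold < 1) stop("mirna_master_fold must be >= 1")
  rise <- hill_rise(tp, half_time = 10, n = 2, t_end = t_end)
  for (m in seq_along(masters)) {
    means[m, ] <- base[m] * (1 + (fold - 1) * rise)
  }
  truth <- list(master_mirnas = masters,
                responsive = stats::setNames(ids %in% masters & fold > 1, ids))
  list(means = means, truth = truth)
}

#' Generate a miRNA seed table with distinct families
#'
#' Draws random 22-nt mature RNA sequences whose extended seeds (nucleotides
#' 2-8) are pairwise distinct, so each miRNA founds its own family.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `mirna_id`, `family_id`,
#'   `mature_sequence` (RNA alphabet, 5' to 3').
#' @export
generate_seed_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "seed_table"))
  n <- config$n_mirnas
  rna <- c("A", "C", "G", "U")
  seqs <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(rna, 22, replace = TRUE), collapse = "")
      seed7 <- substr(s, 2, 8)
      if (!(seed7 %in% seen)) { seen <- c(seen, seed7); break }
    }
    seqs[i] <- s
  }
  data.frame(mirna_id = sprintf("mir-%03d", seq_len(n)),
             family_id = sprintf("fam-%03d", seq_len(n)),
             mature_sequence = seqs,
             stringsAsFactors = FALSE)
}

# DNA site patterns recognized for a 7-nt extended seed (RNA, nt 2-8):
# 7mer-m8 = revcomp(nt2-8); 8mer = 7mer-m8 + A; 7mer-1A = revcomp(nt2-7) + A
seed_patterns <- function(seed7) {
  if (nchar(seed7) != 7) stop("extended seed must be 7 nt")
  dna <- chartr("Uu", "Tt", toupper(seed7))
  m8 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  list(m8 = m8, eight = paste0(m8, "A"),
       one_a = paste0(substr(m8, 2, 7), "A"))
}

#' Generate random background 3'-UTR sequences
#'
#' I.i.d. uniform ACGT sequences with lengths drawn uniformly from a range;
#' no seed-site scrubbing is applied (see [generate_utrs()] for the
#' ground-truthed, scrubbed generator).
#'
#' @param n number of sequences.
#' @param length_range min/max length (nt).
#' @param seed RNG seed.
#' @param ids sequence names (default `gene0001`...).
#' @return a [Biostrings::DNAStringSet].
#' @export
random_utrs <- function(n, length_range = c(300, 500), seed = 1, ids = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  if (is.null(ids)) ids <- sprintf("gene%04d", seq_len(n))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Generate ground-truthed 3'-UTR sequences with planted seed sites
#'
#' Background sequence is i.i.d. uniform ACGT, rejection-sampled (when
#' `scrub_background` is set) so that no 8mer, 7mer-m8 or 7mer-1A match to
#' any configured miRNA family occurs anywhere. Each planted target gene
#' then receives `sites_per_target` 8mer sites of its master miRNA family at
#' recorded positions; planting is re-drawn if the insertion creates an
#' unintended match at a junction.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [generate_gene_profiles()] (supplies gene
#'   ids and planted target ids).
#' @param seed_table miRNA seed table from [generate_seed_table()].
#' @param max_attempts redraw bound per sequence before failing.
#' @return list with `utrs` (named [Biostrings::DNAStringSet]) and
#'   `planted_sites` (per target gene, 0-based start positions of the
#'   planted 8mer sites).
#' @export
generate_utrs <- function(config, truth, seed_table, max_attempts = 200) {
  stopifnot(inherits(config, "sim_config"))
  genes <- names(truth$classes)
  n <- length(genes)
  lo <- config$utr_length_range[1]
  hi <- config$utr_length_range[2]

  pats <- lapply(substr(seed_table$mature_sequence, 2, 8), seed_patterns)
  # scrubbing the two 7-mer classes removes all three site classes
  forbidden <- unique(unlist(lapply(pats, function(p) c(p$m8, p$one_a))))
  # the master family is (by construction) the first seed-table entry
  master_row <- 1L
  site8 <- pats[[master_row]]$eight

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "utrs"))

  lens <- sample(seq(lo, hi), n, replace = TRUE)
  draw <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")
  seqs <- vapply(lens, draw, character(1))

  if (config$scrub_background) {
    dirty <- rep(TRUE, n)
    attempts <- 0
    while (any(dirty)) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("could not scrub background UTRs of accidental seed matches ",
             "after ", max_attempts, " rounds; fewer families or longer ",
             "UTRs required")
      ss <- Biostrings::DNAStringSet(seqs[dirty])
      hit <- rep(FALSE, sum(dirty))
      for (p in forbidden) {
        hit <- hit | Biostrings::vcountPattern(p, ss) > 0
      }
      idx <- which(dirty)
      dirty[idx[!hit]] <- FALSE
      for (i in idx[hit]) seqs[i] <- draw(lens[i])
    }
  }

  planted <- list()
  targets <- intersect(truth$planted_targets, genes)
  k <- config$sites_per_target
  for (g in targets) {
    gi <- match(g, genes)
    L <- lens[gi]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      s <- seqs[gi]
      # evenly spaced, non-overlapping planting positions (1-based starts)
      pos <- round(seq_len(k) * L / (k + 1)) - 4
      pos <- pmin(pmax(pos, 1), L - 7)
      if (k > 1 && any(diff(sort(pos)) < 8)) {
        pos <- seq(1, L - 7, length.out = k)
        pos <- round(pos)
      }
      for (p in pos) substr(s, p, p + 7) <- site8
      if (!config$scrub_background || utr_plant_clean(s, forbidden, pats,
                                                      master_row, pos)) {
        seqs[gi] <- s
        planted[[g]] <- sort(as.integer(pos - 1))
        ok <- TRUE
        break
      }
      seqs[gi] <- draw(L)  # junction artifact: redraw background and retry
    }
    if (!ok) stop("could not plant sites in gene ", g, " without creating ",
                  "unintended seed matches")
  }

  utrs <- Biostrings::DNAStringSet(seqs)
  names(utrs) <- genes
  list(utrs = utrs, planted_sites = planted)
}

# check a planted sequence: every family-site match must be explained by the
# planted 8mers (which contain one 7mer-m8 at p and one 7mer-1A at p+1)
utr_plant_clean <- function(s, forbidden, pats, master_row, pos1) {
  d <- Biostrings::DNAString(s)
  allowed_m8 <- pos1
  allowed_1a <- pos1 + 1
  mp <- pats[[master_row]]
  for (p in forbidden) {
    st <- Biostrings::start(Biostrings::matchPattern(p, d))
    if (!length(st)) next
    ok <- if (p == mp$m8) st %in% allowed_m8
          else if (p == mp$one_a) st %in% allowed_1a
          else rep(FALSE, length(st))
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs the full generator: latent gene and miRNA profiles, NB count
#' sampling, seed table and planted 3'-UTRs.
#'
#' @param config a [simulation_config()].
#' @return list of class `sim_dataset` with elements `mrna_counts`,
#'   `mirna_counts`, `meta`, `utrs`, `seed_table`, `truth`, `latent`
#'   (gene and miRNA latent means) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  gp <- generate_gene_profiles(config)
  mp <- generate_mirna_profiles(config)
  st <- generate_seed_table(config)
  ut <- generate_utrs(config, gp$truth, st)
  sc <- sample_counts(gp$means, config, "mrna_counts")
  sm <- sample_counts(mp$means, config, "mirna_counts")
  truth <- gp$truth
  truth$master_mirnas <- mp$truth$master_mirnas
  truth$mirna_responsive <- mp$truth$responsive
  truth$planted_sites <- ut$planted_sites
  out <- list(mrna_counts = sc$counts,
              mirna_counts = sm$counts,
              meta = sc$meta,
              utrs = ut$utrs,
              seed_table = st,
              truth = truth,
              latent = list(gene_means = gp$means, mirna_means = mp$means,
                            size_factors = sc$size_factors),
              config = config)
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to disk
#'
#' Produces `mrna_counts.tsv`, `mirna_counts.tsv`, `metadata.tsv`,
#' `utrs.fa`, `mirna_seeds.tsv` and `truth.json`; reading the files back
#' with [read_dataset()] reproduces the matrices exactly.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wf <- function(fn) file.path(out_dir, fn)
  write_counts_tsv(dataset$mrna_counts, wf("mrna_counts.tsv"), "gene_id")
  write_counts_tsv(dataset$mirna_counts, wf("mirna_counts.tsv"), "mirna_id")
  write_tsv(dataset$meta, wf("metadata.tsv"))
  Biostrings::writeXStringSet(dataset$utrs, wf("utrs.fa"))
  write_tsv(dataset$seed_table, wf("mirna_seeds.tsv"))
  tr <- dataset$truth
  truth_json <- list(
    classes = as.list(tr$classes),
    responsive = list(genes = names(tr$classes)[tr$responsive],
                      mirnas = names(which(tr$mirna_responsive))),
    master_mirnas = tr$master_mirnas,
    planted_targets = if (length(tr$planted_sites)) tr$planted_sites
                      else stats::setNames(list(), character(0)))
  jsonlite::write_json(truth_json, wf("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the dataset files.
#' @return list with `mrna_counts`, `mirna_counts`, `meta`, `utrs`,
#'   `seed_table` and `truth`.
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(mrna_counts = read_counts_tsv(file.path(dir, "mrna_counts.tsv")),
       mirna_counts = read_counts_tsv(file.path(dir, "mirna_counts.tsv")),
       meta = read_metadata_tsv(file.path(dir, "metadata.tsv")),
       utrs = Biostrings::readDNAStringSet(file.path(dir, "utrs.fa")),
       seed_table = utils::read.delim(file.path(dir, "mirna_seeds.tsv"),
                                      stringsAsFactors = FALSE),
       truth = truth)
}
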