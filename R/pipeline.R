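#' Pipeline configuration
#'
#' Collects all stage parameters with the standard thresholds as defaults:
#' responsive mRNAs need mean normalized expression >= 500 and a significant
#' (BH-adjusted p < 0.05) >= twofold change versus time zero; miRNAs need a
#' mean of >= 50 RPMM and a >= 1.5-fold change at uncorrected p <= 0.05.
#'
#' @param min_mean_mrna mRNA mean normalized expression filter.
#' @param fc_mrna mRNA fold-change threshold (2 = twofold).
#' @param alpha_adj adjusted p-value threshold for mRNAs.
#' @param min_rpmm miRNA expression filter (RPMM).
#' @param fc_mirna miRNA fold-change threshold.
#' @param alpha_mirna uncorrected p-value threshold for miRNAs.
#' @param k number of temporal clusters.
#' @param grid_by interpolation grid step (hours).
#' @param linkage clustering linkage.
#' @param gamma characteristic-direction shrinkage.
#' @param theta characteristic-set cumulative-energy threshold.
#' @param selection_rule characteristic-set rule.
#' @param n_perm Monte-Carlo permutations per enrichment cell.
#' @param score_mode enrichment scoring mode.
#' @param length_match match null sets by UTR-length decile.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_mrna = 500, fc_mrna = 2,
                            alpha_adj = 0.05, min_rpmm = 50,
                            fc_mirna = 1.5, alpha_mirna = 0.05,
                            k = 3, grid_by = 1, linkage = "ward.D2",
                            gamma = 0.5, theta = 0.5,
                            selection_rule = "cumulative_energy",
                            n_perm = 1000, score_mode = "binary",
                            length_match = FALSE, seed = 1) {
  cfg <- as.list(environment())
  bad <- names(Filter(function(v) is.numeric(v) && v <= 0,
                      cfg[c("min_mean_mrna", "fc_mrna", "alpha_adj",
                            "min_rpmm", "fc_mirna", "alpha_mirna", "k",
                            "grid_by", "gamma", "theta", "n_perm")]))
  bad <- setdiff(bad, "gamma")  # gamma = 0 is a valid (pure-shrinkage) choice
  if (length(bad)) stop("thresholds must be positive: ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Validate referential integrity of a dataset bundle
#'
#' Checks that every sample has metadata (and vice versa), that genes in
#' the count matrix have UTR records, and that sequences are well formed.
#' Missing UTRs are warnings (those genes are skipped in enrichment);
#' samples without metadata and malformed sequences are fatal.
#'
#' @param data a dataset list as returned by [read_dataset()].
#' @return list with `fatal` and `warnings` (character vectors); zero fatal
#'   issues means the bundle is runnable.
#' @export
validate_inputs <- function(data) {
  fatal <- character(0)
  warn <- character(0)
  miss_meta <- setdiff(colnames(data$mrna_counts), data$meta$sample_id)
  if (length(miss_meta))
    fatal <- c(fatal, paste0("mRNA sample(s) without metadata: ",
                             paste(miss_meta, collapse = ", ")))
  miss_meta2 <- setdiff(colnames(data$mirna_counts), data$meta$sample_id)
  if (length(miss_meta2))
    fatal <- c(fatal, paste0("miRNA sample(s) without metadata: ",
                             paste(miss_meta2, collapse = ", ")))
  no_utr <- setdiff(rownames(data$mrna_counts), names(data$utrs))
  if (length(no_utr))
    warn <- c(warn, paste0(length(no_utr), " gene(s) without UTR (excluded ",
                           "from enrichment): ",
                           paste(utils::head(no_utr, 5), collapse = ", ")))
  bad_seq <- names(data$utrs)[grepl("[^ACGTU]",
                                    toupper(as.character(data$utrs)))]
  if (length(bad_seq))
    fatal <- c(fatal, paste0("UTR(s) with non-ACGT/U characters: ",
                             paste(bad_seq, collapse = ", ")))
  seqs <- toupper(data$seed_table$mature_sequence)
  bad_mi <- data$seed_table$mirna_id[grepl("[^ACGU]", chartr("T", "U", seqs))]
  if (length(bad_mi))
    fatal <- c(fatal, paste0("miRNA mature sequence(s) with non-RNA ",
                             "characters: ", paste(bad_mi, collapse = ", ")))
  if (any(data$mrna_counts < 0) || any(data$mirna_counts < 0))
    fatal <- c(fatal, "negative counts present")
  list(fatal = fatal, warnings = warn)
}

#' Simulate a dataset and write it to disk with a manifest
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(sim_config = simulation_config(), out_dir) {
  ds <- simulate_dataset(sim_config)
  write_dataset(ds, out_dir)
  manifest <- list(
    stage = "simulate",
    config = unclass(sim_config)[!vapply(unclass(sim_config), is.null,
                                         logical(1))],
    checksums = as.list(tools::md5sum(list.files(out_dir,
                                                 full.names = TRUE))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest$checksums$manifest.json <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the full integrative pipeline
#'
#' Executes every stage on a dataset bundle: mRNA differential expression
#' and the responsiveness filters, timepoint census, temporal clustering of
#' the responsive genes, miRNA response analysis, characteristic-direction
#' gene sets for all consecutive intervals, seed-site enrichment of every
#' expressed miRNA family, and the master-regulator ranking. All stage
#' tables are written as TSV plus a `summary.json` and a `manifest.json`
#' (config, derived seeds and output checksums; no timestamps, so identical
#' inputs give identical bytes).
#'
#' @param data dataset list ([read_dataset()] output or a `sim_dataset`).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return list with all stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_full <- function(data, out_dir, config = pipeline_config()) {
  if (inherits(data, "sim_dataset")) {
    data <- list(mrna_counts = data$mrna_counts,
                 mirna_counts = data$mirna_counts, meta = data$meta,
                 utrs = data$utrs, seed_table = data$seed_table,
                 truth = data$truth)
  }
  chk <- validate_inputs(data)
  for (w in chk$warnings) warning(w, call. = FALSE)
  if (length(chk$fatal))
    stop("input validation failed:\n  ", paste(chk$fatal, collapse = "\n  "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wf <- function(fn) file.path(out_dir, fn)

  stage <- "differential expression"
  res <- tryCatch({
    de <- de_table(data$mrna_counts, data$meta)
    resp <- select_responsive_genes(de, config$min_mean_mrna,
                                    log2(config$fc_mrna), config$alpha_adj)
    census <- if (nrow(resp)) census_timepoints(de, resp,
                                min_abs_log2fc = log2(config$fc_mrna),
                                alpha = config$alpha_adj) else NULL

    stage <- "temporal clustering"
    clust <- if (nrow(resp) >= config$k)
      temporal_clustering(de$normalized, data$meta, resp$gene,
                          k = config$k,
                          grid = seq(0, max(data$meta$time_h),
                                     by = config$grid_by),
                          linkage = config$linkage)
    else NULL

    stage <- "miRNA response"
    rpmm <- rpmm_normalize(data$mirna_counts)
    mir <- test_mirna_response(rpmm, data$meta,
                               thresholds = c(config$fc_mirna, 2),
                               alpha = config$alpha_mirna,
                               min_mean = config$min_rpmm)

    stage <- "characteristic directions"
    ivs <- consecutive_interval_sets(de$normalized, data$meta,
                                     gamma = config$gamma,
                                     rule = config$selection_rule,
                                     theta = config$theta)

    stage <- "target enrichment"
    fams <- group_families(data$seed_table, rowMeans(rpmm),
                           min_mean = config$min_rpmm)
    bg <- intersect(rownames(data$mrna_counts), names(data$utrs))
    utrs <- data$utrs[bg]
    sc <- target_site_counts(utrs, fams)
    sets <- lapply(ivs, function(s) intersect(s$genes, bg))
    em <- enrichment_matrix(fams, sets, bg, sc, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "enrichment"),
                            mode = config$score_mode)
    ranking <- rank_master_regulators(em)
    top_targets <- predicted_targets_in_sets(ranking$family_id[1], sets, sc)
    list(de = de, responsive = resp, census = census, clustering = clust,
         rpmm = rpmm, mirna = mir, interval_sets = ivs, families = fams,
         enrichment = em, ranking = ranking, top_targets = top_targets)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  # stage outputs
  det <- res$de$table
  det$p_adj <- res$de$table$p_adj
  write_tsv(det, wf("de_table.tsv"))
  resp_out <- res$responsive
  if (!is.null(res$clustering)) {
    resp_out$class <- unname(res$clustering$gene_labels[resp_out$gene])
  } else resp_out$class <- NA_character_
  write_tsv(resp_out, wf("responsive_genes.tsv"))
  if (!is.null(res$clustering)) {
    cl <- res$clustering
    write_tsv(data.frame(gene = names(cl$assignment$cluster),
                         cluster = unname(cl$assignment$cluster),
                         label = unname(cl$gene_labels),
                         stringsAsFactors = FALSE), wf("clusters.tsv"))
    cent <- data.frame(label = rownames(cl$centroids), cl$centroids,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(cent, wf("centroids.tsv"))
  }
  write_tsv(res$mirna$table, wf("mirna_response.tsv"))
  cd_rows <- do.call(rbind, lapply(names(res$interval_sets), function(nm) {
    r <- res$interval_sets[[nm]]$ranking
    r$interval <- nm
    r
  }))
  write_tsv(cd_rows, wf("characteristic_genes.tsv"))
  emx <- res$enrichment$neglog10_p
  write_tsv(data.frame(family_id = rownames(emx), emx, check.names = FALSE,
                       stringsAsFactors = FALSE), wf("enrichment_matrix.tsv"))
  write_tsv(res$ranking, wf("ranking.tsv"))
  write_tsv(res$top_targets, wf("top_family_targets.tsv"))

  class_counts <- if (!is.null(res$clustering))
    as.list(table(res$clustering$gene_labels)) else list()
  summary <- list(
    schema_version = "1.0",
    n_genes = nrow(data$mrna_counts),
    n_responsive_genes = nrow(res$responsive),
    class_counts = class_counts,
    census_histogram = if (!is.null(res$census))
      as.list(stats::setNames(as.integer(res$census$histogram),
                              names(res$census$histogram))) else list(),
    n_expressed_mirnas = length(res$mirna$expressed),
    responsive_mirnas = res$mirna[[paste0("responsive_",
      sub("\\.", "p", as.character(config$fc_mirna)))]],
    top_families = utils::head(res$ranking$family_id, 5),
    top_family_targets = res$top_targets$gene)
  jsonlite::write_json(summary, wf("summary.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    stage = "run_full",
    config = unclass(config),
    derived_seeds = list(enrichment = derive_seed(config$seed, "enrichment")),
    checksums = local({
      fls <- setdiff(list.files(out_dir), "manifest.json")
      as.list(stats::setNames(unname(tools::md5sum(file.path(out_dir, fls))),
                              fls))
    }))
  jsonlite::write_json(manifest, wf("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}
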