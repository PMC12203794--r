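#' Run the full discovery cascade
#'
#' Orchestrates every stage under one configuration: simulate (or load) the
#' cohorts; split the methylation cohort by driver median expression; run the
#' EWAS and the combined-p DMR caller; assign hypermethylated genes; run
#' differential expression; intersect into candidate silenced genes; screen
#' the candidates for survival consensus across all cohorts; rank genetic
#' alteration frequencies; stratify the top-ranked target into METH / LOFDEL
#' / CTRL; summarise the strata; and run the two pre-ranked GSEA contrasts.
#' One structured log line is emitted per stage with its input/output counts.
#'
#' @param config a `pipeline_config` (or YAML path / named list accepted by
#'   [validate_config()]); must carry either a `simulation` block or an
#'   `input_dir` of cohort bundle subdirectories.
#' @param outdir optional output directory; when given, intermediates
#'   (EWAS TSV, DMR BED, DE TSV, screen TSV, stratum TSV) and the report
#'   (`report.json`, `report.txt`) are written there.
#' @param force overwrite an existing non-empty `outdir`.
#' @return A list of class `discovery_report`: stage counts, candidate and
#'   consensus tables, alteration ranking, stratum frequencies, combined
#'   inactivation percentage for the top gene, GSEA category table, the full
#'   config echo and derived seeds.
#' @export
run_discovery <- function(config, outdir = NULL, force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
      abort(paste0("outdir '", outdir, "' is not empty; use force = TRUE"))
    }
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }
  log_stage <- function(stage, ...) {
    inform(paste0("[", stage, "] ", paste0(names(c(...)), "=", c(...), collapse = " ")))
  }

  # --- cohorts ---------------------------------------------------------------
  truths <- NULL
  if (!is.null(cfg$simulation)) {
    sims <- simulate_multicohort(cfg$simulation)
    bundles <- lapply(sims, `[[`, "bundle")
    truths <- lapply(sims, `[[`, "truth")
  } else if (!is.null(cfg$input_dir)) {
    dirs <- list.dirs(cfg$input_dir, recursive = FALSE)
    if (length(dirs) == 0) abort("input_dir contains no cohort subdirectories")
    bundles <- lapply(dirs, read_cohort_bundle)
  } else {
    abort("config needs a `simulation` block or an `input_dir`")
  }
  meth_idx <- which(vapply(bundles, function(b) !is.null(b$methylation), logical(1)))
  if (length(meth_idx) == 0) abort("no cohort carries methylation data")
  b0 <- bundles[[meth_idx[1]]]
  log_stage("cohorts", n_cohorts = length(bundles),
            methylation_cohort = b0$cohort_id,
            n_samples = ncol(b0$expression))

  # --- driver split + DMR calling -------------------------------------------
  groups <- split_by_driver(b0$expression, cfg$driver_gene)
  scan <- call_dmrs(b0$methylation, groups, b0$manifest,
                    seed_p = cfg$dmr_seed_p, dist = cfg$dmr_dist,
                    region_filter_p = cfg$dmr_region_filter_p,
                    region_filter_n = cfg$dmr_region_filter_n)
  gene_calls <- assign_regions_to_genes(scan$dmrs, b0$manifest,
                                        gene_dmr_p = cfg$gene_dmr_p)
  hyper_genes <- dplyr::filter(gene_calls, .data$hypermethylated)
  log_stage("dmr", n_probes = nrow(scan$ewas), n_regions = nrow(scan$dmrs),
            n_hypermethylated_genes = nrow(hyper_genes))

  # --- differential expression + intersection -------------------------------
  de <- differential_expression(b0$expression, groups,
                                fc_threshold = cfg$de_fc_threshold,
                                adj_p = cfg$de_adj_p, test = cfg$de_test)
  n_down <- sum(de$call == "down")
  n_up <- sum(de$call == "up")
  candidates <- intersect_silenced(gene_calls, de)
  stopifnot(nrow(candidates) <= min(nrow(hyper_genes), n_down))
  log_stage("diffexpr", n_genes = nrow(de), n_down = n_down, n_up = n_up,
            n_intersection = nrow(candidates))

  # --- survival consensus ----------------------------------------------------
  screen <- gene_survival_screen(bundles, candidates$gene,
                                 alpha = cfg$survival_alpha,
                                 min_cohorts = cfg$consensus_min_cohorts)
  consensus_genes <- screen$consensus$gene[screen$consensus$passes]
  yield <- if (nrow(candidates) > 0) {
    consensus_yield_pct(length(consensus_genes), nrow(candidates))
  } else NA_real_
  log_stage("survival", n_candidates = nrow(candidates),
            n_consensus = length(consensus_genes))

  # --- alteration ranking + stratification ----------------------------------
  universe <- colnames(b0$expression)
  alt_genes <- if (nrow(candidates) > 0) candidates$gene else character(0)
  alt <- if (length(alt_genes) > 0) {
    alteration_frequencies(b0$mutations, b0$cnas, universe, alt_genes)
  } else {
    tibble::tibble(gene = character(), f_lof = numeric(),
                   f_del = numeric(), f_total = numeric())
  }
  top_gene <- if (nrow(alt) > 0 && max(alt$f_total) > 0) alt$gene[1] else NA_character_
  strata <- NULL
  strat_freq <- NULL
  combined_pct <- NA_real_
  summaries <- NULL
  if (!is.na(top_gene)) {
    strata <- stratify_target(b0, cfg$driver_gene, top_gene)
    strat_freq <- stratum_frequencies(strata)
    combined_pct <- combined_inactivation_pct(strata)
    summaries <- tryCatch(stratum_summaries(strata, b0$clinical),
                          error = function(e) NULL)
    log_stage("stratify", target = top_gene,
              combined_pct = sprintf("%.2f", combined_pct))
  } else {
    log_stage("stratify", target = "none")
  }

  # --- GSEA ------------------------------------------------------------------
  gsea_meth <- NULL
  gsea_lofdel <- NULL
  gsea_table <- NULL
  if (!is.null(strata)) {
    sets <- if (!is.null(cfg$gmt)) {
      read_gmt(cfg$gmt)
    } else {
      planted <- if (!is.null(truths)) truths[[meth_idx[1]]]$target_genes else NULL
      simulate_gene_sets(setdiff(rownames(b0$expression), cfg$driver_gene),
                         planted = planted,
                         seed = derive_seed(cfg$rng_seed, 77L))
    }
    s_meth <- strata$sample_id[strata$stratum == "METH"]
    s_lofdel <- strata$sample_id[strata$stratum == "LOFDEL"]
    s_ctrl <- strata$sample_id[strata$stratum == "CTRL"]
    run_contrast <- function(sa, tag) {
      if (length(sa) < 2) return(NULL)
      ranked <- rank_genes(b0$expression, sa, s_ctrl)
      permutation_significance(ranked, sets, nperm = cfg$gsea_nperm,
                               weight = cfg$gsea_weight,
                               seed = derive_seed(cfg$rng_seed, 88L, tag),
                               nominal_p = cfg$gsea_nominal_p,
                               fdr = cfg$gsea_fdr)
    }
    gsea_meth <- run_contrast(s_meth, 1L)
    gsea_lofdel <- run_contrast(s_lofdel, 2L)
    if (!is.null(gsea_meth) && !is.null(gsea_lofdel)) {
      gsea_table <- dual_contrast_report(gsea_meth, gsea_lofdel)
    }
    log_stage("gsea", n_sets = length(sets),
              meth_contrast = !is.null(gsea_meth),
              lofdel_contrast = !is.null(gsea_lofdel))
  }

  report <- structure(list(
    counts = list(
      n_cohorts = length(bundles),
      n_probes = nrow(scan$ewas),
      n_dmrs = nrow(scan$dmrs),
      n_hypermethylated = nrow(hyper_genes),
      n_down = n_down,
      n_up = n_up,
      n_intersection = nrow(candidates),
      n_consensus = length(consensus_genes)
    ),
    consensus_yield_pct = yield,
    candidates = candidates,
    consensus = screen$consensus,
    survival_results = screen$results,
    alteration_table = alt,
    top_gene = top_gene,
    stratum_frequencies = strat_freq,
    combined_inactivation_pct = combined_pct,
    stratum_summaries = summaries,
    gsea_meth = gsea_meth,
    gsea_lofdel = gsea_lofdel,
    gsea_categories = gsea_table,
    config = unclass(cfg)[setdiff(names(cfg), "simulation")],
    simulation = if (!is.null(cfg$simulation)) unclass(cfg$simulation) else NULL,
    rng_seed = cfg$rng_seed,
    truth = if (!is.null(truths)) truths[[meth_idx[1]]] else NULL
  ), class = "discovery_report")

  if (!is.null(outdir)) {
    write_report_files(report, scan, de, screen, strata, outdir)
  }
  report
}

write_report_files <- function(report, scan, de, screen, strata, outdir) {
  readr::write_tsv(scan$ewas, file.path(outdir, "ewas.tsv"), progress = FALSE)
  if (nrow(scan$dmrs) > 0) {
    write_dmr_bed(scan$dmrs, file.path(outdir, "dmrs.bed"))
  }
  readr::write_tsv(tibble::as_tibble(de), file.path(outdir, "diffexpr.tsv"),
                   progress = FALSE)
  readr::write_tsv(screen$results, file.path(outdir, "survival_screen.tsv"),
                   progress = FALSE)
  if (!is.null(strata)) {
    readr::write_tsv(tibble::as_tibble(strata), file.path(outdir, "strata.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(report_as_json(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)), file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Serialise a discovery report to plain lists (JSON-ready)
#' @param report a `discovery_report`.
#' @return A nested list safe for [jsonlite::write_json()].
#' @export
report_as_json <- function(report) {
  drop_listcols <- function(df) {
    if (is.null(df)) return(NULL)
    df <- tibble::as_tibble(df)
    df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  }
  list(
    counts = report$counts,
    consensus_yield_pct = report$consensus_yield_pct,
    candidates = drop_listcols(report$candidates),
    consensus = drop_listcols(report$consensus),
    alteration_table = drop_listcols(report$alteration_table),
    top_gene = report$top_gene,
    stratum_frequencies = drop_listcols(report$stratum_frequencies),
    combined_inactivation_pct = report$combined_inactivation_pct,
    gsea_categories = drop_listcols(report$gsea_categories),
    config = report$config,
    simulation = report$simulation,
    rng_seed = report$rng_seed
  )
}

#' @export
print.discovery_report <- function(x, ...) {
  c0 <- x$counts
  cat("Discovery report\n")
  cat(sprintf("  cohorts: %d (probes tested: %d)\n", c0$n_cohorts, c0$n_probes))
  cat(sprintf("  DMRs called: %d -> hypermethylated genes: %d\n",
              c0$n_dmrs, c0$n_hypermethylated))
  cat(sprintf("  differential expression: %d down / %d up\n", c0$n_down, c0$n_up))
  cat(sprintf("  intersection (hypermethylated & down): %d\n", c0$n_intersection))
  cat(sprintf("  survival consensus (>= %d cohorts): %d (yield %.1f%%)\n",
              x$config$consensus_min_cohorts, c0$n_consensus,
              ifelse(is.na(x$consensus_yield_pct), NA, x$consensus_yield_pct)))
  if (!is.na(x$top_gene)) {
    cat(sprintf("  top altered gene: %s (combined inactivation %.1f%%)\n",
                x$top_gene, x$combined_inactivation_pct))
  }
  if (!is.null(x$gsea_categories)) {
    tab <- table(x$gsea_categories$category)
    cat("  GSEA categories:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
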