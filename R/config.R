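#' Pipeline configuration
#'
#' Assembles the tunable parameters of the discovery cascade with their
#' defaults: the driver gene and its median split, the DMR caller options
#' (seed p 1e-5, window 1000 bp, region filter p 0.05, minimum 2 probes, gene
#' threshold 1e-5 on the Sidak-corrected region p), the differential
#' expression thresholds (fold change 1.5, BH-adjusted p 0.05, Welch t by
#' default), the survival consensus rule (both Cox and log-rank p < 0.05 with
#' HR < 1 in at least 3 cohorts), and the GSEA settings (1000 permutations,
#' weight 1, nominal p < 0.05 and FDR < 0.25).
#'
#' @param ... named overrides of any default listed above.
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    driver_gene = "DNMT3B",
    split_rule = "median",
    dmr_seed_p = 1e-5,
    dmr_dist = 1000,
    dmr_region_filter_p = 0.05,
    dmr_region_filter_n = 2L,
    gene_dmr_p = 1e-5,
    de_fc_threshold = 1.5,
    de_adj_p = 0.05,
    de_test = "welch_t",
    survival_alpha = 0.05,
    consensus_min_cohorts = 3L,
    gsea_nperm = 1000L,
    gsea_weight = 1.0,
    gsea_nominal_p = 0.05,
    gsea_fdr = 0.25,
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) && is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), c(names(defaults), "simulation", "input_dir", "gmt"))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.character(cfg$driver_gene) || length(cfg$driver_gene) != 1 ||
      !nzchar(cfg$driver_gene)) {
    abort("`driver_gene` must be a single gene symbol")
  }
  if (!identical(cfg$split_rule, "median")) {
    abort("`split_rule` must be 'median'")
  }
  check_number(cfg$dmr_seed_p, "dmr_seed_p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$dmr_dist, "dmr_dist", 1, Inf)
  check_number(cfg$dmr_region_filter_p, "dmr_region_filter_p", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$dmr_region_filter_n, "dmr_region_filter_n", 1, Inf, integer = TRUE)
  check_number(cfg$gene_dmr_p, "gene_dmr_p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$de_fc_threshold, "de_fc_threshold", 1, Inf)
  check_number(cfg$de_adj_p, "de_adj_p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (!cfg$de_test %in% c("welch_t", "mann_whitney")) {
    abort("`de_test` must be 'welch_t' or 'mann_whitney'")
  }
  check_number(cfg$survival_alpha, "survival_alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$consensus_min_cohorts, "consensus_min_cohorts", 1, Inf, integer = TRUE)
  check_number(cfg$gsea_nperm, "gsea_nperm", 100, Inf, integer = TRUE)
  check_number(cfg$gsea_weight, "gsea_weight", 0, Inf)
  check_number(cfg$gsea_nominal_p, "gsea_nominal_p", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$gsea_fdr, "gsea_fdr", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$rng_seed, "rng_seed", 1, 2^31 - 1, integer = TRUE)
  invisible(cfg)
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys (so typos never pass
#' silently), fills defaults, and range-checks every threshold. The optional
#' `simulation:` block is validated by [simulation_config()].
#'
#' @param path path to a YAML file, or an already-parsed named list.
#' @return A `pipeline_config` list; any `simulation` block is normalised to a
#'   `simulation_config`.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) path else {
    parsed <- yaml::read_yaml(path)
    if (is.null(parsed)) list() else parsed
  }
  sim <- raw$simulation
  raw$simulation <- NULL
  cfg <- pipeline_config(raw)
  if (!is.null(sim)) {
    cfg$simulation <- do.call(simulation_config, sim)
  }
  cfg
}
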