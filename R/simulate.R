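#' Simulation configuration
#'
#' Parameters of the synthetic multi-cohort generator. Defaults describe a
#' breast-cancer-like study: eight cohorts of 300 tumours, a bimodally
#' expressed driver methyltransferase splitting each cohort in half, ten
#' planted target genes whose promoters gain `delta_beta = 0.3` methylation in
#' driver-high samples across five probes spaced 200 bp apart, a 1 log2-unit
#' expression knock-down of silenced targets with residual sd 0.3, an
#' exponential proportional-hazards survival effect of `hazard_coef = -0.7`
#' per SD of target expression, 30% censoring, and loss-of-function lesions of
#' the first target planted in 15% of driver-low samples — strictly outside
#' the methylation-silenced set, so mutual exclusivity holds by construction.
#'
#' @param n_samples samples per cohort.
#' @param frac_driver_high fraction of samples in the driver-high mode.
#' @param n_genes genes in the shared universe (driver gene is added on top).
#' @param n_target_genes planted silenced targets (first one also receives the
#'   genetic lesions).
#' @param probes_per_promoter promoter-class probes per gene.
#' @param probe_spacing_bp spacing between adjacent promoter probes, bp.
#' @param delta_beta planted mean beta shift in driver-high samples at target
#'   promoter probes.
#' @param beta_noise_kappa Beta-distribution concentration; beta values are
#'   drawn from `Beta(mu*kappa, (1-mu)*kappa)` so they respect \eqn{[0,1]}
#'   without clipping.
#' @param expr_log2fc planted downregulation of silenced targets, log2 units.
#' @param expr_noise_sd residual sd of log2 expression.
#' @param hazard_coef log-hazard per SD of the designated target's functional
#'   activity (negative = protective targets); the remaining targets inherit
#'   an attenuated association through the shared driver-driven knock-down.
#' @param baseline_hazard exponential baseline hazard rate.
#' @param censor_rate expected fraction of censored samples.
#' @param frac_lofdel fraction of driver-low samples given a loss-of-function
#'   lesion of the designated target.
#' @param n_cohorts number of cohorts; only the first carries methylation,
#'   mutation and copy-number tables (the others are expression + clinical
#'   only, mirroring typical public validation cohorts).
#' @param rng_seed master seed; every table draws from its own counter-derived
#'   stream so adding one table never perturbs another.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300L,
                              frac_driver_high = 0.5,
                              n_genes = 1000L,
                              n_target_genes = 10L,
                              probes_per_promoter = 5L,
                              probe_spacing_bp = 200L,
                              delta_beta = 0.3,
                              beta_noise_kappa = 50,
                              expr_log2fc = 1.0,
                              expr_noise_sd = 0.3,
                              hazard_coef = -0.7,
                              baseline_hazard = 0.1,
                              censor_rate = 0.3,
                              frac_lofdel = 0.15,
                              n_cohorts = 8L,
                              rng_seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    frac_driver_high = frac_driver_high,
    n_genes = as.integer(n_genes),
    n_target_genes = as.integer(n_target_genes),
    probes_per_promoter = as.integer(probes_per_promoter),
    probe_spacing_bp = as.integer(probe_spacing_bp),
    delta_beta = delta_beta,
    beta_noise_kappa = beta_noise_kappa,
    expr_log2fc = expr_log2fc,
    expr_noise_sd = expr_noise_sd,
    hazard_coef = hazard_coef,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    frac_lofdel = frac_lofdel,
    n_cohorts = as.integer(n_cohorts),
    rng_seed = as.integer(rng_seed)
  )
  check_number(cfg$n_samples, "n_samples", 10, Inf, integer = TRUE)
  check_number(cfg$frac_driver_high, "frac_driver_high", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$n_genes, "n_genes", 2, Inf, integer = TRUE)
  check_number(cfg$n_target_genes, "n_target_genes", 0, cfg$n_genes, integer = TRUE)
  check_number(cfg$probes_per_promoter, "probes_per_promoter", 1, Inf, integer = TRUE)
  check_number(cfg$probe_spacing_bp, "probe_spacing_bp", 1, Inf, integer = TRUE)
  check_number(cfg$delta_beta, "delta_beta", 0, 1)
  check_number(cfg$beta_noise_kappa, "beta_noise_kappa", 1, Inf)
  check_number(cfg$expr_log2fc, "expr_log2fc", 0, Inf)
  check_number(cfg$expr_noise_sd, "expr_noise_sd", 0, Inf, open_lower = TRUE)
  check_number(cfg$hazard_coef, "hazard_coef")
  check_number(cfg$baseline_hazard, "baseline_hazard", 0, Inf, open_lower = TRUE)
  check_number(cfg$censor_rate, "censor_rate", 0, 1, open_upper = TRUE)
  check_number(cfg$frac_lofdel, "frac_lofdel", 0, 1, open_upper = TRUE)
  check_number(cfg$n_cohorts, "n_cohorts", 1, Inf, integer = TRUE)
  check_number(cfg$rng_seed, "rng_seed", 1, 2^31 - 1, integer = TRUE)
  # baseline promoter means are drawn in [0.15, 0.35]; the planted shift must
  # keep the generative mean inside (0, 1)
  if (cfg$delta_beta + 0.35 >= 0.999) {
    abort("delta_beta implies beta means outside [0,1] (baseline means reach 0.35)")
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_gene_universe <- function(cfg) {
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  list(
    driver = "DNMT3B",
    genes = genes,
    targets = genes[seq_len(cfg$n_target_genes)]
  )
}

# Deterministic genome layout shared by all cohorts: genes round-robin across
# 22 chromosomes, promoters 100 kb apart so planted regions never merge.
sim_manifest <- function(cfg) {
  uni <- sim_gene_universe(cfg)
  k <- cfg$probes_per_promoter
  g_idx <- seq_len(cfg$n_genes)
  chrom_i <- (g_idx - 1L) %% 22L + 1L
  slot <- (g_idx - 1L) %/% 22L
  start <- 1e5 * (slot + 1)
  classes <- rep_len(c("TSS1500", "TSS200", "5UTR"), k)
  tibble::tibble(
    probe_id = sprintf("cg%07d", seq_len(cfg$n_genes * k)),
    chrom = rep(sprintf("chr%d", chrom_i), each = k),
    pos = rep(start, each = k) + rep(0:(k - 1), times = cfg$n_genes) * cfg$probe_spacing_bp,
    strand = "+",
    gene = rep(uni$genes, each = k),
    region_class = rep_len(classes, cfg$n_genes * k)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

# Uniform censoring horizon tau such that the expected censored fraction over
# the cohort's exponential hazards equals censor_rate.
censor_horizon <- function(lambda, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  frac_cens <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau)) - censor_rate
  # frac_cens decreases from 1 (tau -> 0) to 0 (tau -> Inf)
  hi <- 1 / min(lambda)
  while (frac_cens(hi) > 0) hi <- hi * 2
  uniroot(frac_cens, c(1e-12, hi), tol = 1e-10)$root
}

#' Simulate one cohort with planted ground truth
#'
#' Generates one cohort bundle under the generative model described in
#' [simulation_config()]: a bimodal driver gene (modes 3 log2 units apart),
#' promoter-probe beta values Beta-distributed around `base + delta_beta` in
#' driver-high samples at target promoters and `base` elsewhere, target
#' expression knocked down by `expr_log2fc` in silenced samples, exponential
#' survival with hazard `baseline_hazard * exp(hazard_coef * score)` where
#' `score` is the mean standardised target expression, independent uniform
#' censoring calibrated to `censor_rate`, and loss-of-function mutations /
#' deep deletions of the first target planted only in driver-low samples.
#'
#' Only cohort index 0 carries methylation, mutation and CNA tables.
#' Deterministic given `(rng_seed, cohort_index)`.
#'
#' @param cfg a [simulation_config()].
#' @param cohort_index 0-based cohort index.
#' @return A list with elements `bundle` (class `cohort_bundle`: `cohort_id`,
#'   `expression`, `methylation`, `manifest`, `clinical`, `mutations`, `cnas`)
#'   and `truth` (class `ground_truth`: driver-high samples, target genes,
#'   methylation-silenced samples, LOF/deletion samples, planted effects).
#' @export
simulate_cohort <- function(cfg, cohort_index = 0L) {
  stopifnot(inherits(cfg, "simulation_config"))
  cohort_index <- as.integer(cohort_index)
  uni <- sim_gene_universe(cfg)
  n <- cfg$n_samples
  cohort_id <- sprintf("cohort%02d", cohort_index)
  samples <- sprintf("%s_S%04d", cohort_id, seq_len(n))
  has_omics <- cohort_index == 0L

  # cohort-independent streams (shared layout / baselines)
  base_expr <- with_seed(derive_seed(cfg$rng_seed, 0L, 1L),
                         runif(cfg$n_genes, 3, 8))
  manifest <- sim_manifest(cfg)
  base_mu <- with_seed(derive_seed(cfg$rng_seed, 0L, 2L),
                       runif(nrow(manifest), 0.15, 0.35))

  # per-(cohort, table) streams
  s_groups <- derive_seed(cfg$rng_seed, cohort_index + 1L, 1L)
  s_expr   <- derive_seed(cfg$rng_seed, cohort_index + 1L, 2L)
  s_meth   <- derive_seed(cfg$rng_seed, cohort_index + 1L, 3L)
  s_clin   <- derive_seed(cfg$rng_seed, cohort_index + 1L, 4L)
  s_mut    <- derive_seed(cfg$rng_seed, cohort_index + 1L, 5L)

  n_high <- max(1L, min(n - 1L, round(n * cfg$frac_driver_high)))
  high_idx <- with_seed(s_groups, sort(sample.int(n, n_high)))
  is_high <- seq_len(n) %in% high_idx
  driver_high_samples <- samples[is_high]

  # genetic lesions of the designated target, driver-low samples only
  designated <- if (cfg$n_target_genes > 0) uni$targets[1] else NA_character_
  mutations <- NULL
  cnas <- NULL
  lofdel_samples <- character(0)
  if (has_omics) {
    low_idx <- which(!is_high)
    n_lof <- if (is.na(designated)) 0L else round(cfg$frac_lofdel * length(low_idx))
    mut_draws <- with_seed(s_mut, {
      pick <- if (n_lof > 0) sort(low_idx[sample.int(length(low_idx), n_lof)]) else integer(0)
      list(
        pick = pick,
        mech = runif(length(pick)),          # < 0.8: LOF mutation, else deep deletion
        cons = sample(lof_consequences(), length(pick), replace = TRUE),
        # background passenger noise: missense calls in random samples/genes
        noise_s = sample.int(n, max(1L, round(0.05 * n))),
        noise_g = sample(uni$genes, max(1L, round(0.05 * n)), replace = TRUE)
      )
    })
    pick <- mut_draws$pick
    lofdel_samples <- samples[pick]
    is_mut <- mut_draws$mech < 0.8
    mutations <- dplyr::bind_rows(
      tibble::tibble(
        sample_id = samples[pick[is_mut]],
        gene = designated,
        consequence = mut_draws$cons[is_mut]
      ),
      tibble::tibble(
        sample_id = samples[mut_draws$noise_s],
        gene = mut_draws$noise_g,
        consequence = "missense_variant"
      )
    )
    cnas <- tibble::tibble(
      sample_id = samples[pick[!is_mut]],
      gene = designated,
      category = -2L
    )
    if (nrow(cnas) == 0) cnas <- cnas[0, ]
  }

  # expression: driver bimodal; targets knocked down in methylation-silenced
  # samples only. Loss-of-function lesions leave the transcript level intact
  # (the mutated mRNA is still expressed); their effect enters the hazard
  # through the functional-activity score below.
  silenced <- matrix(FALSE, nrow = cfg$n_genes, ncol = n,
                     dimnames = list(uni$genes, samples))
  if (cfg$n_target_genes > 0) {
    silenced[uni$targets, is_high] <- TRUE
  }
  expr <- with_seed(s_expr, {
    driver_expr <- ifelse(is_high, rnorm(n, 5, 0.4), rnorm(n, 2, 0.4))
    noise <- matrix(rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd), cfg$n_genes, n)
    m <- matrix(base_expr, cfg$n_genes, n) - cfg$expr_log2fc * silenced + noise
    m <- rbind(matrix(driver_expr, 1, n), m)
    rownames(m) <- c(uni$driver, uni$genes)
    colnames(m) <- samples
    pmax(m, 0)
  })

  # methylation: Beta(mu*kappa, (1-mu)*kappa) around planted means
  methylation <- NULL
  meth_silenced_samples <- character(0)
  if (has_omics) {
    target_probe <- manifest$gene %in% uni$targets
    mu <- matrix(base_mu, nrow(manifest), n)
    mu[target_probe, is_high] <- mu[target_probe, is_high] + cfg$delta_beta
    methylation <- with_seed(s_meth, {
      b <- matrix(rbeta(length(mu), mu * cfg$beta_noise_kappa,
                        (1 - mu) * cfg$beta_noise_kappa),
                  nrow(manifest), n)
      rownames(b) <- manifest$probe_id
      colnames(b) <- samples
      b
    })
    if (cfg$n_target_genes > 0 && cfg$delta_beta > 0) {
      meth_silenced_samples <- driver_high_samples
    }
  }

  # survival: exponential PH on the standardised functional activity of the
  # designated target. A genetically inactivated sample has normal mRNA but
  # no working protein, so its activity is discounted by expr_log2fc before
  # standardisation; the other targets share the driver-driven knock-down, so
  # every target carries a recoverable (attenuated) hazard association.
  clinical <- with_seed(s_clin, {
    score <- if (cfg$n_target_genes > 0) {
      activity <- expr[designated, ]
      if (length(lofdel_samples) > 0) {
        activity[samples %in% lofdel_samples] <-
          activity[samples %in% lofdel_samples] - cfg$expr_log2fc
      }
      as.numeric(scale(activity))
    } else rep(0, n)
    lambda <- cfg$baseline_hazard * exp(cfg$hazard_coef * score)
    t_event <- rexp(n, rate = lambda)
    tau <- censor_horizon(lambda, cfg$censor_rate)
    c_time <- if (is.finite(tau)) runif(n, 0, tau) else rep(Inf, n)
    p_high <- c(`basal-like` = 0.60, `HER2-enriched` = 0.25,
                `luminal-A` = 0.10, `luminal-B` = 0.05)
    p_low <- c(`basal-like` = 0.10, `HER2-enriched` = 0.10,
               `luminal-A` = 0.50, `luminal-B` = 0.30)
    subtype <- vapply(seq_len(n), function(i) {
      p <- if (is_high[i]) p_high else p_low
      sample(names(p), 1, prob = p)
    }, character(1))
    tibble::tibble(
      sample_id = samples,
      dfs_time = pmax(pmin(t_event, c_time), 1e-8),
      dfs_event = as.integer(t_event <= c_time),
      subtype = subtype
    )
  })

  truth <- structure(list(
    driver_high_samples = driver_high_samples,
    target_genes = uni$targets,
    designated_target = designated,
    meth_silenced_samples = meth_silenced_samples,
    lofdel_samples = lofdel_samples,
    effects = tibble::tibble(
      gene = uni$targets,
      delta_beta = cfg$delta_beta,
      expr_log2fc = cfg$expr_log2fc,
      hazard_coef = cfg$hazard_coef
    )
  ), class = "ground_truth")
  stopifnot(length(intersect(truth$meth_silenced_samples, truth$lofdel_samples)) == 0)

  bundle <- structure(list(
    cohort_id = cohort_id,
    expression = expr,
    methylation = methylation,
    manifest = if (has_omics) manifest else NULL,
    clinical = clinical,
    mutations = mutations,
    cnas = cnas
  ), class = "cohort_bundle")
  list(bundle = bundle, truth = truth)
}

#' Simulate a multi-cohort study
#'
#' All cohorts share the gene universe and planted targets; only cohort 0
#' carries methylation, mutation and copy-number tables, while every cohort
#' carries expression and clinical tables.
#'
#' @param cfg a [simulation_config()].
#' @return A list of `n_cohorts` elements, each as returned by
#'   [simulate_cohort()].
#' @export
simulate_multicohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  lapply(seq_len(cfg$n_cohorts) - 1L, function(i) simulate_cohort(cfg, i))
}

#' Simulate a gene set collection
#'
#' Builds a small collection for enrichment testing on the simulated gene
#' universe: random sets plus, optionally, one planted set of the silenced
#' targets (named `PLANTED_TARGETS`).
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param min_size,max_size random set size range.
#' @param planted optional character vector forming the planted set.
#' @param seed RNG seed.
#' @return Named list of gene sets (GMT-compatible).
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, min_size = 10, max_size = 50,
                               planted = NULL, seed = 1L) {
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      s <- sample(min_size:max_size, 1)
      sort(sample(universe, s))
    })
  })
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
  if (!is.null(planted) && length(planted) > 0) {
    sets <- c(list(PLANTED_TARGETS = planted), sets)
  }
  attr(sets, "collection") <- "SIM"
  sets
}

#' Write a cohort bundle to disk
#'
#' Writes the TSV/GMT representation of a bundle (expression, methylation,
#' manifest, clinical, mutations, CNAs) under `dir`, plus a
#' `ground_truth.json` sidecar when truth is supplied.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to serialise alongside.
#' @export
write_cohort_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$expression, file.path(dir, "expression.tsv"), id_col = "gene")
  readr::write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  if (!is.null(bundle$methylation)) {
    write_matrix(bundle$methylation, file.path(dir, "methylation.tsv"), id_col = "probe_id")
    write_probe_manifest(bundle$manifest, file.path(dir, "manifest.tsv"))
  }
  if (!is.null(bundle$mutations)) {
    readr::write_tsv(
      dplyr::rename(bundle$mutations, sample = "sample_id"),
      file.path(dir, "mutations.tsv"), progress = FALSE
    )
  }
  if (!is.null(bundle$cnas)) {
    readr::write_tsv(
      dplyr::rename(bundle$cnas, sample = "sample_id"),
      file.path(dir, "cnas.tsv"), progress = FALSE
    )
  }
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort_bundle()]
#' @param dir directory holding the bundle TSVs.
#' @param cohort_id cohort identifier; defaults to the directory name.
#' @return A `cohort_bundle`.
#' @export
read_cohort_bundle <- function(dir, cohort_id = basename(dir)) {
  p <- function(f) file.path(dir, f)
  structure(list(
    cohort_id = cohort_id,
    expression = read_matrix(p("expression.tsv"), "expression"),
    methylation = if (file.exists(p("methylation.tsv"))) read_matrix(p("methylation.tsv"), "beta") else NULL,
    manifest = if (file.exists(p("manifest.tsv"))) read_probe_manifest(p("manifest.tsv")) else NULL,
    clinical = readr::read_tsv(p("clinical.tsv"), col_types = "cdic", progress = FALSE),
    mutations = if (file.exists(p("mutations.tsv"))) read_mutations(p("mutations.tsv")) else NULL,
    cnas = if (file.exists(p("cnas.tsv"))) read_cnas(p("cnas.tsv")) else NULL
  ), class = "cohort_bundle")
}
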