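test_that("same configuration and seed reproduce a cohort exactly", {
  cfg <- simulation_config(n_samples = 40, n_genes = 30, n_target_genes = 3,
                           n_cohorts = 2, rng_seed = 11)
  a <- simulate_cohort(cfg, 0)
  b <- simulate_cohort(cfg, 0)
  expect_identical(a$bundle$expression, b$bundle$expression)
  expect_identical(a$bundle$methylation, b$bundle$methylation)
  expect_identical(a$bundle$clinical, b$bundle$clinical)
  expect_identical(a$truth$lofdel_samples, b$truth$lofdel_samples)
  # a different cohort index gives different draws
  c2 <- simulate_cohort(cfg, 1)
  expect_false(identical(a$bundle$expression["DNMT3B", ],
                         c2$bundle$expression["DNMT3B", ]))
})

test_that("generated values respect their supports and structure", {
  cfg <- simulation_config(n_samples = 60, n_genes = 40, n_target_genes = 4,
                           n_cohorts = 3, rng_seed = 2)
  sims <- simulate_multicohort(cfg)
  expect_length(sims, 3)
  # only cohort 0 carries methylation / mutations / CNAs
  expect_false(is.null(sims[[1]]$bundle$methylation))
  expect_true(is.null(sims[[2]]$bundle$methylation))
  expect_true(is.null(sims[[3]]$bundle$mutations))
  for (s in sims) {
    expect_true(all(s$bundle$expression >= 0))
    expect_true(all(s$bundle$clinical$dfs_time > 0))
    expect_true(all(s$bundle$clinical$dfs_event %in% c(0, 1)))
  }
  b0 <- sims[[1]]$bundle
  expect_true(all(b0$methylation >= 0 & b0$methylation <= 1))
  # driver bimodality: group means separated by at least 2 log2 units
  tr <- sims[[1]]$truth
  hi <- b0$expression["DNMT3B", tr$driver_high_samples]
  lo <- b0$expression["DNMT3B", setdiff(colnames(b0$expression),
                                        tr$driver_high_samples)]
  expect_gt(mean(hi) - mean(lo), 2)
  # probes per target promoter with promoter-proximal classes
  ann <- b0$manifest[!is.na(b0$manifest$gene) & b0$manifest$gene == tr$target_genes[1], ]
  expect_equal(nrow(ann), cfg$probes_per_promoter)
  expect_true(all(ann$region_class %in% promoter_classes()))
  expect_equal(diff(sort(ann$pos)), rep(cfg$probe_spacing_bp,
                                        cfg$probes_per_promoter - 1))
})

test_that("planted mutual exclusivity holds exactly in every realisation", {
  for (seed in 1:5) {
    cfg <- simulation_config(n_samples = 80, n_genes = 30, n_target_genes = 3,
                             n_cohorts = 1, frac_lofdel = 0.3, rng_seed = seed)
    sim <- simulate_cohort(cfg, 0)
    expect_length(intersect(sim$truth$meth_silenced_samples,
                            sim$truth$lofdel_samples), 0)
    # lesions live strictly outside the driver-high (methylation-silenced) set
    expect_length(intersect(sim$truth$lofdel_samples,
                            sim$truth$driver_high_samples), 0)
  }
})

test_that("planted beta shift matches the configured generative mean", {
  cfg <- simulation_config(n_samples = 200, frac_driver_high = 0.5,
                           n_genes = 60, n_target_genes = 10,
                           delta_beta = 0.3, n_cohorts = 1, rng_seed = 4)
  sim <- simulate_cohort(cfg, 0)
  b <- sim$bundle
  tr <- sim$truth
  target_probes <- b$manifest$probe_id[!is.na(b$manifest$gene) &
                                         b$manifest$gene %in% tr$target_genes]
  hi <- tr$driver_high_samples
  lo <- setdiff(colnames(b$methylation), hi)
  d <- rowMeans(b$methylation[target_probes, hi]) -
    rowMeans(b$methylation[target_probes, lo])
  expect_lt(abs(mean(d) - 0.3), 0.02)
})

test_that("null configuration plants no effects and censoring matches its rate", {
  cfg <- simulation_config(n_samples = 400, n_genes = 50, n_target_genes = 5,
                           delta_beta = 0, expr_log2fc = 0, hazard_coef = 0,
                           censor_rate = 0.3, n_cohorts = 1, rng_seed = 9)
  sim <- simulate_cohort(cfg, 0)
  expect_true(all(sim$truth$effects$delta_beta == 0))
  expect_true(all(sim$truth$effects$expr_log2fc == 0))
  frac_cens <- mean(sim$bundle$clinical$dfs_event == 0)
  # binomial error band around the configured rate
  expect_lt(abs(frac_cens - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("null Cox coefficients are centred on zero across seeds", {
  betas <- ses <- numeric(6)
  for (s in 1:6) {
    cfg <- simulation_config(n_samples = 150, n_genes = 20, n_target_genes = 2,
                             delta_beta = 0, expr_log2fc = 0, hazard_coef = 0,
                             n_cohorts = 1, rng_seed = 100 + s)
    sim <- simulate_cohort(cfg, 0)
    b <- sim$bundle
    g <- sim$truth$target_genes[1]
    fit <- cox_fit(b$clinical$dfs_time, b$clinical$dfs_event,
                   as.numeric(scale(b$expression[g, ])))
    betas[s] <- fit$beta
    ses[s] <- fit$se
  }
  expect_lt(abs(mean(betas)), 3 * mean(ses) / sqrt(6))
})

test_that("increasing delta_beta never decreases planted probes passing EWAS", {
  hits <- vapply(c(0.05, 0.15, 0.3), function(db) {
    n_hit <- 0
    for (s in 1:3) {
      cfg <- simulation_config(n_samples = 100, n_genes = 40, n_target_genes = 5,
                               delta_beta = db, n_cohorts = 1, rng_seed = 200 + s)
      sim <- simulate_cohort(cfg, 0)
      b <- sim$bundle
      grp <- tibble::tibble(
        sample_id = colnames(b$expression),
        group = ifelse(colnames(b$expression) %in% sim$truth$driver_high_samples,
                       "high", "low")
      )
      ew <- ewas(b$methylation, grp, b$manifest)
      planted <- b$manifest$probe_id[!is.na(b$manifest$gene) &
                                       b$manifest$gene %in% sim$truth$target_genes]
      n_hit <- n_hit + sum(ew$p_value[ew$probe_id %in% planted] < 1e-5)
    }
    n_hit
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("invalid simulation configurations are rejected before sampling", {
  expect_error(simulation_config(delta_beta = 0.7), "outside \\[0,1\\]")
  expect_error(simulation_config(frac_driver_high = 1), "out of range")
  expect_error(simulation_config(n_target_genes = 50, n_genes = 10), "out of range")
})
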