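test_that("LOF classification keeps the retained vocabulary and nothing else", {
  expect_true(classify_lof("stop_gained"))
  expect_true(classify_lof("Frameshift Variant"))
  expect_true(classify_lof("In-Frame Deletion"))
  expect_false(classify_lof("missense_variant"))
  expect_false(classify_lof("synonymous_variant"))
  expect_warning(out <- classify_lof("totally_novel_term"), "unknown")
  expect_false(out)
  expect_false("missense_variant" %in% lof_consequences())
})

test_that("alteration frequencies use union semantics over the full universe", {
  universe <- paste0("S", 1:200)
  mut <- tibble::tibble(
    sample_id = paste0("S", 1:17), gene = "G",
    consequence = "stop_gained"
  )
  cna <- tibble::tibble(sample_id = c("S1", "S30"), gene = "G",
                        category = c(-2L, -2L))
  out <- alteration_frequencies(mut, cna, universe, "G")
  expect_equal(out$f_lof, 17 / 200)
  expect_equal(out$f_del, 2 / 200)
  # S1 has both lesions and counts once in the union
  expect_equal(out$f_total, 18 / 200)
  expect_true(out$f_total <= out$f_lof + out$f_del)
  expect_true(out$f_total >= max(out$f_lof, out$f_del))
  # empty records give all-zero frequencies; ranking ties break by symbol
  out0 <- alteration_frequencies(NULL, NULL, universe, c("B", "A"))
  expect_equal(out0$gene, c("A", "B"))
  expect_true(all(out0$f_total == 0))
  # complement identity: union frequency = 1 - fraction with no record
  n_clean <- length(setdiff(universe, union(mut$sample_id, cna$sample_id)))
  expect_equal(out$f_total, 1 - n_clean / 200)
})

test_that("stratification is mutually exclusive with genetic precedence", {
  cfg <- simulation_config(n_samples = 150, n_genes = 40, n_target_genes = 4,
                           n_cohorts = 1, rng_seed = 31)
  sim <- simulate_cohort(cfg, 0)
  b <- sim$bundle
  tgt <- sim$truth$designated_target
  st <- stratify_target(b, "DNMT3B", tgt)
  expect_length(intersect(st$sample_id[st$stratum == "METH"],
                          st$sample_id[st$stratum == "LOFDEL"]), 0)
  expect_setequal(unique(st$stratum),
                  intersect(c("METH", "LOFDEL", "CTRL", "unassigned"),
                            unique(st$stratum)))
  # every genetically altered sample lands in LOFDEL even if hypermethylated
  lof <- unique(b$mutations$sample_id[b$mutations$gene == tgt &
                                        classify_lof(b$mutations$consequence)])
  del <- unique(b$cnas$sample_id[b$cnas$gene == tgt & b$cnas$category == -2L])
  expect_true(all(st$stratum[st$sample_id %in% union(lof, del)] == "LOFDEL"))
  # deterministic and invariant to record order
  b2 <- b
  b2$mutations <- b$mutations[rev(seq_len(nrow(b$mutations))), ]
  st2 <- stratify_target(b2, "DNMT3B", tgt)
  expect_identical(st$stratum, st2$stratum)
})

test_that("driver-low unaltered samples are controls", {
  cfg <- simulation_config(n_samples = 100, n_genes = 30, n_target_genes = 3,
                           n_cohorts = 1, rng_seed = 37)
  sim <- simulate_cohort(cfg, 0)
  st <- stratify_target(sim$bundle, "DNMT3B", sim$truth$designated_target)
  low <- setdiff(colnames(sim$bundle$expression), sim$truth$driver_high_samples)
  clean_low <- setdiff(low, sim$truth$lofdel_samples)
  expect_true(all(st$stratum[st$sample_id %in% clean_low] == "CTRL"))
})

test_that("stratum frequencies and the combined-inactivation identity", {
  assignment <- tibble::tibble(
    sample_id = paste0("S", 1:500),
    stratum = rep(c("METH", "LOFDEL", "CTRL", "unassigned"),
                  c(34, 43, 300, 123))
  )
  class(assignment) <- c("stratum_assignment", class(assignment))
  freq <- stratum_frequencies(assignment)
  expect_equal(freq$pct[freq$stratum == "METH"], 6.8)
  expect_equal(freq$pct[freq$stratum == "LOFDEL"], 8.6)
  expect_equal(combined_inactivation_pct(assignment), 15.4)
})

test_that("stratum summaries: survival contrasts and subtype composition", {
  cfg <- simulation_config(n_samples = 500, n_genes = 40, n_target_genes = 4,
                           n_cohorts = 1, rng_seed = 41)
  sim <- simulate_cohort(cfg, 0)
  st <- stratify_target(sim$bundle, "DNMT3B", sim$truth$designated_target)
  ss <- stratum_summaries(st, sim$bundle$clinical)
  expect_setequal(ss$survival$contrast, c("METH_vs_CTRL", "LOFDEL_vs_CTRL"))
  # planted worse hazard in both inactivated strata
  expect_true(all(ss$survival$logrank_p < 0.05))
  expect_true(all(ss$survival$hr > 1))
  comp <- ss$composition
  sums <- tapply(comp$pct, comp$stratum, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # identical survival gives a null contrast
  clin <- sim$bundle$clinical
  clin$dfs_time <- rep(1, nrow(clin))
  clin$dfs_event <- rep(1, nrow(clin))
  ss0 <- stratum_summaries(st, clin)
  expect_true(all(ss0$survival$logrank_p[!is.na(ss0$survival$logrank_p)] > 0.9))
})

test_that("recovered strata match the planted truth closely", {
  cfg <- simulation_config(rng_seed = 43)
  sim <- simulate_cohort(cfg, 0)
  st <- stratify_target(sim$bundle, "DNMT3B", sim$truth$designated_target)
  expect_gte(jaccard(st$sample_id[st$stratum == "METH"],
                     sim$truth$meth_silenced_samples), 0.9)
  expect_gte(jaccard(st$sample_id[st$stratum == "LOFDEL"],
                     sim$truth$lofdel_samples), 0.9)
})
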