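expr_mat <- function(values, samples = NULL) {
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}

test_that("median split sends ties to the low group and rejects degeneracy", {
  e <- expr_mat(list(DNMT3B = c(1, 2, 3, 4), G1 = c(5, 5, 5, 5)))
  g <- split_by_driver(e, "DNMT3B")
  expect_setequal(g$sample_id[g$group == "high"], c("S3", "S4"))
  # odd n: the median sample itself goes low
  e2 <- expr_mat(list(DNMT3B = c(1, 2, 3)))
  g2 <- split_by_driver(e2, "DNMT3B")
  expect_equal(g2$sample_id[g2$group == "high"], "S3")
  expect_error(split_by_driver(e, "G1"), "constant")
  expect_error(split_by_driver(e, "ABSENT"), "not in expression")
})

test_that("differential expression calls follow the symmetric fold-change rule", {
  set.seed(8)
  n <- 30
  e <- rbind(
    down = c(rnorm(n, 4), rnorm(n, 6)),   # high minus low = -2
    up = c(rnorm(n, 8), rnorm(n, 6)),
    flat = rnorm(2 * n, 5),
    const = rep(3, 2 * n)
  )
  colnames(e) <- paste0("S", seq_len(2 * n))
  g <- tibble::tibble(sample_id = colnames(e),
                      group = rep(c("high", "low"), each = n))
  de <- differential_expression(e, g)
  expect_equal(de$call[de$gene == "down"], "down")
  expect_equal(de$call[de$gene == "up"], "up")
  expect_equal(de$call[de$gene == "flat"], "ns")
  expect_equal(de$p_value[de$gene == "const"], 1)
  expect_true(all(de$fold_change > 0))
  # invariance to column and row order
  de2 <- differential_expression(e[c(3, 1, 4, 2), sample(colnames(e))], g)
  expect_equal(dplyr::arrange(tibble::as_tibble(de), gene),
               dplyr::arrange(tibble::as_tibble(de2), gene), tolerance = 1e-12)
  # Mann-Whitney variant agrees with a direct wilcox.test
  dem <- differential_expression(e, g, test = "mann_whitney")
  w <- wilcox.test(e["down", 1:n], e["down", (n + 1):(2 * n)], exact = FALSE)
  expect_equal(dem$p_value[dem$gene == "down"], w$p.value, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up arithmetic and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  e <- matrix(0, 4, 8, dimnames = list(paste0("g", 1:4), paste0("S", 1:8)))
  # direct check of the documented example via p.adjust semantics
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(12)
  raw <- runif(50)
  adj <- p.adjust(raw, "BH")
  expect_true(all(adj[order(raw)] == cummax(adj[order(raw)])))
  expect_true(all(adj <= 1))
})

test_that("intersection keeps genes both hypermethylated and downregulated", {
  hyper <- tibble::tibble(gene = c("A", "B"), hypermethylated = TRUE,
                          best_p_sidak = c(1e-8, 1e-6), n_regions = 1L)
  de <- tibble::tibble(gene = c("B", "C"), log2_fc = c(-1, -2),
                       fold_change = 2^c(-1, -2), p_value = 0.001,
                       p_adj = 0.01, call = "down")
  out <- intersect_silenced(hyper, de)
  expect_equal(out$gene, "B")
  de_up <- dplyr::mutate(de, call = "up")
  expect_equal(nrow(intersect_silenced(hyper, de_up)), 0)
})

test_that("group comparison uses pooled t for k=2 and ANOVA for k>2", {
  out <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # closed-form pooled-variance oracle
  t_oracle <- (mean(c(1, 2, 3)) - mean(c(4, 5, 6))) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(out$statistic, t_oracle, tolerance = 1e-12)
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  k3 <- group_compare(c(1, 2, 3, 1.2, 2.2, 3.2, 0.8, 1.8, 2.8),
                      rep(c("a", "b", "c"), each = 3))
  expect_equal(k3$method, "anova")
  expect_gt(k3$p_value, 0.05)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), ">= 2 values")
})

test_that("correlation handles exact fits, oracles and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 6)
  out <- correlate(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  t_or <- r_oracle * sqrt((5 - 2) / (1 - r_oracle^2))
  expect_equal(out$p_value, 2 * pt(abs(t_or), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(c(1, 2), c(3, 4)), ">= 3")
})

test_that("planted correlation triangle has the expected signs", {
  # driver up -> promoter methylation up -> target expression down
  ok <- 0
  for (s in 1:5) {
    cfg <- simulation_config(n_samples = 200, n_genes = 50, n_target_genes = 5,
                             n_cohorts = 1, rng_seed = 300 + s)
    sim <- simulate_cohort(cfg, 0)
    b <- sim$bundle
    tgt <- sim$truth$target_genes[2]
    driver <- b$expression["DNMT3B", ]
    pb <- promoter_mean_beta(b$methylation, b$manifest, tgt)
    tx <- b$expression[tgt, ]
    c1 <- correlate(driver, pb)
    c2 <- correlate(pb, tx)
    c3 <- correlate(driver, tx)
    if (c1$r > 0 && c1$p_value < 0.05 &&
        c2$r < 0 && c2$p_value < 0.05 &&
        c3$r < 0 && c3$p_value < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 5 * 0.95 - 1)  # allow one failing seed out of five
})

test_that("recovered fold-change signs match the planted direction", {
  cfg <- simulation_config(n_samples = 120, n_genes = 60, n_target_genes = 6,
                           n_cohorts = 1, rng_seed = 17)
  sim <- simulate_cohort(cfg, 0)
  g <- split_by_driver(sim$bundle$expression, "DNMT3B")
  de <- differential_expression(sim$bundle$expression, g)
  rec <- de[de$gene %in% sim$truth$target_genes & de$call == "down", ]
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$log2_fc < 0))
})
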