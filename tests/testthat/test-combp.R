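# The combined-p DMR machinery: Stouffer-Liptak closed forms, ACF estimation,
# window adjustment, region growth, and region scoring against brute force.

sorted_tbl <- function(pos, p, chrom = "chr1", delta = 0.1) {
  tibble::tibble(
    probe_id = sprintf("p%02d", seq_along(pos)),
    chrom = chrom,
    pos = as.numeric(pos),
    delta_beta = rep_len(delta, length(pos)),
    p_value = p
  )
}

test_that("Stouffer-Liptak closed forms hold", {
  expect_equal(stouffer_liptak(0.03, matrix(1)), 0.03, tolerance = 1e-12)
  expect_equal(stouffer_liptak(c(0.5, 0.5), 0), 0.5, tolerance = 1e-12)
  # hand-computed example: z = (2.3263, 2.0537), rho = 0.5
  # z_comb = 4.3800 / sqrt(3) = 2.5288
  hand <- pnorm(4.3800 / sqrt(3), lower.tail = FALSE)
  expect_lt(abs(stouffer_liptak(c(0.01, 0.02), 0.5) - hand), 1e-4)
  expect_error(stouffer_liptak(c(0.5, 0.5), matrix(c(1, -3, -3, 1), 2)),
               "positive")
})

test_that("ACF estimation recovers independence and planted correlation", {
  # i.i.d. uniform p-values: all bins near zero
  set.seed(71)
  n <- 10000
  tbl <- sorted_tbl(cumsum(sample(20:60, n, replace = TRUE)), runif(n))
  a <- estimate_acf(tbl, max_lag = 1000, step = 50)
  expect_true(all(a$rho[!a$fallback] < 0.05))
  # planted AR-like z with known lag correlation ~0.6 at 50 bp spacing
  rho_true <- 0.6
  z <- numeric(n)
  z[1] <- rnorm(1)
  for (i in 2:n) z[i] <- rho_true * z[i - 1] + sqrt(1 - rho_true^2) * rnorm(1)
  tbl2 <- sorted_tbl(seq(50, by = 50, length.out = n), pnorm(z, lower.tail = FALSE))
  a2 <- estimate_acf(tbl2, max_lag = 1000, step = 50)
  expect_lt(abs(a2$rho[1] - rho_true), 0.05)
})

test_that("degenerate identical p-values fall back to near-total correlation", {
  tbl <- sorted_tbl(seq(10, by = 30, length.out = 50), rep(0.2, 50))
  a <- estimate_acf(tbl, max_lag = 300, step = 50)
  expect_true(all(a$rho == 0.99))
  expect_true(all(a$fallback))
})

test_that("too-sparse data triggers an actionable ACF error", {
  tbl <- sorted_tbl(c(10, 5000), runif(2))
  expect_error(estimate_acf(tbl, max_lag = 1000, step = 50), "constant_acf")
})

test_that("window adjustment: isolated probes, reinforcement, and order checks", {
  acf0 <- constant_acf(0, max_lag = 1000, step = 50)
  # isolated probe keeps its raw p
  tbl <- sorted_tbl(c(100, 5000), c(0.01, 0.4))
  adj <- sliding_window_adjust(tbl, acf0, dist = 1000)
  expect_equal(adj$p_adj, adj$p_value)
  # three equally significant adjacent probes reinforce under independence
  tbl2 <- sorted_tbl(c(100, 200, 300), rep(0.01, 3))
  adj2 <- sliding_window_adjust(tbl2, acf0, dist = 1000)
  expect_true(all(adj2$p_adj < 0.01))
  # unsorted input is rejected rather than silently mis-windowed
  expect_error(sliding_window_adjust(tbl2[c(2, 1, 3), ], acf0), "sorted")
})

test_that("region growth follows the seed/extend/gap/min-probes rules", {
  acf0 <- constant_acf(0)
  tbl <- sorted_tbl(c(100, 400, 5000), c(1e-7, 0.01, 1e-7))
  tbl$p_adj <- tbl$p_value
  regions <- find_regions(tbl, seed_p = 1e-5, dist = 1000,
                          region_filter_p = 0.05, region_filter_n = 2)
  # gap 400 -> 5000 exceeds dist: the singleton at 5000 is filtered out
  expect_equal(nrow(regions), 1)
  expect_equal(regions$probe_ids[[1]], c("p01", "p02"))
  expect_equal(regions$start, 99)
  expect_equal(regions$end, 400)
  # no probe below seed_p: empty result
  tbl2 <- tbl
  tbl2$p_adj <- rep(0.01, 3)
  expect_equal(nrow(find_regions(tbl2, 1e-5, 1000, 0.05, 2)), 0)
})

test_that("tightening region_filter_p never grows any region", {
  set.seed(5)
  for (rep in 1:10) {
    tbl <- random_dmr_instance(20)
    tbl$p_adj <- tbl$p_value
    sizes <- vapply(c(0.05, 0.01, 0.001), function(fp) {
      r <- find_regions(tbl, seed_p = 1e-4, dist = 1000,
                        region_filter_p = fp, region_filter_n = 1)
      if (nrow(r) == 0) 0L else max(r$n_probes)
    }, integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("region scoring matches direct Sidak arithmetic", {
  acf0 <- constant_acf(0)
  tbl <- sorted_tbl(c(100, 200, 10100), c(1e-8, 1e-8, 0.5))
  tbl$p_adj <- tbl$p_value
  regions <- find_regions(tbl, 1e-5, 1000, 0.05, 2)
  sc <- score_region(regions[1, ], tbl, acf0)
  # exponent B/w: B = 10000, w = 200 - 99 = 101
  pc_oracle <- oracle_sl(c(1e-8, 1e-8), diag(2))
  expect_equal(sc$p_combined, pc_oracle, tolerance = 1e-12)
  expect_equal(sc$p_sidak, 1 - (1 - pc_oracle)^(10000 / 101), tolerance = 1e-12)
  expect_gte(sc$p_sidak, sc$p_combined)
})

test_that("exponent floors at one and p_sidak degenerates with p_combined", {
  # B/w < 1: single chromosome whose full span equals the region span
  acf0 <- constant_acf(0)
  tbl <- sorted_tbl(c(100, 300), c(1e-8, 1e-8))
  tbl$p_adj <- tbl$p_value
  regions <- find_regions(tbl, 1e-5, 1000, 0.05, 2)
  sc <- score_region(regions[1, ], tbl, acf0)
  # w = 201 > B = 200 so the exponent is floored at 1
  expect_equal(sc$p_sidak, sc$p_combined, tolerance = 1e-12)
})

test_that("full DMR path matches brute force on random toy instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    tbl <- random_dmr_instance(n, two_chrom = rep %% 3 == 0)
    acf <- constant_acf(runif(1, 0, 0.6), max_lag = 1000, step = 50)
    adj <- sliding_window_adjust(tbl, acf, dist = 1000)
    expect_equal(adj$p_adj, oracle_window_adjust(tbl, acf, 1000),
                 tolerance = 1e-10)
    regions <- find_regions(adj, seed_p = 1e-3, dist = 1000,
                            region_filter_p = 0.05, region_filter_n = 2)
    oracle <- oracle_regions(adj, adj$p_adj, 1e-3, 1000, 0.05, 2)
    expect_equal(nrow(regions), length(oracle))
    if (nrow(regions) > 0) {
      pkg_members <- lapply(regions$member_rows, identity)
      expect_setequal(vapply(pkg_members, paste, character(1), collapse = ","),
                      vapply(oracle, paste, character(1), collapse = ","))
      for (i in seq_len(nrow(regions))) {
        sc <- score_region(regions[i, ], adj, acf)
        osc <- oracle_score_region(adj, regions$member_rows[[i]], acf)
        expect_equal(sc$p_combined, osc$p_combined, tolerance = 1e-10)
        expect_equal(sc$p_sidak, osc$p_sidak, tolerance = 1e-10)
      }
    }
  }
})

test_that("gene assignment honours direction, class and fan-out rules", {
  manifest <- tibble::tibble(
    probe_id = c("p1", "p1", "p2", "p3"),
    chrom = "chr1",
    pos = c(100, 100, 200, 300),
    strand = "+",
    gene = c("A", "B", "A", "C"),
    region_class = c("TSS200", "Body", "TSS1500", "Body")
  )
  dmrs <- tibble::tibble(
    chrom = "chr1", start = 99, end = 300, n_probes = 3L,
    direction = c("hyper"),
    probe_ids = list(c("p1", "p2", "p3")),
    member_rows = list(1:3),
    p_combined = 1e-9, p_sidak = 1e-7
  )
  calls <- assign_regions_to_genes(dmrs, manifest, gene_dmr_p = 1e-5)
  # A qualifies through promoter-class probes; B (Body) and C (Body) do not
  expect_true(calls$hypermethylated[calls$gene == "A"])
  expect_false(calls$hypermethylated[calls$gene == "B"])
  expect_false(calls$hypermethylated[calls$gene == "C"])
  # hypo direction never qualifies regardless of p
  dmrs_hypo <- dplyr::mutate(dmrs, direction = "hypo", p_sidak = 1e-9)
  calls2 <- assign_regions_to_genes(dmrs_hypo, manifest, gene_dmr_p = 1e-5)
  expect_false(any(calls2$hypermethylated))
})
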