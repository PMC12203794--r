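#' Split samples by driver-gene median expression
#'
#' Samples strictly above the cohort median of the driver gene go to `high`;
#' samples at or below the median go to `low` (ties to low).
#'
#' @param expr gene-by-sample expression matrix, log2(1+x) scale.
#' @param driver_gene driver gene symbol.
#' @return Tibble `(sample_id, group)` with both groups non-empty.
#' @export
split_by_driver <- function(expr, driver_gene) {
  if (!driver_gene %in% rownames(expr)) {
    abort(paste0("driver gene '", driver_gene, "' not in expression matrix"))
  }
  x <- expr[driver_gene, ]
  if (all(x == x[1])) {
    abort("driver expression is constant; median split is degenerate")
  }
  med <- median(x)
  grp <- ifelse(x > med, "high", "low")
  if (!all(c("high", "low") %in% grp)) {
    abort("median split produced an empty group")
  }
  tibble::tibble(sample_id = colnames(expr), group = unname(grp))
}

#' Two-group differential expression with fold-change and BH control
#'
#' Per gene, a Welch t-test (default) or Mann-Whitney test between the `high`
#' and `low` groups, Benjamini-Hochberg adjustment across all genes, and a
#' symmetric fold-change rule: a gene is called `down` when
#' `fold_change <= 1/fc_threshold` and `p_adj < adj_p`, `up` when
#' `fold_change >= fc_threshold` and `p_adj < adj_p`, otherwise `ns`. The
#' fold change is `2^(mean(high) - mean(low))` on the log2(1+x) scale. Genes
#' with zero variance in both groups under the t-test get `p = 1`.
#'
#' @param expr gene-by-sample expression matrix.
#' @param groups sample grouping (tibble or named vector, `"high"`/`"low"`).
#' @param fc_threshold fold-change threshold (> 1).
#' @param adj_p adjusted-p threshold.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @return Tibble of class `ep_de`: `gene`, `log2_fc`, `fold_change`,
#'   `p_value`, `p_adj`, `call`.
#' @export
differential_expression <- function(expr, groups, fc_threshold = 1.5,
                                    adj_p = 0.05,
                                    test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  gv <- as_group_vector(groups)
  common <- intersect(colnames(expr), names(gv))
  hi <- common[gv[common] == "high"]
  lo <- common[gv[common] == "low"]
  if (length(hi) < 2 || length(lo) < 2) abort("need >= 2 samples per group")
  x1 <- expr[, hi, drop = FALSE]
  x0 <- expr[, lo, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  log2_fc <- m1 - m0
  if (test == "welch_t") {
    n1 <- length(hi); n0 <- length(lo)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
    se2 <- v1 / n1 + v0 / n0
    t_stat <- log2_fc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
    p[se2 == 0] <- 1
  } else {
    p <- vapply(seq_len(nrow(expr)), function(i) {
      wilcox.test(x1[i, ], x0[i, ], exact = FALSE)$p.value
    }, numeric(1))
    p[is.na(p)] <- 1 # all-tied gene
  }
  p_adj_v <- p.adjust(p, method = "BH")
  fold_change <- 2^log2_fc
  call <- dplyr::case_when(
    fold_change >= fc_threshold & p_adj_v < adj_p ~ "up",
    fold_change <= 1 / fc_threshold & p_adj_v < adj_p ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    gene = rownames(expr),
    log2_fc = unname(log2_fc),
    fold_change = unname(fold_change),
    p_value = unname(p),
    p_adj = unname(p_adj_v),
    call = call
  )
  class(out) <- c("ep_de", class(out))
  attr(out, "test") <- test
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "adj_p") <- adj_p
  out
}

#' Intersect hypermethylated and downregulated genes
#'
#' The candidate silenced genes: hypermethylated in the promoter/5'UTR (per
#' the DMR gene assignment) *and* called `down` by differential expression.
#'
#' @param hyper_genes tibble from [assign_regions_to_genes()].
#' @param de_results tibble from [differential_expression()].
#' @return Tibble `gene`, `best_p_sidak`, `log2_fc`, `p_adj`, sorted by best
#'   DMR p.
#' @export
intersect_silenced <- function(hyper_genes, de_results) {
  hyper <- dplyr::filter(hyper_genes, .data$hypermethylated)
  down <- dplyr::filter(de_results, .data$call == "down")
  dplyr::inner_join(
    dplyr::select(hyper, "gene", "best_p_sidak"),
    dplyr::select(down, "gene", "log2_fc", "p_adj"),
    by = "gene"
  ) |>
    dplyr::arrange(.data$best_p_sidak, .data$gene)
}

#' Compare a numeric variable across k groups
#'
#' Two groups: two-tailed pooled-variance t-test. More than two groups:
#' one-way ANOVA (equal-variance F test).
#'
#' @param values numeric vector.
#' @param groups grouping vector, same length.
#' @return Tibble `statistic`, `p_value`, `method`, `k`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least two groups")
  if (any(sizes < 2)) abort("every group needs >= 2 values")
  if (length(sizes) == 2) {
    fit <- t.test(values ~ groups, var.equal = TRUE)
    tibble::tibble(statistic = unname(fit$statistic),
                   p_value = fit$p.value, method = "t", k = 2L)
  } else {
    fit <- oneway.test(values ~ groups, var.equal = TRUE)
    tibble::tibble(statistic = unname(fit$statistic),
                   p_value = fit$p.value, method = "anova",
                   k = length(sizes))
  }
}

#' Pearson correlation with a two-sided p-value
#'
#' Drops incomplete pairs, requires at least 3 complete observations and
#' non-zero variance in both variables; the p-value comes from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` df.
#'
#' @param x,y sample-aligned numeric vectors.
#' @param labels optional length-2 character vector naming the pair.
#' @return Tibble `label_x`, `label_y`, `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y, labels = c("x", "y")) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need >= 3 complete paired observations")
  if (var(x) == 0 || var(y) == 0) abort("undefined correlation: zero variance")
  fit <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(label_x = labels[1], label_y = labels[2],
                 r = unname(fit$estimate), p_value = fit$p.value, n = n)
}

#' Per-sample mean promoter methylation of a gene
#'
#' Mean beta over the gene's promoter-proximal probes
#' (TSS200/TSS1500/5'UTR by default), missing values removed per sample.
#'
#' @param beta probe-by-sample beta matrix.
#' @param manifest long-format probe manifest.
#' @param gene gene symbol.
#' @param classes promoter-proximal region classes.
#' @return Named numeric vector over samples.
#' @export
promoter_mean_beta <- function(beta, manifest, gene, classes = promoter_classes()) {
  probes <- manifest$probe_id[!is.na(manifest$gene) & manifest$gene == gene &
                                manifest$region_class %in% classes]
  probes <- intersect(unique(probes), rownames(beta))
  if (length(probes) == 0) {
    abort(paste0("no promoter-class probes for gene '", gene, "'"))
  }
  colMeans(beta[probes, , drop = FALSE], na.rm = TRUE)
}
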