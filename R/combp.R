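# Native combined-p DMR caller: distance-binned autocorrelation of probit
# scores, Stouffer-Liptak aggregation, seeded region growth, Sidak correction.

#' Estimate the autocorrelation of EWAS probit scores by genomic distance
#'
#' For each distance bin `((k-1)*step, k*step]` up to `max_lag`, computes the
#' Pearson correlation of probit scores \eqn{z = \Phi^{-1}(1-p)} over all
#' same-chromosome probe pairs whose separation falls in the bin. Correlations
#' are clipped to \eqn{[0, 0.99]}; bins with fewer than 10 pairs inherit the
#' nearest populated bin's value; a bin whose score variance is zero (e.g.
#' identical p at every probe) is degenerate and falls back to 0.99, flagged.
#' Lag 0 is defined as correlation 1 and pairs beyond `max_lag` are treated as
#' uncorrelated by the lookup.
#'
#' @param ewas_results genome-sorted EWAS tibble with `chrom`, `pos`,
#'   `p_value`.
#' @param max_lag maximum lag in bp (the DMR window width).
#' @param step bin width in bp.
#' @return Tibble of class `acf_estimate` with columns `lag_lo`, `lag_hi`,
#'   `rho`, `n_pairs`, `fallback`; attributes `max_lag`, `step`.
#' @export
estimate_acf <- function(ewas_results, max_lag = 1000, step = 50) {
  stopifnot(max_lag > 0, step > 0, max_lag %% step == 0)
  check_sorted(ewas_results)
  nbins <- as.integer(max_lag / step)
  z <- probit_score(ewas_results$p_value)
  acc <- matrix(0, nbins, 6,
                dimnames = list(NULL, c("n", "sx", "sy", "sxx", "syy", "sxy")))
  for (idx in split(seq_len(nrow(ewas_results)), ewas_results$chrom)) {
    pos <- ewas_results$pos[idx]
    zz <- z[idx]
    n <- length(pos)
    if (n < 2) next
    k <- 1L
    while (k < n) {
      d <- pos[(k + 1):n] - pos[1:(n - k)]
      if (min(d) > max_lag) break
      keep <- d > 0 & d <= max_lag
      if (any(keep)) {
        bins <- ceiling(d[keep] / step)
        x <- zz[1:(n - k)][keep]
        y <- zz[(k + 1):n][keep]
        upd <- rowsum(cbind(1, x, y, x * x, y * y, x * y), bins)
        acc[as.integer(rownames(upd)), ] <- acc[as.integer(rownames(upd)), , drop = FALSE] + upd
      }
      k <- k + 1L
    }
  }
  n_pairs <- acc[, "n"]
  rho <- rep(NA_real_, nbins)
  fallback <- rep(FALSE, nbins)
  for (b in seq_len(nbins)) {
    if (n_pairs[b] < 10) next
    nb <- n_pairs[b]
    cov_xy <- acc[b, "sxy"] - acc[b, "sx"] * acc[b, "sy"] / nb
    var_x <- acc[b, "sxx"] - acc[b, "sx"]^2 / nb
    var_y <- acc[b, "syy"] - acc[b, "sy"]^2 / nb
    if (var_x <= 1e-12 || var_y <= 1e-12) {
      rho[b] <- 0.99 # degenerate: identical scores carry full correlation
      fallback[b] <- TRUE
    } else {
      rho[b] <- min(max(cov_xy / sqrt(var_x * var_y), 0), 0.99)
    }
  }
  populated <- which(!is.na(rho))
  if (length(populated) == 0) {
    abort(paste0("fewer than 10 probe pairs in every distance bin up to ",
                 max_lag, " bp; supply more data or inject a fixed ACF ",
                 "(see constant_acf())"))
  }
  for (b in which(is.na(rho))) {
    nearest <- populated[which.min(abs(populated - b))]
    rho[b] <- rho[nearest]
    fallback[b] <- TRUE
  }
  out <- tibble::tibble(
    lag_lo = (seq_len(nbins) - 1) * step,
    lag_hi = seq_len(nbins) * step,
    rho = rho,
    n_pairs = as.integer(n_pairs),
    fallback = fallback
  )
  attr(out, "max_lag") <- max_lag
  attr(out, "step") <- step
  class(out) <- c("acf_estimate", class(out))
  out
}

#' A constant (injected) autocorrelation estimate
#'
#' Useful for tiny inputs where the empirical ACF is unidentifiable, and for
#' oracle tests that must pin the correlation structure.
#' @param rho correlation used at every lag in `(0, max_lag]`.
#' @param max_lag,step bin structure in bp.
#' @return An `acf_estimate`.
#' @export
constant_acf <- function(rho = 0, max_lag = 1000, step = 50) {
  stopifnot(rho >= 0, rho <= 0.99, max_lag %% step == 0)
  nbins <- as.integer(max_lag / step)
  out <- tibble::tibble(
    lag_lo = (seq_len(nbins) - 1) * step,
    lag_hi = seq_len(nbins) * step,
    rho = rho,
    n_pairs = NA_integer_,
    fallback = FALSE
  )
  attr(out, "max_lag") <- max_lag
  attr(out, "step") <- step
  class(out) <- c("acf_estimate", class(out))
  out
}

#' Look up the ACF correlation at given distances
#'
#' Lag 0 maps to 1; lags beyond `max_lag` map to 0.
#' @param acf an `acf_estimate`.
#' @param d numeric vector of distances in bp.
#' @return Numeric vector of correlations.
#' @export
acf_rho <- function(acf, d) {
  step <- attr(acf, "step")
  max_lag <- attr(acf, "max_lag")
  out <- numeric(length(d))
  out[d == 0] <- 1
  inside <- d > 0 & d <= max_lag
  out[inside] <- acf$rho[ceiling(d[inside] / step)]
  out
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Combines p-values via summed probit scores with a variance correction for
#' their correlation: \eqn{z_i = \Phi^{-1}(1-p_i)},
#' \eqn{z_{comb} = \sum z_i / \sqrt{\sum_{ij} \sigma_{ij}}}, returning
#' \eqn{1 - \Phi(z_{comb})}. p-values are clamped to
#' \eqn{[10^{-300}, 1-10^{-16}]} before the probit.
#'
#' @param p vector of p-values in (0, 1).
#' @param sigma correlation matrix (symmetric, unit diagonal); a scalar is
#'   treated as the common off-diagonal correlation.
#' @return Combined p-value.
#' @export
stouffer_liptak <- function(p, sigma) {
  k <- length(p)
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == k, ncol(sigma) == k)
  } else {
    stopifnot(length(sigma) == 1)
    sigma <- matrix(sigma, k, k)
    diag(sigma) <- 1
  }
  denom <- sum(sigma)
  if (denom <= 0) abort("sum of the correlation matrix must be positive")
  z <- probit_score(p)
  pc <- pnorm(sum(z) / sqrt(denom), lower.tail = FALSE)
  min(max(pc, 1e-300), 1)
}

#' Sliding-window Stouffer-Liptak adjustment of per-probe p-values
#'
#' For each probe, combines the raw p-values of all same-chromosome probes
#' within `dist/2` bp on either side (itself included), with pairwise
#' correlations taken from the ACF bin of their separation. A probe with no
#' neighbours keeps its raw p.
#'
#' @param ewas_results genome-sorted EWAS tibble.
#' @param acf an `acf_estimate`.
#' @param dist window width in bp (the window extends `dist/2` each way).
#' @return The input tibble with a `p_adj` column appended.
#' @export
sliding_window_adjust <- function(ewas_results, acf, dist = 1000) {
  check_sorted(ewas_results)
  half <- dist / 2
  p_adj <- ewas_results$p_value
  z <- probit_score(ewas_results$p_value)
  for (idx in split(seq_len(nrow(ewas_results)), ewas_results$chrom)) {
    pos <- ewas_results$pos[idx]
    n <- length(pos)
    lo <- 1L
    hi <- 1L
    for (i in seq_len(n)) {
      while (pos[i] - pos[lo] > half) lo <- lo + 1L
      if (hi < i) hi <- i
      while (hi < n && pos[hi + 1] - pos[i] <= half) hi <- hi + 1L
      if (hi == lo) next
      w <- lo:hi
      dmat <- abs(outer(pos[w], pos[w], "-"))
      sig <- matrix(acf_rho(acf, as.vector(dmat)), length(w), length(w))
      zc <- sum(z[idx[w]]) / sqrt(sum(sig))
      p_adj[idx[i]] <- min(max(pnorm(zc, lower.tail = FALSE), 1e-300), 1)
    }
  }
  dplyr::mutate(ewas_results, p_adj = p_adj)
}

#' Grow candidate DMRs from window-adjusted p-values
#'
#' A region is seeded at any probe with adjusted p below `seed_p` and extended
#' bidirectionally over consecutive probes with adjusted p below
#' `region_filter_p`, provided each inter-probe gap is at most `dist` bp.
#' Overlapping grown regions merge (runs are maximal), and regions with fewer
#' than `region_filter_n` probes are discarded. Region direction is the sign
#' of the member-probe mean `delta_beta` (ties resolved to `hypo`).
#'
#' @param adjusted genome-sorted tibble from [sliding_window_adjust()].
#' @param seed_p seeding threshold on adjusted p.
#' @param dist maximum inter-probe gap within a region, bp.
#' @param region_filter_p extension threshold on adjusted p.
#' @param region_filter_n minimum member probes.
#' @return Tibble of candidate regions: `chrom`, `start` (0-based), `end`,
#'   `n_probes`, `direction`, list-column `probe_ids`, list-column `member_rows`
#'   (member row indices into `adjusted`).
#' @export
find_regions <- function(adjusted, seed_p = 1e-5, dist = 1000,
                         region_filter_p = 0.05, region_filter_n = 2) {
  check_sorted(adjusted)
  out <- list()
  for (idx in split(seq_len(nrow(adjusted)), adjusted$chrom)) {
    pos <- adjusted$pos[idx]
    pa <- adjusted$p_adj[idx]
    pass <- pa < region_filter_p
    n <- length(idx)
    i <- 1L
    while (i <= n) {
      if (!pass[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && pass[j + 1] && pos[j + 1] - pos[j] <= dist) j <- j + 1L
      run <- i:j
      if (length(run) >= region_filter_n && any(pa[run] < seed_p)) {
        rows <- idx[run]
        mean_db <- mean(adjusted$delta_beta[rows])
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = adjusted$chrom[rows[1]],
          start = min(adjusted$pos[rows]) - 1,
          end = max(adjusted$pos[rows]),
          n_probes = length(rows),
          direction = if (mean_db > 0) "hyper" else "hypo",
          probe_ids = list(adjusted$probe_id[rows]),
          member_rows = list(rows)
        )
      }
      i <- j + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_probes = integer(), direction = character(),
      probe_ids = list(), member_rows = list()
    ))
  }
  dplyr::bind_rows(out)
}

#' Score a region: combined and Sidak-corrected p-values
#'
#' The combined p is the Stouffer-Liptak combination of the *raw* member
#' p-values with ACF-derived correlations. The Sidak correction accounts for
#' the effective number of same-width tests genome-wide:
#' \eqn{p_{sidak} = 1 - (1 - p_{comb})^{B/w}} with \eqn{w} the region span in
#' bp (minimum 1) and \eqn{B} the total bases spanned by tested probes (sum
#' over chromosomes of max pos − min pos); the exponent is floored at 1.
#'
#' @param region one row of the [find_regions()] output.
#' @param ewas_results the genome-sorted EWAS tibble (raw p-values).
#' @param acf an `acf_estimate`.
#' @return Named list with `p_combined` and `p_sidak`.
#' @export
score_region <- function(region, ewas_results, acf) {
  rows <- region$member_rows[[1]]
  p <- ewas_results$p_value[rows]
  pos <- ewas_results$pos[rows]
  dmat <- abs(outer(pos, pos, "-"))
  sig <- matrix(acf_rho(acf, as.vector(dmat)), length(pos), length(pos))
  p_comb <- stouffer_liptak(p, sig)
  b_total <- total_tested_span(ewas_results)
  w <- max(region$end - region$start, 1)
  expo <- max(b_total / w, 1)
  p_sidak <- -expm1(expo * log1p(-p_comb))
  p_sidak <- min(max(p_sidak, p_comb), 1)
  list(p_combined = p_comb, p_sidak = p_sidak)
}

total_tested_span <- function(ewas_results) {
  spans <- tapply(ewas_results$pos, ewas_results$chrom,
                  function(x) max(x) - min(x))
  sum(spans)
}

#' Call DMRs from a beta matrix
#'
#' End-to-end native combined-p DMR calling: EWAS, ACF estimation,
#' sliding-window adjustment, seeded region growth, and region scoring.
#'
#' @param beta probe-by-sample beta matrix.
#' @param groups sample grouping (see [ewas()]).
#' @param manifest probe manifest (for coordinates and, later, gene
#'   assignment).
#' @param seed_p,dist,region_filter_p,region_filter_n region-calling options
#'   (defaults match the published comb-p settings `--seed 1e-5 --dist 1000
#'   --region-filter-p 0.05 --region-filter-n 2`).
#' @param acf optional injected `acf_estimate`; estimated from the data when
#'   `NULL`.
#' @param acf_step ACF bin width in bp.
#' @return A list of class `dmr_scan`: `ewas` (per-probe results with
#'   `p_adj`), `acf`, and `dmrs` — a tibble with coordinates, member probes,
#'   `p_combined`, `p_sidak`, `direction` and assigned `genes`.
#' @export
call_dmrs <- function(beta, groups, manifest,
                      seed_p = 1e-5, dist = 1000,
                      region_filter_p = 0.05, region_filter_n = 2,
                      acf = NULL, acf_step = 50) {
  ew <- ewas(beta, groups, manifest)
  if (is.null(acf)) acf <- estimate_acf(ew, max_lag = dist, step = acf_step)
  adj <- sliding_window_adjust(ew, acf, dist = dist)
  regions <- find_regions(adj, seed_p = seed_p, dist = dist,
                          region_filter_p = region_filter_p,
                          region_filter_n = region_filter_n)
  if (nrow(regions) > 0) {
    scores <- lapply(seq_len(nrow(regions)), function(i) {
      score_region(regions[i, ], adj, acf)
    })
    regions$p_combined <- vapply(scores, `[[`, numeric(1), "p_combined")
    regions$p_sidak <- vapply(scores, `[[`, numeric(1), "p_sidak")
    ann <- dplyr::filter(manifest, !is.na(.data$gene))
    regions$genes <- lapply(regions$probe_ids, function(ids) {
      sort(unique(ann$gene[ann$probe_id %in% ids]))
    })
  } else {
    regions$p_combined <- numeric(0)
    regions$p_sidak <- numeric(0)
    regions$genes <- list()
  }
  structure(list(ewas = adj, acf = acf, dmrs = regions), class = "dmr_scan")
}

#' Assign scored DMRs to genes through promoter/5'UTR probes
#'
#' A gene is called hypermethylated iff at least one DMR (i) has direction
#' `hyper`, (ii) has `p_sidak` below `gene_dmr_p`, and (iii) contains a member
#' probe annotated to that gene with a promoter-proximal region class
#' (TSS200/TSS1500/5'UTR by default). Multi-gene probes fan out to every
#' annotated gene, each judged against its own region class.
#'
#' @param dmrs scored DMR tibble (from [call_dmrs()]`$dmrs`).
#' @param manifest long-format probe manifest.
#' @param gene_dmr_p significance threshold on `p_sidak`.
#' @param classes promoter-proximal region classes.
#' @return Tibble with one row per gene touched by any DMR probe annotation:
#'   `gene`, `hypermethylated`, `best_p_sidak` (minimum qualifying `p_sidak`,
#'   `NA` if none), `n_regions` (qualifying region count).
#' @export
assign_regions_to_genes <- function(dmrs, manifest, gene_dmr_p = 1e-5,
                                    classes = promoter_classes()) {
  if (nrow(dmrs) == 0) {
    return(tibble::tibble(gene = character(), hypermethylated = logical(),
                          best_p_sidak = numeric(), n_regions = integer()))
  }
  ann <- dplyr::filter(manifest, !is.na(.data$gene))
  touched <- dmrs |>
    dplyr::mutate(.region = dplyr::row_number()) |>
    dplyr::select(".region", "probe_ids", "direction", "p_sidak") |>
    tidyr::unnest_longer("probe_ids", values_to = "probe_id") |>
    dplyr::inner_join(ann, by = "probe_id", relationship = "many-to-many")
  touched |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      hypermethylated = any(.data$direction == "hyper" &
                              .data$p_sidak < gene_dmr_p &
                              .data$region_class %in% classes),
      best_p_sidak = {
        q <- .data$p_sidak[.data$direction == "hyper" &
                             .data$p_sidak < gene_dmr_p &
                             .data$region_class %in% classes]
        if (length(q) > 0) min(q) else NA_real_
      },
      n_regions = dplyr::n_distinct(.data$.region[.data$direction == "hyper" &
                                                    .data$p_sidak < gene_dmr_p &
                                                    .data$region_class %in% classes]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$best_p_sidak, .data$gene)
}

check_sorted <- function(tbl) {
  need <- c("chrom", "pos", "p_value")
  if (!all(need %in% names(tbl))) {
    abort("expected a genome-annotated EWAS tibble with chrom, pos, p_value")
  }
  o <- order(tbl$chrom, tbl$pos)
  if (!identical(o, seq_len(nrow(tbl)))) {
    abort("results must be genome-sorted by (chrom, pos)")
  }
  invisible(tbl)
}
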