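# Native pre-ranked GSEA: fold-change ranking, weighted Kolmogorov-Smirnov
# enrichment score, gene-label permutation NES / nominal p / FDR q.

#' Rank genes by mean expression difference between two strata
#'
#' The ranking metric is the mean log2(1+x) expression in stratum A minus the
#' mean in stratum B, per gene, sorted descending. Ties are broken
#' deterministically (metric descending, then symbol ascending) so downstream
#' results are reproducible.
#'
#' @param expr gene-by-sample expression matrix.
#' @param samples_a,samples_b sample ids of the two strata.
#' @return Tibble of class `ranked_list`: `gene`, `metric`, in rank order.
#' @export
rank_genes <- function(expr, samples_a, samples_b) {
  samples_a <- intersect(samples_a, colnames(expr))
  samples_b <- intersect(samples_b, colnames(expr))
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    abort("both strata need >= 2 samples")
  }
  metric <- rowMeans(expr[, samples_a, drop = FALSE]) -
    rowMeans(expr[, samples_b, drop = FALSE])
  ord <- order(-metric, rownames(expr))
  out <- tibble::tibble(gene = rownames(expr)[ord], metric = unname(metric[ord]))
  class(out) <- c("ranked_list", class(out))
  out
}

# Enrichment score from sorted hit indices. Hits increment the running sum by
# |metric|^weight / sum(|metric|^weight over hits); misses decrement by
# 1/(N - N_hits). The extremum can only occur immediately after a hit (for
# the maximum) or immediately before one (for the minimum), which makes the
# walk O(N_hits). All-zero hit weights fall back to equal increments (the
# unweighted KS statistic).
es_core <- function(hit_idx, hit_w, n_total) {
  nh <- length(hit_idx)
  tot <- sum(hit_w)
  inc <- if (tot > 0) hit_w / tot else rep(1 / nh, nh)
  miss_dec <- 1 / (n_total - nh)
  after <- cumsum(inc) - (hit_idx - seq_len(nh)) * miss_dec
  before <- after - inc
  i_max <- which.max(after)
  i_min <- which.min(before)
  es_pos <- after[i_max]
  es_neg <- min(before[i_min], 0)
  if (es_pos >= -es_neg) {
    list(es = es_pos, extremum = i_max, positive = TRUE)
  } else {
    list(es = es_neg, extremum = i_min, positive = FALSE)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; genes in the set ("hits") increment the running sum
#' proportionally to |metric|^weight, the rest decrement it uniformly. The
#' enrichment score is the extremum of maximal absolute deviation (signed);
#' the leading edge is the hits up to the extremum (positive ES) or after it
#' (negative ES). Set genes absent from the ranked universe are dropped; the
#' intersection must be a non-empty proper subset.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of gene symbols.
#' @param weight metric exponent (1 = classic weighted ES, 0 = unweighted
#'   KS).
#' @return List: `es`, `leading_edge`, `n_hits`, and `running` — a tibble of
#'   the full running sum for plotting.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  n <- nrow(ranked)
  hit_idx <- sort(which(ranked$gene %in% gene_set))
  if (length(hit_idx) == 0 || length(hit_idx) == n) {
    abort("undefined ES: gene set intersection is empty or the full list")
  }
  hit_w <- abs(ranked$metric[hit_idx])^weight
  core <- es_core(hit_idx, hit_w, n)
  leading <- if (core$positive) {
    ranked$gene[hit_idx[seq_len(core$extremum)]]
  } else {
    ranked$gene[hit_idx[core$extremum:length(hit_idx)]]
  }
  tot <- sum(hit_w)
  inc_full <- numeric(n)
  inc_full[hit_idx] <- if (tot > 0) hit_w / tot else 1 / length(hit_idx)
  inc_full[-hit_idx] <- -1 / (n - length(hit_idx))
  list(
    es = core$es,
    leading_edge = leading,
    n_hits = length(hit_idx),
    running = tibble::tibble(rank = seq_len(n), score = cumsum(inc_full))
  )
}

#' Permutation significance for a gene set collection
#'
#' Gene-label permutations: for each set size, `nperm` size-matched random
#' sets are drawn from the ranked universe. The normalised enrichment score
#' is ES divided by the mean |permutation ES| of matching sign; the nominal p
#' is the add-one-corrected fraction of matching-sign permutation scores at
#' least as extreme; the FDR q follows the NES-ratio procedure of the
#' original GSEA method over the pooled observed and permuted NES. A set with
#' no matching-sign permutations is flagged with `NES = NA`. Deterministic
#' given `seed`.
#'
#' @param ranked a `ranked_list`.
#' @param collection named list of gene sets.
#' @param nperm number of permutations (>= 100).
#' @param weight metric exponent.
#' @param seed RNG seed.
#' @param nominal_p,fdr significance thresholds (defaults 0.05 and 0.25).
#' @return Tibble of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `significant`, `leading_edge` (list-column),
#'   `flagged`.
#' @export
permutation_significance <- function(ranked, collection, nperm = 1000,
                                     weight = 1, seed = 1L,
                                     nominal_p = 0.05, fdr = 0.25) {
  if (nperm < 100) abort("nperm must be >= 100")
  n <- nrow(ranked)
  w_all <- abs(ranked$metric)^weight
  obs <- lapply(collection, function(gs) {
    hit_idx <- sort(which(ranked$gene %in% gs))
    if (length(hit_idx) == 0 || length(hit_idx) == n) return(NULL)
    core <- es_core(hit_idx, w_all[hit_idx], n)
    leading <- if (core$positive) {
      ranked$gene[hit_idx[seq_len(core$extremum)]]
    } else {
      ranked$gene[hit_idx[core$extremum:length(hit_idx)]]
    }
    list(es = core$es, size = length(hit_idx), leading = leading)
  })
  keep <- !vapply(obs, is.null, logical(1))
  if (!all(keep)) {
    warn(paste0("dropping set(s) with empty or full-list intersection: ",
                paste(names(collection)[!keep], collapse = ", ")))
  }
  obs <- obs[keep]
  if (length(obs) == 0) abort("no testable gene sets")
  sizes <- vapply(obs, `[[`, integer(1), "size")

  # one permutation ES matrix per distinct set size, shared across sets
  perm_by_size <- list()
  for (s in sort(unique(sizes))) {
    key <- as.character(s)
    perm_by_size[[key]] <- with_seed(derive_seed(seed, s), {
      vapply(seq_len(nperm), function(b) {
        idx <- sort(sample.int(n, s))
        es_core(idx, w_all[idx], n)$es
      }, numeric(1))
    })
  }

  res <- purrr::imap(obs, function(o, nm) {
    perm <- perm_by_size[[as.character(o$size)]]
    same <- if (o$es >= 0) perm[perm >= 0] else perm[perm < 0]
    if (length(same) == 0) {
      return(tibble::tibble(set = nm, size = o$size, es = o$es, nes = NA_real_,
                            nominal_p = NA_real_, fdr_q = NA_real_,
                            significant = FALSE,
                            leading_edge = list(o$leading), flagged = TRUE))
    }
    nes <- o$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
    tibble::tibble(set = nm, size = o$size, es = o$es, nes = nes,
                   nominal_p = p, fdr_q = NA_real_, significant = FALSE,
                   leading_edge = list(o$leading), flagged = FALSE)
  }) |> dplyr::bind_rows()

  # FDR: normalise every permutation ES by its size's matching-sign mean and
  # compare tail fractions of the pooled permuted NES against the observed.
  perm_nes <- unlist(lapply(sort(unique(sizes)), function(s) {
    perm <- perm_by_size[[as.character(s)]]
    mp <- mean(perm[perm >= 0])
    mn <- mean(abs(perm[perm < 0]))
    out <- numeric(length(perm))
    out[perm >= 0] <- if (is.nan(mp)) NA else perm[perm >= 0] / mp
    out[perm < 0] <- if (is.nan(mn)) NA else perm[perm < 0] / mn
    out
  }))
  perm_nes <- perm_nes[!is.na(perm_nes)]
  obs_nes <- res$nes[!is.na(res$nes)]
  q_for <- function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      denom_perm <- sum(perm_nes >= 0)
      denom_obs <- sum(obs_nes >= 0)
      num_perm <- sum(perm_nes >= nes)
      num_obs <- sum(obs_nes >= nes)
    } else {
      denom_perm <- sum(perm_nes < 0)
      denom_obs <- sum(obs_nes < 0)
      num_perm <- sum(perm_nes <= nes)
      num_obs <- sum(obs_nes <= nes)
    }
    if (denom_perm == 0 || denom_obs == 0 || num_obs == 0) return(1)
    min(1, (num_perm / denom_perm) / (num_obs / denom_obs))
  }
  res$fdr_q <- vapply(res$nes, q_for, numeric(1))
  res$significant <- !res$flagged & res$nominal_p < nominal_p & res$fdr_q < fdr
  class(res) <- c("gsea_result", class(res))
  attr(res, "nperm") <- nperm
  attr(res, "weight") <- weight
  res
}

#' Shared/distinct signature table across the two inactivation contrasts
#'
#' Joins the GSEA results of the METH-vs-CTRL and LOFDEL-vs-CTRL contrasts
#' and categorises each set: `shared-enriched` / `shared-depleted`
#' (significant with the same ES sign in both), `METH-only` / `LOFDEL-only`
#' (significant in one), `discordant` (significant in both with opposite
#' signs — e.g. immune programmes enriched under methylation silencing but
#' depleted under genetic loss), or `ns`.
#'
#' @param results_meth,results_lofdel `gsea_result` tibbles over the same
#'   collection.
#' @return Tibble `set`, `nes_meth`, `nes_lofdel`, `category`.
#' @export
dual_contrast_report <- function(results_meth, results_lofdel) {
  joined <- dplyr::full_join(
    dplyr::select(results_meth, "set", nes_meth = "nes", sig_meth = "significant",
                  es_meth = "es"),
    dplyr::select(results_lofdel, "set", nes_lofdel = "nes",
                  sig_lofdel = "significant", es_lofdel = "es"),
    by = "set"
  )
  joined |>
    dplyr::mutate(
      sig_meth = dplyr::coalesce(.data$sig_meth, FALSE),
      sig_lofdel = dplyr::coalesce(.data$sig_lofdel, FALSE),
      category = dplyr::case_when(
        sig_meth & sig_lofdel & es_meth > 0 & es_lofdel > 0 ~ "shared-enriched",
        sig_meth & sig_lofdel & es_meth < 0 & es_lofdel < 0 ~ "shared-depleted",
        sig_meth & sig_lofdel ~ "discordant",
        sig_meth ~ "METH-only",
        sig_lofdel ~ "LOFDEL-only",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::select("set", "nes_meth", "nes_lofdel", "category")
}
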