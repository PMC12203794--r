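# Genetic-alteration classification, frequencies, and the mutually exclusive
# METH / LOFDEL / CTRL stratification of a target gene.

#' The retained loss-of-function consequence vocabulary
#'
#' Consequence terms treated as loss-of-function: stop gained, start lost,
#' frameshift, in-frame insertion/deletion, protein-altering. Missense
#' variants are deliberately excluded — without functional annotation their
#' effect is ambiguous.
#' @return Character vector of normalised consequence terms.
#' @export
lof_consequences <- function() {
  c("stop_gained", "start_lost", "frameshift_variant",
    "inframe_deletion", "inframe_insertion", "protein_altering_variant")
}

known_non_lof <- function() {
  c("missense_variant", "synonymous_variant", "stop_lost",
    "splice_region_variant", "splice_acceptor_variant", "splice_donor_variant",
    "intron_variant", "five_prime_utr_variant", "three_prime_utr_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "intergenic_variant", "non_coding_transcript_variant")
}

#' Classify a consequence term as loss-of-function
#'
#' Closed-vocabulary membership test against [lof_consequences()]. Terms
#' outside the known vocabulary return `FALSE` with a warning, never an
#' error. Accepts un-normalised spellings (normalised internally). The
#' spellings `in_frame_deletion`/`in_frame_insertion` are folded onto the
#' retained in-frame terms.
#'
#' @param consequence character vector of consequence terms.
#' @return Logical vector.
#' @export
classify_lof <- function(consequence) {
  x <- normalise_consequence(consequence)
  x[x %in% c("in_frame_deletion", "in_frame_insertion")] <-
    sub("in_frame", "inframe", x[x %in% c("in_frame_deletion", "in_frame_insertion")])
  unknown <- setdiff(unique(x), c(lof_consequences(), known_non_lof()))
  if (length(unknown) > 0) {
    warn(paste0("unknown consequence term(s) treated as non-LOF: ",
                paste(unknown, collapse = ", ")))
  }
  x %in% lof_consequences()
}

#' Per-gene genetic-alteration frequencies
#'
#' For each requested gene, the fraction of the sample universe carrying at
#' least one LOF mutation (`f_lof`), a deep deletion — copy-number category
#' -2 — (`f_del`), and their union (`f_total`; a sample with both counts
#' once). All fractions use the full universe as denominator. Genes are
#' ranked descending by the requested frequency, ties broken by symbol.
#'
#' @param mutations mutation tibble (`sample_id`, `gene`, `consequence`) or
#'   `NULL`.
#' @param cnas CNA tibble (`sample_id`, `gene`, `category`) or `NULL`.
#' @param sample_universe all cohort sample ids (samples without records
#'   count in the denominator).
#' @param genes genes to tabulate.
#' @param rank_by which frequency orders the table.
#' @return Ranked tibble `gene`, `f_lof`, `f_del`, `f_total`.
#' @export
alteration_frequencies <- function(mutations, cnas, sample_universe, genes,
                                   rank_by = c("total", "lof", "del")) {
  rank_by <- match.arg(rank_by)
  if (length(sample_universe) == 0) abort("sample universe is empty")
  n <- length(sample_universe)
  lof_tbl <- if (!is.null(mutations) && nrow(mutations) > 0) {
    dplyr::filter(mutations, classify_lof(.data$consequence),
                  .data$gene %in% genes,
                  .data$sample_id %in% sample_universe)
  } else tibble::tibble(sample_id = character(), gene = character())
  del_tbl <- if (!is.null(cnas) && nrow(cnas) > 0) {
    dplyr::filter(cnas, .data$category == -2L, .data$gene %in% genes,
                  .data$sample_id %in% sample_universe)
  } else tibble::tibble(sample_id = character(), gene = character())
  per_gene <- function(g) {
    s_lof <- unique(lof_tbl$sample_id[lof_tbl$gene == g])
    s_del <- unique(del_tbl$sample_id[del_tbl$gene == g])
    tibble::tibble(
      gene = g,
      f_lof = length(s_lof) / n,
      f_del = length(s_del) / n,
      f_total = length(union(s_lof, s_del)) / n
    )
  }
  out <- dplyr::bind_rows(lapply(genes, per_gene))
  key <- switch(rank_by, total = out$f_total, lof = out$f_lof, del = out$f_del)
  out[order(-key, out$gene), ]
}

#' Stratify a cohort by target-gene inactivation mechanism
#'
#' Builds the three mutually exclusive strata used to contrast epigenetic and
#' genetic silencing of a target gene:
#' \describe{
#'   \item{LOFDEL}{samples with a LOF mutation or deep deletion of the
#'     target (genetic inactivation takes precedence, which keeps the strata
#'     disjoint by construction).}
#'   \item{METH}{driver-high samples whose target promoter mean beta exceeds
#'     the `meth_quantile` (default 90th) percentile of the driver-low
#'     population *and* whose target expression is below the cohort median,
#'     excluding any LOFDEL sample.}
#'   \item{CTRL}{driver-low samples with no genetic alteration of the
#'     target.}
#' }
#' Remaining samples are `unassigned`. The sample-level methylation rule is a
#' documented operational construction; the quantile is exposed for
#' sensitivity analyses.
#'
#' @param bundle a `cohort_bundle` with methylation, mutations and CNAs.
#' @param driver_gene driver gene symbol (median split defines driver-high).
#' @param target_gene target gene symbol.
#' @param meth_quantile driver-low promoter-beta quantile defining the
#'   hypermethylation threshold.
#' @param classes promoter-proximal region classes.
#' @return Tibble of class `stratum_assignment` `(sample_id, stratum)` with
#'   attributes `target`, `driver`, `beta_threshold`.
#' @export
stratify_target <- function(bundle, driver_gene, target_gene,
                            meth_quantile = 0.9, classes = promoter_classes()) {
  if (is.null(bundle$methylation) || is.null(bundle$manifest)) {
    abort("stratification needs a cohort with methylation data")
  }
  if (is.null(bundle$mutations) && is.null(bundle$cnas)) {
    abort("stratification needs mutation and/or CNA tables")
  }
  expr <- bundle$expression
  samples <- colnames(expr)
  grp <- as_group_vector(split_by_driver(expr, driver_gene))[samples]
  promb <- promoter_mean_beta(bundle$methylation, bundle$manifest,
                              target_gene, classes)[samples]

  lof_samples <- character(0)
  if (!is.null(bundle$mutations) && nrow(bundle$mutations) > 0) {
    m <- bundle$mutations
    lof_samples <- unique(m$sample_id[m$gene == target_gene &
                                        classify_lof(m$consequence)])
  }
  del_samples <- character(0)
  if (!is.null(bundle$cnas) && nrow(bundle$cnas) > 0) {
    cn <- bundle$cnas
    del_samples <- unique(cn$sample_id[cn$gene == target_gene & cn$category == -2L])
  }
  lofdel <- intersect(union(lof_samples, del_samples), samples)

  thr <- quantile(promb[grp == "low"], meth_quantile, na.rm = TRUE, names = FALSE)
  tx <- expr[target_gene, samples]
  med <- median(tx)
  meth <- samples[grp == "high" & promb > thr & tx < med & !(samples %in% lofdel)]
  ctrl <- samples[grp == "low" & !(samples %in% lofdel)]
  if (length(ctrl) == 0) abort("empty CTRL stratum: contrasts are undefined")

  stratum <- rep("unassigned", length(samples))
  stratum[samples %in% lofdel] <- "LOFDEL"
  stratum[samples %in% meth] <- "METH"
  stratum[samples %in% ctrl] <- "CTRL"
  stopifnot(length(intersect(meth, lofdel)) == 0,
            length(intersect(ctrl, c(meth, lofdel))) == 0)
  out <- tibble::tibble(sample_id = samples, stratum = stratum)
  class(out) <- c("stratum_assignment", class(out))
  attr(out, "target") <- target_gene
  attr(out, "driver") <- driver_gene
  attr(out, "beta_threshold") <- thr
  out
}

#' Stratum frequencies as percentages of the cohort
#'
#' @param assignment a `stratum_assignment`.
#' @return Tibble `stratum`, `n`, `pct` covering METH, LOFDEL, CTRL and
#'   unassigned.
#' @export
stratum_frequencies <- function(assignment) {
  n_total <- nrow(assignment)
  assignment |>
    dplyr::count(.data$stratum, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / n_total)
}

#' Combined inactivation percentage of the target gene
#'
#' Because METH and LOFDEL are disjoint by construction, the combined
#' inactivation frequency is exactly the sum of the two stratum percentages;
#' the identity is asserted, not assumed.
#' @param assignment a `stratum_assignment`.
#' @return Percentage of the cohort in METH or LOFDEL.
#' @export
combined_inactivation_pct <- function(assignment) {
  freq <- stratum_frequencies(assignment)
  pct <- function(s) {
    v <- freq$pct[freq$stratum == s]
    if (length(v) == 0) 0 else v
  }
  n_union <- sum(assignment$stratum %in% c("METH", "LOFDEL"))
  combined <- 100 * n_union / nrow(assignment)
  stopifnot(isTRUE(all.equal(combined, pct("METH") + pct("LOFDEL"))))
  combined
}

#' Survival and subtype summaries of the strata
#'
#' Pairwise METH-vs-CTRL and LOFDEL-vs-CTRL contrasts (log-rank chi-squared
#' and a Cox hazard ratio for membership in the inactivated stratum relative
#' to CTRL), plus the molecular-subtype composition of each stratum
#' (percentages over samples with a known subtype, summing to 100 within a
#' stratum). Strata smaller than 5 samples are summarised with a
#' small-sample flag.
#'
#' @param assignment a `stratum_assignment`.
#' @param clinical clinical tibble with `sample_id`, `dfs_time`, `dfs_event`
#'   and optional `subtype`.
#' @return List of class `stratum_summary`: `survival` (one row per
#'   contrast) and `composition`.
#' @export
stratum_summaries <- function(assignment, clinical) {
  df <- dplyr::inner_join(assignment, clinical, by = "sample_id")
  present <- intersect(c("METH", "LOFDEL", "CTRL"), unique(df$stratum))
  if (length(present) < 2 || !"CTRL" %in% present) {
    abort("need CTRL plus at least one inactivated stratum")
  }
  ctrl <- dplyr::filter(df, .data$stratum == "CTRL")
  contrast <- function(name) {
    grp <- dplyr::filter(df, .data$stratum == name)
    small <- nrow(grp) < 5 || nrow(ctrl) < 5
    lr <- tryCatch(
      logrank_test(grp$dfs_time, grp$dfs_event, ctrl$dfs_time, ctrl$dfs_event),
      error = function(e) tibble::tibble(chi2 = NA_real_, p_value = NA_real_,
                                         n = nrow(grp) + nrow(ctrl),
                                         n_events = NA_real_)
    )
    cx <- tryCatch({
      both <- dplyr::bind_rows(grp, ctrl)
      cox_fit(both$dfs_time, both$dfs_event,
              as.numeric(both$stratum == name))
    }, error = function(e) tibble::tibble(hr = NA_real_, p_value = NA_real_))
    tibble::tibble(
      contrast = paste0(name, "_vs_CTRL"),
      n = nrow(grp), n_ctrl = nrow(ctrl),
      chi2 = lr$chi2, logrank_p = lr$p_value,
      hr = cx$hr, cox_p = cx$p_value,
      small_sample = small
    )
  }
  surv_tbl <- dplyr::bind_rows(lapply(setdiff(present, "CTRL"), contrast))
  comp <- df |>
    dplyr::filter(.data$stratum != "unassigned", !is.na(.data$subtype)) |>
    dplyr::count(.data$stratum, .data$subtype, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(survival = surv_tbl, composition = comp),
            class = "stratum_summary")
}
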