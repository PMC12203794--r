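# broom-style tidiers for the package's composite result objects.

#' Tidy a survival screen
#' @param x a `survival_screen`.
#' @param ... unused.
#' @return The per-(gene, cohort) results tibble.
#' @method tidy survival_screen
#' @export
tidy.survival_screen <- function(x, ...) {
  x$results
}

#' One-row summary of a survival screen
#' @param x a `survival_screen`.
#' @param ... unused.
#' @return Tibble with candidate/consensus counts and the filter settings.
#' @method glance survival_screen
#' @export
glance.survival_screen <- function(x, ...) {
  tibble::tibble(
    n_genes = dplyr::n_distinct(x$results$gene),
    n_cohorts = dplyr::n_distinct(x$results$cohort_id),
    n_passing = sum(x$consensus$passes),
    alpha = x$alpha,
    min_cohorts = x$min_cohorts
  )
}

#' Tidy a DMR scan
#' @param x a `dmr_scan`.
#' @param ... unused.
#' @return The DMR tibble without list-columns.
#' @method tidy dmr_scan
#' @export
tidy.dmr_scan <- function(x, ...) {
  d <- x$dmrs
  d$probe_ids <- NULL
  d$member_rows <- NULL
  d$genes <- vapply(x$dmrs$genes, function(g) paste(g, collapse = ","), character(1))
  d
}

#' One-row summary of a DMR scan
#' @param x a `dmr_scan`.
#' @param ... unused.
#' @return Tibble with probe, region and significance counts.
#' @method glance dmr_scan
#' @export
glance.dmr_scan <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$ewas),
    n_regions = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    min_p_sidak = if (nrow(x$dmrs) > 0) min(x$dmrs$p_sidak) else NA_real_
  )
}

#' One-row summary of a discovery report
#' @param x a `discovery_report`.
#' @param ... unused.
#' @return Tibble of the cascade counts.
#' @method glance discovery_report
#' @export
glance.discovery_report <- function(x, ...) {
  tibble::as_tibble(x$counts) |>
    dplyr::mutate(consensus_yield_pct = x$consensus_yield_pct,
                  combined_inactivation_pct = x$combined_inactivation_pct)
}
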