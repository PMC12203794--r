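#' Per-probe epigenome-wide association study
#'
#' For every probe, ordinary least squares of the beta value on the 0/1
#' driver-group indicator — numerically identical to the equal-variance
#' two-sample t-test — with a two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom. Missing beta values are dropped pairwise per
#' probe. Probes with zero variance return `delta_beta = 0`, `p = 1`; probes
#' with fewer than two usable samples in either group are emitted with
#' `p = 1` and flag `"insufficient_data"` rather than dropped.
#'
#' @param beta probe-by-sample beta matrix (values in \eqn{[0,1]}, `NA`
#'   allowed).
#' @param groups sample grouping: tibble `(sample_id, group)` or named vector
#'   with values `"high"`/`"low"`.
#' @param manifest optional probe manifest; when supplied, `chrom`/`pos` are
#'   attached and the result is genome-sorted (required downstream by the DMR
#'   caller).
#' @return Tibble with columns `probe_id`, (`chrom`, `pos`,) `delta_beta`
#'   (mean high minus mean low), `t_stat`, `p_value`, `flag`.
#' @export
ewas <- function(beta, groups, manifest = NULL) {
  gv <- as_group_vector(groups)
  common <- intersect(colnames(beta), names(gv))
  if (length(common) < 4) abort("need >= 4 samples shared between beta and groups")
  hi <- common[gv[common] == "high"]
  lo <- common[gv[common] == "low"]
  if (length(hi) < 2 || length(lo) < 2) {
    abort("need >= 2 samples per group")
  }
  stats_hi <- group_rowstats(beta[, hi, drop = FALSE])
  stats_lo <- group_rowstats(beta[, lo, drop = FALSE])
  n1 <- stats_hi$n; n0 <- stats_lo$n
  delta <- stats_hi$mean - stats_lo$mean
  df <- n1 + n0 - 2
  pooled <- (stats_hi$ss + stats_lo$ss) / df
  se <- sqrt(pooled * (1 / n1 + 1 / n0))
  t_stat <- delta / se
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)

  insufficient <- n1 < 2 | n0 < 2
  zero_var <- !insufficient & (pooled <= 0 | !is.finite(se) | se == 0)
  flag <- rep(NA_character_, nrow(beta))
  flag[insufficient] <- "insufficient_data"
  flag[zero_var & delta == 0] <- "zero_variance"
  # constant probe: no evidence either way
  p[zero_var & delta == 0] <- 1
  t_stat[zero_var & delta == 0] <- 0
  # perfectly separated probe: zero within-group variance but distinct means
  p[zero_var & delta != 0] <- 1e-300
  t_stat[zero_var & delta != 0] <- sign(delta[zero_var & delta != 0]) * Inf
  p[insufficient] <- 1
  t_stat[insufficient] <- NA_real_
  delta[is.na(delta)] <- 0
  p <- pmax(p, 1e-300)

  out <- tibble::tibble(
    probe_id = rownames(beta),
    delta_beta = unname(delta),
    t_stat = unname(t_stat),
    p_value = unname(p),
    flag = flag
  )
  if (!is.null(manifest)) {
    coords <- dplyr::distinct(manifest, .data$probe_id, .data$chrom, .data$pos)
    out <- dplyr::inner_join(out, coords, by = "probe_id") |>
      dplyr::relocate("chrom", "pos", .after = "probe_id") |>
      dplyr::arrange(.data$chrom, .data$pos)
  }
  out
}

group_rowstats <- function(x) {
  ok <- !is.na(x)
  n <- rowSums(ok)
  s <- rowSums(x, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x^2, na.rm = TRUE) - n * ifelse(n > 0, m^2, 0)
  ss <- pmax(ss, 0) # guard tiny negative round-off
  list(n = n, mean = m, ss = ss)
}
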