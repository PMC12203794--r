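# Survival screening: Kaplan-Meier, log-rank, Cox PH (through the survival
# package) and the >= k-of-n multi-cohort consensus filter.

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: samples censored at an event time remain at risk
#' through that time.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = relapse, 0 = censored).
#' @return Tibble of class `ep_km`: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("empty survival input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  class(out) <- c("ep_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance at each distinct event
#' time; p from chi-squared with 1 df.
#'
#' @param times_a,events_a group A follow-up times and event indicators.
#' @param times_b,events_b group B follow-up times and event indicators.
#' @return Tibble `chi2`, `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("both groups must be non-empty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    abort("log-rank undefined with zero events")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  tibble::tibble(
    chi2 = unname(fit$chisq),
    p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE),
    n = length(time),
    n_events = sum(event)
  )
}

#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the Breslow-ties partial likelihood
#' (convergence tolerance 1e-9 on the coefficient, at most 50 iterations),
#' with a two-sided Wald p. Non-convergence or monotone-likelihood separation
#' is returned as a flagged result with `p = NA` rather than an error.
#'
#' @param times,events follow-up times and event indicators.
#' @param covariate numeric covariate (typically standardised expression).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Tibble of class `ep_cox`: `beta`, `hr`, `se`, `p_value`,
#'   `n`, `n_events`, `flagged`.
#' @export
cox_fit <- function(times, events, covariate, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(length(times) == length(events), length(times) == length(covariate))
  if (var(covariate) == 0) abort("covariate has zero variance")
  if (sum(events) < 2) abort("need >= 2 events")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(times, events) ~ covariate,
      ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)
    ),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) flagged <- TRUE
  out <- tibble::tibble(
    beta = beta,
    hr = exp(beta),
    se = se,
    p_value = if (flagged) NA_real_ else 2 * pnorm(abs(beta / se), lower.tail = FALSE),
    n = length(times),
    n_events = sum(events),
    flagged = flagged
  )
  class(out) <- c("ep_cox", class(out))
  out
}

#' Multi-cohort gene survival screen with consensus filter
#'
#' Per gene per cohort, two univariate disease-free-survival analyses: a Cox
#' model on the gene's standardised continuous expression, and a log-rank
#' test on the gene's own median split. A (gene, cohort) pair is significant
#' when both p-values are below `alpha` *and* the Cox hazard ratio is below 1
#' (higher expression protective). A gene passes the consensus filter when it
#' is significant in at least `min_cohorts` cohorts. No cross-gene
#' multiplicity correction is applied: replication across cohorts is the
#' guard.
#'
#' @param cohorts list of `cohort_bundle`s (or of lists holding `bundle`).
#' @param genes character vector of candidate genes.
#' @param alpha per-test significance level.
#' @param min_cohorts consensus threshold.
#' @return List of class `survival_screen`: `results` (per gene x cohort:
#'   `gene`, `cohort_id`, `hr`, `cox_p`, `logrank_p`, `n`, `n_events`,
#'   `significant`) and `consensus` (`gene`, `n_significant_cohorts`,
#'   `passes`).
#' @export
gene_survival_screen <- function(cohorts, genes, alpha = 0.05, min_cohorts = 3) {
  bundles <- lapply(cohorts, function(x) if (inherits(x, "cohort_bundle")) x else x$bundle)
  rows <- list()
  for (b in bundles) {
    clin <- b$clinical
    samples <- intersect(colnames(b$expression), clin$sample_id)
    clin <- clin[match(samples, clin$sample_id), ]
    for (g in genes) {
      if (!g %in% rownames(b$expression)) {
        inform(paste0("gene '", g, "' absent from cohort ", b$cohort_id,
                      "; counted non-significant"))
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = g, cohort_id = b$cohort_id, hr = NA_real_, cox_p = NA_real_,
          logrank_p = NA_real_, n = length(samples), n_events = sum(clin$dfs_event),
          significant = FALSE
        )
        next
      }
      x <- b$expression[g, samples]
      res <- tryCatch({
        cx <- cox_fit(clin$dfs_time, clin$dfs_event, as.numeric(scale(x)))
        med <- median(x)
        hi <- x > med
        lr <- logrank_test(clin$dfs_time[hi], clin$dfs_event[hi],
                           clin$dfs_time[!hi], clin$dfs_event[!hi])
        tibble::tibble(
          gene = g, cohort_id = b$cohort_id, hr = cx$hr, cox_p = cx$p_value,
          logrank_p = lr$p_value, n = length(samples), n_events = sum(clin$dfs_event),
          significant = !is.na(cx$p_value) & cx$p_value < alpha &
            lr$p_value < alpha & cx$hr < 1
        )
      }, error = function(e) {
        tibble::tibble(
          gene = g, cohort_id = b$cohort_id, hr = NA_real_, cox_p = NA_real_,
          logrank_p = NA_real_, n = length(samples), n_events = sum(clin$dfs_event),
          significant = FALSE
        )
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  results <- dplyr::bind_rows(rows)
  if (nrow(results) == 0) {
    results <- tibble::tibble(
      gene = character(), cohort_id = character(), hr = numeric(),
      cox_p = numeric(), logrank_p = numeric(), n = integer(),
      n_events = numeric(), significant = logical()
    )
  }
  consensus <- results |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_significant_cohorts = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(passes = .data$n_significant_cohorts >= min_cohorts) |>
    dplyr::arrange(dplyr::desc(.data$n_significant_cohorts), .data$gene)
  structure(list(results = results, consensus = consensus,
                 alpha = alpha, min_cohorts = min_cohorts),
            class = "survival_screen")
}

#' Consensus-filter yield as a percentage
#'
#' The fraction of screened candidates that pass the consensus filter,
#' on the percent scale.
#' @param n_pass number of genes passing.
#' @param n_candidates number of screened candidates.
#' @return Percentage (0-100).
#' @export
consensus_yield_pct <- function(n_pass, n_candidates) {
  if (n_candidates <= 0) abort("n_candidates must be positive")
  100 * n_pass / n_candidates
}
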