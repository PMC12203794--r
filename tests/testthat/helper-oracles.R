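# Independent brute-force oracles. These deliberately re-implement the same
# statistical rules with naive loops and none of the package's code paths, so
# agreement is informative.

oracle_rho <- function(acf_tbl, d) {
  # direct bin lookup from the ACF table, written independently of acf_rho()
  max_lag <- max(acf_tbl$lag_hi)
  vapply(d, function(di) {
    if (di == 0) return(1)
    if (di > max_lag) return(0)
    acf_tbl$rho[which(di > acf_tbl$lag_lo & di <= acf_tbl$lag_hi)]
  }, numeric(1))
}

oracle_sl <- function(p, sigma) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  z <- qnorm(p, lower.tail = FALSE) # upper-tail probit, exact for small p
  pnorm(sum(z) / sqrt(sum(sigma)), lower.tail = FALSE)
}

oracle_window_adjust <- function(df, acf_tbl, dist) {
  half <- dist / 2
  vapply(seq_len(nrow(df)), function(i) {
    m <- which(df$chrom == df$chrom[i] & abs(df$pos - df$pos[i]) <= half)
    if (length(m) == 1) return(df$p_value[i])
    sig <- outer(df$pos[m], df$pos[m],
                 function(a, b) oracle_rho(acf_tbl, abs(a - b)))
    oracle_sl(df$p_value[m], sig)
  }, numeric(1))
}

oracle_regions <- function(df, p_adj, seed_p, dist, filter_p, filter_n) {
  # grow from every seed, collect unique membership sets
  seen <- list()
  for (i in which(p_adj < seed_p)) {
    members <- i
    repeat {
      left <- min(members) - 1
      if (left >= 1 && df$chrom[left] == df$chrom[i] &&
          p_adj[left] < filter_p &&
          df$pos[min(members)] - df$pos[left] <= dist) {
        members <- c(left, members)
      } else break
    }
    repeat {
      right <- max(members) + 1
      if (right <= nrow(df) && df$chrom[right] == df$chrom[i] &&
          p_adj[right] < filter_p &&
          df$pos[right] - df$pos[max(members)] <= dist) {
        members <- c(members, right)
      } else break
    }
    key <- paste(members, collapse = ",")
    seen[[key]] <- members
  }
  out <- unname(seen[!duplicated(names(seen))])
  out[vapply(out, length, integer(1)) >= filter_n]
}

oracle_score_region <- function(df, members, acf_tbl) {
  sig <- outer(df$pos[members], df$pos[members],
               function(a, b) oracle_rho(acf_tbl, abs(a - b)))
  pc <- oracle_sl(df$p_value[members], sig)
  spans <- tapply(df$pos, df$chrom, function(x) max(x) - min(x))
  b_total <- sum(spans)
  w <- max(max(df$pos[members]) - (min(df$pos[members]) - 1), 1)
  expo <- max(b_total / w, 1)
  # 1 - (1-p)^k, evaluated in the numerically exact equivalent form so the
  # oracle itself does not underflow for tiny combined p
  list(p_combined = pc, p_sidak = -expm1(expo * log1p(-pc)))
}

# weighted-KS enrichment score by direct walk over the full list
oracle_es <- function(metric, hit, weight = 1) {
  n <- length(metric)
  nh <- sum(hit)
  wsum <- sum(abs(metric[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (wsum > 0) abs(metric[i])^weight / wsum else 1 / nh
    } else {
      cur <- cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Breslow-ties Cox partial log-likelihood for one covariate
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(times, events, x) {
  optimize(function(b) -oracle_cox_loglik(b, times, events, x),
           interval = c(-10, 10), tol = 1e-9)$minimum
}

# two-group log-rank by explicit O-E / V tabulation
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- c(e1, e2)
  g1 <- rep(c(TRUE, FALSE), c(length(t1), length(t2)))
  oe <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    nt <- sum(at_risk)
    n1t <- sum(at_risk & g1)
    dt <- sum(event == 1 & time == t)
    d1t <- sum(event == 1 & time == t & g1)
    oe <- oe + d1t - dt * n1t / nt
    if (nt > 1) {
      v <- v + dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1)
    }
  }
  oe^2 / v
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(times[events == 1]))) {
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events == 1)
    s <- s * (1 - d_t / n_t)
    out <- c(out, s)
  }
  out
}

# random toy EWAS-like tibble, genome-sorted, for DMR oracle tests
random_dmr_instance <- function(n_probes, two_chrom = FALSE) {
  chrom <- if (two_chrom) {
    sort(sample(c("chr1", "chr2"), n_probes, replace = TRUE))
  } else rep("chr1", n_probes)
  df <- NULL
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos <- sort(sample.int(5000, k))
    df <- rbind(df, data.frame(chrom = ch, pos = pos))
  }
  # mix of null and signal probes so regions actually form
  z <- rnorm(n_probes) + sample(c(0, 4), n_probes, replace = TRUE, prob = c(0.6, 0.4))
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(n_probes)),
    chrom = df$chrom,
    pos = as.numeric(df$pos),
    delta_beta = runif(n_probes, -0.5, 0.5),
    p_value = pmin(pmax(pnorm(z, lower.tail = FALSE), 1e-12), 1 - 1e-12)
  )
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
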