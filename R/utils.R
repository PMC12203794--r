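# Internal helpers shared across modules.

# Deterministic derived seeds: fold integer parts into a 31-bit stream id with
# a Lehmer-style multiplier. Exact in double precision (products < 2^53).
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in parts) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s %% 2147483562) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Probit score z = qnorm(1 - p) with the clamping used throughout the
# combined-p machinery.
probit_score <- function(p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  qnorm(p, lower.tail = FALSE)
}

# Accept either a two-column tibble (sample_id, group) or a named vector.
as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    out <- setNames(as.character(groups$group), groups$sample_id)
  } else {
    if (is.null(names(groups))) {
      abort("`groups` must be a tibble (sample_id, group) or a named vector.")
    }
    out <- setNames(as.character(groups), names(groups))
  }
  bad <- setdiff(unique(out), c("high", "low"))
  if (length(bad) > 0) {
    abort(paste0("group labels must be 'high'/'low'; found: ",
                 paste(bad, collapse = ", ")))
  }
  out
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(paste0("`", name, "` must be a single number."))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(paste0("`", name, "` = ", x, " is out of range."))
  }
  if (integer && x != round(x)) {
    abort(paste0("`", name, "` must be an integer."))
  }
  invisible(x)
}
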