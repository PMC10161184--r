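# CUSUM changepoint detection on per-token change-metric series.

#' CUSUM configuration
#'
#' The detector accumulates successive differences of the metric series with
#' zero drift by default and fires when the running sum exceeds a threshold.
#' The threshold is either given directly or derived as a percentile
#' (default the 99th) of every generated timepoint pooled across all tokens
#' and transitions; exactly one of the two must be supplied at run time.
#'
#' @param drift non-negative drift subtracted from each accumulated
#'   difference (default 0).
#' @param threshold positive alarm threshold, or `NULL` to derive it.
#' @param percentile percentile in (0, 100) used by [globalThreshold()] when
#'   `threshold` is `NULL` (default 99).
#' @param twoSided detect both rises and falls (default) or rises only.
#' @return A list of class `CusumConfig`.
#' @export
cusumConfig <- function(drift = 0, threshold = NULL, percentile = 99,
                        twoSided = TRUE) {
  stopifnot(drift >= 0)
  if (!is.null(threshold)) {
    stopifnot(threshold > 0)
    percentile <- NULL
  } else {
    stopifnot(percentile > 0, percentile < 100)
  }
  structure(
    list(drift = drift, threshold = threshold, percentile = percentile,
         twoSided = isTRUE(twoSided)),
    class = "CusumConfig"
  )
}

#' Global percentile threshold over pooled metric values
#'
#' The empirical percentile (linear-interpolation quantile) of all metric
#' values pooled across every token and every transition. Thresholding the
#' CUSUM statistic at the pooled 99th percentile makes roughly 1% of
#' generated timepoints extreme enough to contribute to an alarm, whatever
#' the corpus.
#'
#' @param series data.frame from [buildSeries()], or a numeric vector of
#'   pooled metric values.
#' @param percentile percentile in (0, 100).
#' @return The threshold value.
#' @examples
#' globalThreshold(1:100, 50)  # 50.5
#' @export
globalThreshold <- function(series, percentile = 99) {
  pool <- if (is.data.frame(series)) series$metric else series
  pool <- pool[is.finite(pool)]
  if (!length(pool)) stop("no finite metric values to pool")
  stats::quantile(pool, percentile / 100, type = 7, names = FALSE)
}

#' Percentile rank of a value in a pooled distribution
#'
#' Inverts the linear-interpolation quantile: the percentile p such that
#' `quantile(pool, p/100, type = 7)` equals `value`. Values outside the
#' pooled range clamp to 0 / 100.
#'
#' @param pool numeric vector.
#' @param value the value whose rank is sought.
#' @return Percentile in \[0, 100\].
#' @export
percentileRank <- function(pool, value) {
  pool <- sort(pool[is.finite(pool)])
  n <- length(pool)
  if (n < 2L) stop("need >= 2 pooled values")
  p <- (seq_len(n) - 1) / (n - 1) * 100
  if (value <= pool[1L]) return(0)
  if (value >= pool[n]) return(100)
  stats::approx(pool, p, xout = value, ties = "ordered")$y
}

# core two-sided CUSUM recursion on one numeric series; returns integer
# indices (into x) at which an alarm fires, with direction
cusumCore <- function(x, drift, threshold, twoSided) {
  gp <- 0; gn <- 0
  idx <- integer(0); dir <- character(0); val <- numeric(0)
  for (t in seq_along(x)[-1L]) {
    d <- x[t] - x[t - 1L]
    gp <- max(0, gp + d - drift)
    gn <- max(0, gn - d - drift)
    if (gp > threshold) {
      idx <- c(idx, t); dir <- c(dir, "rise"); val <- c(val, gp)
      gp <- 0; gn <- 0
    } else if (twoSided && gn > threshold) {
      idx <- c(idx, t); dir <- c(dir, "fall"); val <- c(val, gn)
      gp <- 0; gn <- 0
    }
  }
  list(idx = idx, direction = dir, cusum = val)
}

#' CUSUM changepoint detection on one token's series
#'
#' Runs the cumulative-sum recursion over the successive differences of the
#' metric series: `gp_t = max(0, gp_{t-1} + (x_t - x_{t-1}) - drift)` (and
#' symmetrically `gn_t` for falls when two-sided). An alarm fires when an
#' accumulator exceeds the threshold; both accumulators reset to zero after
#' an alarm. Gaps in the series (non-consecutive transitions) also reset the
#' accumulators: differences are never taken across years in which the token
#' was unobserved.
#'
#' @param series one token's rows of the [buildSeries()] data.frame.
#' @param cfg a [cusumConfig()] with `threshold` set.
#' @return A data.frame of calls: `token`, `year_prev`, `year_next`,
#'   `metric`, `cusum_value`, `direction` — the transition at which each
#'   alarm fired, in order.
#' @export
cusumDetect <- function(series, cfg) {
  if (is.null(cfg$threshold)) {
    stop("threshold unresolved; derive it with globalThreshold() first")
  }
  series <- series[order(series$year_prev), , drop = FALSE]
  emptyCalls <- data.frame(
    token = character(0), year_prev = integer(0), year_next = integer(0),
    metric = numeric(0), cusum_value = numeric(0), direction = character(0)
  )
  if (nrow(series) < 2L) return(emptyCalls)
  # split at gaps: runs of consecutive transitions
  runs <- split(seq_len(nrow(series)),
                cumsum(c(1L, diff(series$year_prev) != 1L)))
  calls <- lapply(runs, function(rr) {
    if (length(rr) < 2L) return(emptyCalls)
    seg <- series[rr, , drop = FALSE]
    res <- cusumCore(seg$metric, cfg$drift, cfg$threshold, cfg$twoSided)
    if (!length(res$idx)) return(emptyCalls)
    data.frame(
      token = seg$token[res$idx], year_prev = seg$year_prev[res$idx],
      year_next = seg$year_next[res$idx], metric = seg$metric[res$idx],
      cusum_value = res$cusum, direction = res$direction,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Detect changepoints for every token
#'
#' Resolves the threshold (given, or the configured global percentile of the
#' pooled metric values), runs [cusumDetect()] per token, and summarizes the
#' calls: a per-transition histogram of call counts and the number of tokens
#' with exactly one call (semantic shifts are typically single events).
#'
#' @param series data.frame from [buildSeries()].
#' @param cfg a [cusumConfig()].
#' @return A list with `calls` (data.frame as in [cusumDetect()], tokens in
#'   sorted order), `threshold`, and `summary` (list: `n_calls`,
#'   `per_transition` table, `tokens_called`, `single_call_tokens`).
#' @export
detectAll <- function(series, cfg = cusumConfig()) {
  if (is.null(cfg$threshold)) {
    cfg$threshold <- globalThreshold(series, cfg$percentile)
  }
  toks <- sort(unique(series$token))
  calls <- do.call(rbind, lapply(toks, function(tk) {
    cusumDetect(series[series$token == tk, , drop = FALSE], cfg)
  }))
  if (is.null(calls)) {
    calls <- data.frame(
      token = character(0), year_prev = integer(0), year_next = integer(0),
      metric = numeric(0), cusum_value = numeric(0), direction = character(0)
    )
  }
  rownames(calls) <- NULL
  perToken <- table(calls$token)
  list(
    calls = calls,
    threshold = cfg$threshold,
    summary = list(
      n_calls = nrow(calls),
      per_transition = table(paste(calls$year_prev, calls$year_next, sep = "-")),
      tokens_called = length(perToken),
      single_call_tokens = sum(perToken == 1L)
    )
  )
}
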