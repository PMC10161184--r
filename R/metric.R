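# Per-token change time series: intra-year instability, inter-year distance,
# frequency ratio, and the combined change metric.

#' Cosine distance
#'
#' `1 - cos(u, v)`, bounded in \[0, 2\]: 0 for identical directions, 1 for
#' orthogonal vectors, 2 for antipodal ones. Values are clipped to the bounds
#' against floating-point rounding.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return A number in \[0, 2\].
#' @examples
#' cosineDistance(c(1, 0), c(1, 0))   # 0
#' cosineDistance(c(1, 0), c(-1, 0))  # 2
#' cosineDistance(c(1, 0), c(0, 1))   # 1
#' @export
cosineDistance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero-norm input")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

# rows scaled to unit norm
rowNormalize <- function(m) m / sqrt(rowSums(m^2))

# per-token mean cosine distance over all unordered replicate pairs of one
# ensemble, as a named vector over the (shared) vocabulary
intraYearMeans <- function(ens) {
  mats <- lapply(ens@models, function(m) rowNormalize(m@vectors))
  vocab <- rownames(mats[[1L]])
  R <- length(mats)
  if (R < 2L) stop("intra-year distance needs >= 2 replicates")
  acc <- numeric(length(vocab))
  npair <- 0L
  for (i in seq_len(R - 1L)) {
    for (j in seq(i + 1L, R)) {
      acc <- acc + (1 - rowSums(mats[[i]] * mats[[j]][vocab, , drop = FALSE]))
      npair <- npair + 1L
    }
  }
  pmin(pmax(acc / npair, 0), 2)
}

# per-token mean cosine distance over the full cross-year Cartesian product,
# restricted to tokens shared by both years
interYearMeans <- function(prevEns, nextEns) {
  shared <- intersect(vocabulary(prevEns), vocabulary(nextEns))
  a <- lapply(prevEns@models, function(m) {
    rowNormalize(m@vectors)[shared, , drop = FALSE]
  })
  b <- lapply(nextEns@models, function(m) {
    rowNormalize(m@vectors)[shared, , drop = FALSE]
  })
  acc <- numeric(length(shared))
  for (mi in a) for (mj in b) acc <- acc + (1 - rowSums(mi * mj))
  structure(pmin(pmax(acc / (length(a) * length(b)), 0), 2), names = shared)
}

#' Intra-year distance of a token
#'
#' Mean cosine distance between a token's vectors over all R(R-1)/2
#' unordered replicate pairs of one year's ensemble — a measure of how
#' unstable the token's embedding is under retraining.
#'
#' @param ens a [YearEnsemble-class].
#' @param token token string.
#' @return Mean pairwise cosine distance.
#' @export
intraYearDistance <- function(ens, token) {
  if (!token %in% vocabulary(ens)) {
    stop("token '", token, "' absent from the year ", ens@year, " vocabulary")
  }
  vs <- lapply(ens@models, function(m) m@vectors[token, ])
  R <- length(vs)
  pairs <- utils::combn(R, 2L)
  mean(apply(pairs, 2L, function(p) cosineDistance(vs[[p[1L]]], vs[[p[2L]]])))
}

#' Inter-year distance of a token
#'
#' Mean cosine distance between a token's vectors over the full Cartesian
#' product of the two years' replicate models (R^2 pairs) — the raw
#' cross-year change signal.
#'
#' @param prevEns,nextEns [YearEnsemble-class] objects for consecutive years.
#' @param token token string, present in both years.
#' @return Mean cross-year cosine distance.
#' @export
interYearDistance <- function(prevEns, nextEns, token) {
  if (!token %in% vocabulary(prevEns) || !token %in% vocabulary(nextEns)) {
    stop("token '", token, "' absent from one of the two years")
  }
  va <- lapply(prevEns@models, function(m) m@vectors[token, ])
  vb <- lapply(nextEns@models, function(m) m@vectors[token, ])
  mean(vapply(va, function(u) {
    mean(vapply(vb, function(v) cosineDistance(u, v), numeric(1)))
  }, numeric(1)))
}

#' Frequency ratio of a token across consecutive years
#'
#' Ratio of corpus-size-normalized token frequency in the more recent year
#' over the previous year. Relative, not raw, frequencies are used because
#' corpus sizes can grow by an order of magnitude over an analysis period.
#'
#' @param prev,next_ [CorpusSlice-class] or [EmbeddingModel-class] for the
#'   earlier and later year.
#' @param token token string.
#' @return Positive ratio; `NA` if the token is uncounted in either year
#'   (zero previous frequency leaves the ratio undefined).
#' @export
frequencyRatio <- function(prev, next_, token) {
  fp <- relativeFrequency(prev, token)
  fn <- relativeFrequency(next_, token)
  if (is.na(fp) || is.na(fn) || fp == 0) return(NA_real_)
  fn / fp
}

#' Combine distance and frequency statistics into the change metric
#'
#' The distance ratio is the mean inter-year distance over the average
#' intra-year distance of the two flanking years; dividing by intra-year
#' instability penalizes tokens whose embeddings wobble between replicate
#' models and rewards stable tokens. The frequency ratio is folded in by
#' multiplication: the default `"symmetric"` combiner multiplies by
#' `max(f, 1/f)` so both frequency rises and drops raise the signal, while
#' `"directional"` multiplies by the raw ratio `f`.
#'
#' @param stats list or one-row data.frame with `intra_mean_prev`,
#'   `intra_mean_next`, `inter_mean`.
#' @param freqRatio positive frequency ratio.
#' @param combiner `"symmetric"` (default) or `"directional"`.
#' @param epsilon floor applied to the intra-year denominator when the
#'   replicate models happen to agree exactly (with a warning).
#' @return The positive change metric; a stable token (inter = intra,
#'   frequency ratio 1) scores 1.
#' @export
changeMetric <- function(stats, freqRatio,
                         combiner = c("symmetric", "directional"),
                         epsilon = 1e-8) {
  combiner <- match.arg(combiner)
  intra <- mean(c(stats$intra_mean_prev, stats$intra_mean_next))
  if (intra < epsilon) {
    warning("intra-year distances vanish; applying epsilon floor")
    intra <- epsilon
  }
  distanceRatio <- stats$inter_mean / intra
  f <- if (combiner == "symmetric") max(freqRatio, 1 / freqRatio) else freqRatio
  distanceRatio * f
}

#' Build per-token change time series across all consecutive years
#'
#' For every consecutive year pair and every token present in both years'
#' vocabularies, computes the intra-year distances of the two flanking
#' years, the inter-year distance, the frequency ratio and the combined
#' change metric. Tokens missing from a year simply have no point at the
#' transitions involving that year (gappy series); downstream changepoint
#' detection never accumulates across such gaps.
#'
#' @param aligned named list year -> aligned [YearEnsemble-class] (at least
#'   two consecutive years).
#' @param tokens optional character vector restricting the series to given
#'   tokens; default all tokens.
#' @param combiner,epsilon passed to [changeMetric()].
#' @param intraMode `"mean"` (default) averages the two flanking years'
#'   intra-year distances in the denominator; `"prev"` uses only the earlier
#'   year's.
#' @return A data.frame with one row per (token, transition): `token`,
#'   `year_prev`, `year_next`, `intra_prev`, `intra_next`, `inter`,
#'   `distance_ratio`, `freq_ratio`, `metric`; tokens in deterministic
#'   (sorted) order within each transition. The combiner is recorded in
#'   `attr(, "combiner")`.
#' @export
buildSeries <- function(aligned, tokens = NULL,
                        combiner = c("symmetric", "directional"),
                        intraMode = c("mean", "prev"), epsilon = 1e-8) {
  combiner <- match.arg(combiner)
  intraMode <- match.arg(intraMode)
  yrs <- sort(unname(vapply(aligned, function(e) e@year, integer(1))))
  if (length(yrs) < 2L) stop("need at least two years")
  byYear <- setNames(aligned[order(vapply(aligned, function(e) e@year,
                                          integer(1)))], yrs)
  intra <- lapply(byYear, intraYearMeans)

  rows <- list()
  for (i in seq_len(length(yrs) - 1L)) {
    yPrev <- yrs[i]; yNext <- yrs[i + 1L]
    if (yNext != yPrev + 1L) next  # gap between observed years
    ePrev <- byYear[[as.character(yPrev)]]
    eNext <- byYear[[as.character(yNext)]]
    inter <- interYearMeans(ePrev, eNext)
    toks <- sort(names(inter))
    if (!is.null(tokens)) toks <- intersect(toks, tokens)
    if (!length(toks)) next

    mPrev <- ePrev@models[[1L]]; mNext <- eNext@models[[1L]]
    fPrev <- relativeFrequency(mPrev, toks)
    fNext <- relativeFrequency(mNext, toks)
    fr <- fNext / fPrev
    ip <- intra[[as.character(yPrev)]][toks]
    nx <- intra[[as.character(yNext)]][toks]
    denom <- if (intraMode == "mean") (ip + nx) / 2 else ip
    low <- denom < epsilon
    if (any(low)) {
      warning(sum(low), " token(s) with vanishing intra-year distance; ",
              "epsilon floor applied")
      denom[low] <- epsilon
    }
    dr <- inter[toks] / denom
    f <- if (combiner == "symmetric") pmax(fr, 1 / fr) else fr
    rows[[length(rows) + 1L]] <- data.frame(
      token = toks, year_prev = yPrev, year_next = yNext,
      intra_prev = unname(ip), intra_next = unname(nx),
      inter = unname(inter[toks]), distance_ratio = unname(dr),
      freq_ratio = unname(fr), metric = unname(dr * f),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      token = character(0), year_prev = integer(0), year_next = integer(0),
      intra_prev = numeric(0), intra_next = numeric(0), inter = numeric(0),
      distance_ratio = numeric(0), freq_ratio = numeric(0), metric = numeric(0)
    )
  }
  rownames(out) <- NULL
  attr(out, "combiner") <- combiner
  attr(out, "intraMode") <- intraMode
  out
}

#' Extract one token's time series
#'
#' @param series the data.frame returned by [buildSeries()].
#' @param token token string.
#' @return The token's rows ordered by `year_prev`.
#' @export
tokenSeries <- function(series, token) {
  out <- series[series$token == token, , drop = FALSE]
  out[order(out$year_prev), , drop = FALSE]
}
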