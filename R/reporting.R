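# Nearest-neighbour tables through time and stability diagnostics.

#' Nearest neighbours of a token within one year
#'
#' Candidate distances are the replicate-averaged cosine distances to the
#' query token, consistent with the multi-model design (a single replicate's
#' neighbourhood is noisy). Ties break lexicographically so the table is
#' deterministic.
#'
#' @param ens a [YearEnsemble-class] (aligned or not; neighbour ranks are
#'   invariant under the orthogonal alignment rotation).
#' @param token query token; must be in the year's vocabulary (exact match).
#' @param k number of neighbours (default 15); capped at vocabulary size - 1.
#' @return A data.frame `token`, `year`, `neighbor`, `distance`, sorted
#'   ascending by distance, excluding the query itself.
#' @export
nearestNeighbors <- function(ens, token, k = 15L) {
  vocab <- vocabulary(ens)
  if (!token %in% vocab) {
    stop("token '", token, "' not in the year ", ens@year, " vocabulary")
  }
  acc <- numeric(length(vocab))
  for (m in ens@models) {
    nm <- rowNormalize(m@vectors)
    acc <- acc + (1 - as.vector(nm %*% nm[token, ]))
  }
  d <- pmin(pmax(acc / length(ens@models), 0), 2)
  names(d) <- vocab
  d <- d[names(d) != token]
  ord <- order(d, names(d))
  top <- ord[seq_len(min(k, length(d)))]
  data.frame(
    token = token, year = ens@year, neighbor = names(d)[top],
    distance = unname(d[top]), stringsAsFactors = FALSE
  )
}

#' Per-year frequency series of a token
#'
#' @param slices named list year -> [CorpusSlice-class] (or models).
#' @param token token string.
#' @param normalized if `TRUE` (default), counts are divided by each year's
#'   total corpus size; years where the token is absent report zero.
#' @return A data.frame `year`, `value`.
#' @export
frequencySeries <- function(slices, token, normalized = TRUE) {
  yrs <- vapply(slices, function(s) s@year, integer(1))
  vals <- vapply(slices, function(s) {
    cnt <- tokenCounts(s)[token]
    if (is.na(cnt)) cnt <- 0L
    if (normalized) cnt / totalTokens(s) else as.numeric(cnt)
  }, numeric(1))
  data.frame(year = unname(yrs), value = unname(vals))[order(yrs), ]
}

#' Compare two neighbour tables of one token
#'
#' Partition of the union of two years' neighbour sets into tokens shared by
#' both years and tokens unique to either — the raw material of a
#' two-year neighbourhood comparison.
#'
#' @param tableA,tableB data.frames from [nearestNeighbors()] for the same
#'   query token.
#' @return A list `shared`, `unique_a`, `unique_b` of sorted token sets.
#' @export
neighborOverlap <- function(tableA, tableB) {
  if (!identical(unique(tableA$token), unique(tableB$token))) {
    stop("neighbour tables answer different query tokens")
  }
  a <- tableA$neighbor; b <- tableB$neighbor
  list(
    shared = sort(intersect(a, b)),
    unique_a = sort(setdiff(a, b)),
    unique_b = sort(setdiff(b, a))
  )
}

#' Single-model versus multi-model stability diagnostic
#'
#' Uneven corpus sizes across years make embedding models from small-corpus
#' years intrinsically noisier, which a single-model year-to-year distance
#' conflates with genuine semantic change. This diagnostic contrasts, for a
#' token sample, (a) the naive single-model statistic — the cosine distance
#' between one replicate of each year and one replicate of a reference year
#' — with (b) the integrated multi-model statistic — the inter-year distance
#' to the reference year divided by the mean intra-year distance. Dividing
#' by intra-year instability cancels the year-specific noise floor, so the
#' multi-model statistic disperses less in under-sampled years.
#'
#' @param aligned named list year -> aligned [YearEnsemble-class].
#' @param referenceYear the year compared against (e.g. a mid-series year).
#' @param tokens tokens to sample over; default: 100 tokens shared by every
#'   year, sampled deterministically (first 100 in sorted order).
#' @param nTokens sample size when `tokens` is `NULL`.
#' @return A data.frame `year`, `token`, `single_model`, `multi_model` (the
#'   reference year itself is excluded).
#' @export
stabilityDiagnostic <- function(aligned, referenceYear, tokens = NULL,
                                nTokens = 100L) {
  yrs <- vapply(aligned, function(e) e@year, integer(1))
  if (!referenceYear %in% yrs) stop("reference year not present")
  ref <- aligned[[which(yrs == referenceYear)[1L]]]
  if (is.null(tokens)) {
    shared <- Reduce(intersect, lapply(aligned, vocabulary))
    tokens <- utils::head(sort(shared), nTokens)
  }
  refSingle <- rowNormalize(ref@models[[1L]]@vectors)
  refIntra <- intraYearMeans(ref)

  rows <- list()
  for (ens in aligned) {
    if (ens@year == referenceYear) next
    toks <- intersect(tokens, vocabulary(ens))
    single <- 1 - rowSums(
      rowNormalize(ens@models[[1L]]@vectors)[toks, , drop = FALSE] *
        refSingle[toks, , drop = FALSE]
    )
    inter <- interYearMeans(ens, ref)[toks]
    intra <- (intraYearMeans(ens)[toks] + refIntra[toks]) / 2
    rows[[length(rows) + 1L]] <- data.frame(
      year = ens@year, token = toks,
      single_model = unname(pmin(pmax(single, 0), 2)),
      multi_model = unname(inter / intra), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
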