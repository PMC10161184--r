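# Synthetic year-binned corpora with planted semantic shifts.
#
# The generator emulates the statistical structure a context-predictive
# embedding responds to, not fluent language: a fixed topical mixture shared
# across years (every sentence is drawn from one topic, giving each token a
# sharply determined co-occurrence signature, so models stabilize as corpora
# grow the way they do on real text), plus designated target tokens whose
# local context distribution switches from one token set to another at a
# known year, optionally together with a change in occurrence frequency.
# Because CBOW encodes context distributions, the mixture weight is directly
# the planted effect size.

#' Describe one planted semantic shift
#'
#' @param token target token name; must not collide with the background
#'   vocabulary or any context token.
#' @param changeYear year at which the context distribution (and frequency)
#'   switches; must lie strictly inside the corpus year range.
#' @param contextA,contextB disjoint token sets the target's neighbours are
#'   drawn from before / after the change. The default (`NULL`) lets
#'   [generateCorpus()] assign two distinct background topics: topic members
#'   are anchored by their own background co-occurrences, so a target whose
#'   neighbours switch topics must genuinely relocate in embedding space,
#'   the way a term that migrates between topical clusters does. Explicit
#'   sets may name any tokens (including ones outside the background
#'   vocabulary).
#' @param mixingAfter fraction in (0, 1\]: at and after `changeYear`,
#'   neighbours come from `contextB` with this probability and from
#'   `contextA` otherwise. 1 is a complete context replacement.
#' @param freqBefore,freqAfter per-sentence occurrence probability before and
#'   at/after the change.
#' @return A list of class `TargetShift`.
#' @export
targetShift <- function(token, changeYear, contextA = NULL, contextB = NULL,
                        mixingAfter = 1, freqBefore = 0.02,
                        freqAfter = 0.06) {
  stopifnot(mixingAfter > 0, mixingAfter <= 1,
            freqBefore > 0, freqBefore <= 1, freqAfter > 0, freqAfter <= 1)
  stopifnot(is.null(contextA) == is.null(contextB))
  if (length(intersect(contextA, contextB))) {
    stop("context sets must be disjoint")
  }
  if (token %in% c(contextA, contextB)) {
    stop("target token collides with its context sets")
  }
  structure(
    list(token = token, changeYear = as.integer(changeYear),
         contextA = contextA, contextB = contextB,
         mixingAfter = mixingAfter, freqBefore = freqBefore,
         freqAfter = freqAfter),
    class = "TargetShift"
  )
}

#' Specification of a synthetic corpus
#'
#' Defaults describe the reference benchmark used throughout the package's
#' validation: a 500-type Zipf background over 8 years of 20,000
#' twelve-token sentences per year.
#'
#' @param vocabSize number of background token types.
#' @param years inclusive integer vector of years (e.g. `2014:2021`).
#' @param sentencesPerYear sentences per year; either a single number or one
#'   per year (uneven corpus sizes emulate the growth of a literature).
#' @param sentenceLength tokens per sentence (>= 5 when targets are planted).
#' @param targets list of [targetShift()] objects (possibly empty).
#' @param seed integer seed; the corpus is fully deterministic given it.
#' @param topicSize tokens per background topic. The vocabulary is
#'   partitioned into `vocabSize / topicSize` topics by interleaving
#'   frequency ranks, so every topic has the same frequency profile; each
#'   sentence is drawn from a single topic. Topical structure gives every
#'   token a sharply determined co-occurrence signature, which is what makes
#'   embedding models stabilize as a corpus grows.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(vocabSize = 500L, years = 2014:2021,
                          sentencesPerYear = 20000L, sentenceLength = 12L,
                          targets = list(), seed = 1L,
                          topicSize = 25L) {
  years <- as.integer(years)
  stopifnot(length(years) >= 2L, all(diff(years) == 1L), vocabSize >= 10L,
            sentenceLength >= 2L, topicSize >= 5L)
  if (vocabSize %% topicSize != 0L) {
    stop("vocabSize must be a multiple of topicSize")
  }
  if (length(sentencesPerYear) == 1L) {
    sentencesPerYear <- rep(as.integer(sentencesPerYear), length(years))
  }
  stopifnot(length(sentencesPerYear) == length(years))
  for (tg in targets) {
    stopifnot(inherits(tg, "TargetShift"))
    if (tg$changeYear <= min(years) || tg$changeYear > max(years)) {
      stop("target '", tg$token,
           "': changeYear must lie strictly inside the year range")
    }
    if (length(targets) && sentenceLength < 5L) {
      stop("sentenceLength must be >= 5 to embed a target with its context")
    }
  }
  tgTokens <- vapply(targets, `[[`, character(1), "token")
  if (anyDuplicated(tgTokens)) stop("duplicate target tokens")
  ctx <- unlist(lapply(targets, function(t) c(t$contextA, t$contextB)))
  if (length(intersect(ctx, tgTokens))) {
    stop("context tokens collide with target tokens")
  }
  if (length(intersect(tgTokens, sprintf("w%04d", seq_len(vocabSize))))) {
    stop("target tokens collide with the background vocabulary")
  }
  structure(
    list(vocabSize = as.integer(vocabSize), years = years,
         sentencesPerYear = as.integer(sentencesPerYear),
         sentenceLength = as.integer(sentenceLength), targets = targets,
         seed = as.integer(seed), topicSize = as.integer(topicSize)),
    class = "SyntheticSpec"
  )
}

#' Generate a synthetic year-binned corpus with planted shifts
#'
#' Every background sentence is drawn from one topic: topics partition the
#' vocabulary by interleaving Zipf frequency ranks (so all topics share one
#' frequency profile), and tokens within a sentence are sampled from the
#' topic's members by their relative Zipf weights. The process is identical
#' in every year, so a corpus with no targets is statistically exchangeable
#' across years. Each target token is planted into a sentence with its
#' per-sentence occurrence probability, surrounded by four context tokens
#' drawn from `contextA` before its change year and from the
#' `(1 - mixingAfter) A + mixingAfter B` mixture at and after it.
#'
#' @param spec a [syntheticSpec()].
#' @return A list: `slices` (named list year -> [CorpusSlice-class]) and
#'   `truth` (data.frame token, change_year — empty for a null corpus).
#' @export
generateCorpus <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec$seed)

  V <- spec$vocabSize
  vocab <- sprintf("w%04d", seq_len(V))
  L <- spec$sentenceLength

  # topics partition the vocabulary by interleaved frequency rank: topic t
  # holds ranks t, t + ntopic, t + 2 ntopic, ..., so every topic has the same
  # Zipf profile and global token frequency remains ~ 1/rank
  topicSize <- spec$topicSize
  ntopic <- V %/% topicSize
  members <- matrix(seq_len(V), nrow = ntopic)  # members[t, j] = token rank
  withinProbs <- (1 / seq_len(topicSize)) / sum(1 / seq_len(topicSize))

  # resolve default context sets: a pair of whole background topics per
  # target. Topic members are anchored by their own background co-occurrence
  # (they do not drift toward the target), both topics share one frequency
  # profile (the before/after regimes are statistically symmetric), and a
  # topic is a coherent cluster, so the planted shift is a genuine relocation
  # between clusters.
  targets <- spec$targets
  nAuto <- sum(vapply(targets, function(t) is.null(t$contextA), logical(1)))
  if (2L * nAuto > ntopic) {
    stop("not enough background topics to carve default context sets")
  }
  autoIdx <- 0L
  for (k in seq_along(targets)) {
    if (is.null(targets[[k]]$contextA)) {
      targets[[k]]$contextA <- vocab[members[2L * autoIdx + 1L, ]]
      targets[[k]]$contextB <- vocab[members[2L * autoIdx + 2L, ]]
      autoIdx <- autoIdx + 1L
    }
  }

  slices <- list()
  for (k in seq_along(spec$years)) {
    y <- spec$years[k]
    N <- spec$sentencesPerYear[k]
    tp <- sample.int(ntopic, N, replace = TRUE)
    within <- matrix(
      sample.int(topicSize, N * L, replace = TRUE, prob = withinProbs),
      nrow = N, ncol = L
    )
    m <- matrix(members[cbind(rep(tp, L), as.vector(within))],
                nrow = N, ncol = L)
    chars <- matrix(vocab[m], nrow = N, ncol = L)

    for (tg in targets) {
      after <- y >= tg$changeYear
      pFreq <- if (after) tg$freqAfter else tg$freqBefore
      hit <- which(stats::runif(N) < pFreq)
      if (!length(hit)) next
      pos <- sample(3:(L - 2L), length(hit), replace = TRUE)
      drawCtx <- function(n) {
        if (after) {
          fromB <- stats::runif(n) < tg$mixingAfter
          out <- character(n)
          if (any(fromB)) {
            out[fromB] <- sample(tg$contextB, sum(fromB), replace = TRUE)
          }
          if (any(!fromB)) {
            out[!fromB] <- sample(tg$contextA, sum(!fromB), replace = TRUE)
          }
          out
        } else {
          sample(tg$contextA, n, replace = TRUE)
        }
      }
      chars[cbind(hit, pos)] <- tg$token
      for (off in c(-2L, -1L, 1L, 2L)) {
        chars[cbind(hit, pos + off)] <- drawCtx(length(hit))
      }
    }
    slices[[as.character(y)]] <- corpusSlice(y, lapply(asplit(chars, 1L), as.character))
  }

  truth <- if (length(spec$targets)) {
    data.frame(
      token = vapply(spec$targets, `[[`, character(1), "token"),
      change_year = vapply(spec$targets, `[[`, integer(1), "changeYear"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(token = character(0), change_year = integer(0))
  }
  list(slices = slices, truth = truth)
}

#' Score changepoint calls against planted ground truth
#'
#' A planted shift at year Y corresponds to the transition (Y-1, Y); it
#' counts as recovered if any call on its token lies within
#' `toleranceTransitions` transitions of that one. Calls on tokens without a
#' planted shift, and calls on target tokens outside the tolerance, are
#' false positives.
#'
#' @param calls the `calls` data.frame of [detectAll()].
#' @param truth the `truth` data.frame of [generateCorpus()].
#' @param toleranceTransitions localization slack in transitions (default 1).
#' @return A list: `recall`, `precision` (`NA` when there are no calls),
#'   `localization_error` (mean |call - planted| over recovered targets, in
#'   transitions), `n_true_positive_calls`, `n_false_positive_calls`,
#'   `recovered` (logical per target).
#' @export
evaluateCalls <- function(calls, truth, toleranceTransitions = 1L) {
  recovered <- logical(nrow(truth))
  locErr <- rep(NA_real_, nrow(truth))
  isTP <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    tok <- truth$token[i]
    onTok <- which(calls$token == tok)
    if (!length(onTok)) next
    dist <- abs(calls$year_next[onTok] - truth$change_year[i])
    hit <- dist <= toleranceTransitions
    if (any(hit)) {
      recovered[i] <- TRUE
      locErr[i] <- min(dist)
      isTP[onTok[hit]] <- TRUE
    }
  }
  nTP <- sum(isTP)
  nFP <- nrow(calls) - nTP
  list(
    recall = if (nrow(truth)) mean(recovered) else NA_real_,
    precision = if (nrow(calls)) nTP / nrow(calls) else NA_real_,
    localization_error = if (any(recovered)) {
      mean(locErr[recovered])
    } else NA_real_,
    n_true_positive_calls = nTP,
    n_false_positive_calls = nFP,
    recovered = stats::setNames(recovered, truth$token)
  )
}

#' Run the full detection pipeline on corpus slices
#'
#' Convenience wrapper chaining [trainAllYears()], [alignAll()],
#' [buildSeries()] and [detectAll()].
#'
#' @param slices named list year -> [CorpusSlice-class].
#' @param cfg a [trainingConfig()].
#' @param cusum a [cusumConfig()].
#' @param ... passed to [buildSeries()].
#' @param verbose print per-year progress.
#' @return A list: `ensembles` (aligned), `series`, `detection`
#'   (see [detectAll()]).
#' @export
runPipeline <- function(slices, cfg = trainingConfig(),
                        cusum = cusumConfig(), ..., verbose = FALSE) {
  ens <- trainAllYears(slices, cfg, verbose = verbose)
  aligned <- alignAll(ens)
  series <- buildSeries(aligned, ...)
  det <- detectAll(series, cusum)
  list(ensembles = aligned, series = series, detection = det)
}
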