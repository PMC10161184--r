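# Independent oracles and fixture builders shared across tests.

# Straight-line reimplementation of the two-sided CUSUM recursion, kept
# deliberately naive and separate from the package's vectorized/segmented
# implementation.
referenceCusum <- function(x, drift, threshold, twoSided = TRUE) {
  gp <- 0; gn <- 0
  out <- data.frame(idx = integer(0), direction = character(0),
                    cusum = numeric(0))
  if (length(x) < 2) return(out)
  for (t in 2:length(x)) {
    d <- x[t] - x[t - 1]
    gp <- max(0, gp + d - drift)
    gn <- max(0, gn - d - drift)
    if (gp > threshold) {
      out <- rbind(out, data.frame(idx = t, direction = "rise", cusum = gp))
      gp <- 0; gn <- 0
    } else if (twoSided && gn > threshold) {
      out <- rbind(out, data.frame(idx = t, direction = "fall", cusum = gn))
      gp <- 0; gn <- 0
    }
  }
  out
}

# Random embedding model over a given vocabulary (unit-free random vectors,
# no zero rows), for geometry tests that do not need trained vectors.
randomModel <- function(vocab, dim, year = 2020L, replicate = 0L) {
  m <- matrix(stats::rnorm(length(vocab) * dim), length(vocab), dim,
              dimnames = list(vocab, NULL))
  counts <- stats::setNames(sample(5:50, length(vocab), replace = TRUE), vocab)
  embeddingModel(year, replicate, m, counts)
}

randomEnsemble <- function(vocab, dim, year = 2020L, R = 3L) {
  new("YearEnsemble", year = as.integer(year),
      models = lapply(seq_len(R) - 1L, function(r) {
        randomModel(vocab, dim, year = year, replicate = r)
      }),
      anchorId = integer(0))
}

# random d x d rotation (or reflection) via QR
randomOrthogonal <- function(d) {
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
}

# A micro corpus slice in which "aa" and "bb" are interchangeable (they
# appear in identical filler contexts, alternating) while "cc" appears in a
# disjoint filler context: distributionally, aa ~ bb and both differ from cc.
cooccurrenceSlice <- function(year = 2020L, n = 600L) {
  fillerAB <- sprintf("f%02d", 1:6)
  fillerC <- sprintf("g%02d", 1:6)
  sents <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    x <- if (i %% 2L == 0L) "aa" else "bb"
    sents[[2L * i - 1L]] <- c(x, sample(fillerAB, 4L, replace = TRUE))
    sents[[2L * i]] <- c("cc", sample(fillerC, 4L, replace = TRUE))
  }
  corpusSlice(year, sents)
}

# tiny deterministic slice family for fast pipeline tests
tinySlices <- function(years = 2019:2021, n = 300L, seed = 5L) {
  withr::with_seed(seed, {
    vocab <- sprintf("t%02d", 1:30)
    out <- list()
    for (y in years) {
      sents <- replicate(n, sample(vocab, 8L, replace = TRUE),
                         simplify = FALSE)
      out[[as.character(y)]] <- corpusSlice(y, sents)
    }
    out
  })
}
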