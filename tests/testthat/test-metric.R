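test_that("cosine distance hits its analytic anchor points", {
  set.seed(1)
  v <- rnorm(300)
  expect_equal(cosineDistance(v, v), 0)
  expect_equal(cosineDistance(v, -v), 2)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_error(cosineDistance(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("intra-year distance averages all unordered replicate pairs", {
  set.seed(2)
  vocab <- c("q", "r", "s")

  # R = 2: exactly the single pair's distance
  e2 <- randomEnsemble(vocab, 6L, R = 2L)
  v <- lapply(models(e2), embeddingVectors)
  expect_equal(intraYearDistance(e2, "q"),
               cosineDistance(v[[1]]["q", ], v[[2]]["q", ]))

  # R = 4: brute-force enumeration of the 6 pairs
  e4 <- randomEnsemble(vocab, 6L, R = 4L)
  v <- lapply(models(e4), embeddingVectors)
  manual <- mean(apply(utils::combn(4, 2), 2, function(p) {
    cosineDistance(v[[p[1]]]["r", ], v[[p[2]]]["r", ])
  }))
  expect_equal(intraYearDistance(e4, "r"), manual)

  # identical replicates collapse to zero
  dup <- new("YearEnsemble", year = 2020L,
             models = list(models(e2)[[1]], models(e2)[[1]]),
             anchorId = integer(0))
  expect_equal(intraYearDistance(dup, "s"), 0)
})

test_that("inter-year distance averages the full Cartesian product", {
  set.seed(3)
  vocab <- c("q", "r")
  a <- randomEnsemble(vocab, 5L, year = 2020L, R = 2L)
  b <- randomEnsemble(vocab, 5L, year = 2021L, R = 2L)
  va <- lapply(models(a), embeddingVectors)
  vb <- lapply(models(b), embeddingVectors)
  pairD <- c(
    cosineDistance(va[[1]]["q", ], vb[[1]]["q", ]),
    cosineDistance(va[[1]]["q", ], vb[[2]]["q", ]),
    cosineDistance(va[[2]]["q", ], vb[[1]]["q", ]),
    cosineDistance(va[[2]]["q", ], vb[[2]]["q", ])
  )
  got <- interYearDistance(a, b, "q")
  expect_equal(got, mean(pairD))
  expect_gte(got, min(pairD))
  expect_lte(got, max(pairD))

  # a copied year still has nonzero mean: the product includes cross pairs,
  # and only the two self pairs are zero
  bCopy <- new("YearEnsemble", year = 2021L,
               models = lapply(models(a), function(m) {
                 embeddingModel(2021L, m@replicate, embeddingVectors(m),
                                tokenCounts(m))
               }),
               anchorId = integer(0))
  cross <- cosineDistance(va[[1]]["q", ], va[[2]]["q", ])
  expect_equal(interYearDistance(a, bCopy, "q"), (0 + 0 + cross + cross) / 4)
})

test_that("frequency ratios compare corpus-normalized frequencies", {
  prev <- corpusSlice(2020L, list(rep("a", 1), rep("b", 99)))
  next_ <- corpusSlice(2021L, list(rep("a", 4), rep("b", 196)))
  expect_equal(frequencyRatio(prev, next_, "a"), 2)   # 0.02 / 0.01
  expect_equal(frequencyRatio(prev, next_, "b"), 98 / 100 / (99 / 100))
  expect_true(is.na(frequencyRatio(prev, next_, "zz")))
})

test_that("the change metric is 1 for a stable token and penalizes instability", {
  stable <- list(intra_mean_prev = 0.2, intra_mean_next = 0.2,
                 inter_mean = 0.2)
  expect_equal(changeMetric(stable, 1), 1)

  # directional combiner, hand arithmetic: 0.4 / mean(0.1, 0.3) * 2 = 4
  st <- list(intra_mean_prev = 0.1, intra_mean_next = 0.3, inter_mean = 0.4)
  expect_equal(changeMetric(st, 2, combiner = "directional"), 4)
  # symmetric combiner treats a halving like a doubling
  expect_equal(changeMetric(st, 0.5), changeMetric(st, 2))

  # homogeneity: doubling both intra means halves the ratio
  st2 <- list(intra_mean_prev = 0.2, intra_mean_next = 0.6, inter_mean = 0.4)
  expect_equal(changeMetric(st2, 1), changeMetric(st, 1) / 2)

  # strictly decreasing in intra-year instability at fixed inter and freq
  intras <- seq(0.05, 1, by = 0.05)
  ms <- vapply(intras, function(i) {
    changeMetric(list(intra_mean_prev = i, intra_mean_next = i,
                      inter_mean = 0.5), 1)
  }, numeric(1))
  expect_true(all(diff(ms) < 0))

  expect_warning(
    changeMetric(list(intra_mean_prev = 0, intra_mean_next = 0,
                      inter_mean = 0.1), 1),
    "epsilon"
  )
})

test_that("series construction matches the per-token operations", {
  set.seed(6)
  vocab <- sprintf("w%02d", 1:25)
  aligned <- list(
    `2019` = randomEnsemble(vocab, 8L, year = 2019L, R = 3L),
    `2020` = randomEnsemble(vocab, 8L, year = 2020L, R = 3L),
    `2021` = randomEnsemble(vocab, 8L, year = 2021L, R = 3L)
  )
  ser <- buildSeries(aligned, combiner = "directional")
  expect_identical(nrow(tokenSeries(ser, "w01")), 2L)

  for (tok in c("w03", "w17")) {
    s <- tokenSeries(ser, tok)
    for (i in seq_len(nrow(s))) {
      yp <- as.character(s$year_prev[i]); yn <- as.character(s$year_next[i])
      expect_equal(s$intra_prev[i], intraYearDistance(aligned[[yp]], tok))
      expect_equal(s$intra_next[i], intraYearDistance(aligned[[yn]], tok))
      inter <- interYearDistance(aligned[[yp]], aligned[[yn]], tok)
      expect_equal(s$inter[i], inter)
      fr <- frequencyRatio(models(aligned[[yp]])[[1]],
                           models(aligned[[yn]])[[1]], tok)
      expect_equal(s$freq_ratio[i], fr)
      expect_equal(s$metric[i], inter /
                     mean(c(s$intra_prev[i], s$intra_next[i])) * fr)
    }
  }
})

test_that("tokens absent from a year leave a gap, not a bogus point", {
  set.seed(7)
  common <- sprintf("w%02d", 1:10)
  aligned <- list(
    `2019` = randomEnsemble(c(common, "fleeting"), 6L, year = 2019L, R = 2L),
    `2020` = randomEnsemble(common, 6L, year = 2020L, R = 2L),
    `2021` = randomEnsemble(c(common, "fleeting"), 6L, year = 2021L, R = 2L)
  )
  ser <- buildSeries(aligned)
  expect_identical(nrow(tokenSeries(ser, "fleeting")), 0L)
  expect_identical(nrow(tokenSeries(ser, "w01")), 2L)

  onlyLast <- buildSeries(list(
    `2020` = randomEnsemble(common, 6L, year = 2020L, R = 2L),
    `2021` = randomEnsemble(c(common, "late"), 6L, year = 2021L, R = 2L)
  ))
  expect_identical(nrow(tokenSeries(onlyLast, "late")), 0L)
})

test_that("distances are invariant to a common orthogonal rotation", {
  set.seed(8)
  vocab <- sprintf("w%02d", 1:15)
  a <- randomEnsemble(vocab, 9L, year = 2020L, R = 2L)
  b <- randomEnsemble(vocab, 9L, year = 2021L, R = 2L)
  Q <- randomOrthogonal(9L)
  rot <- function(ens) {
    new("YearEnsemble", year = ens@year, models = lapply(models(ens), function(m) {
      embeddingModel(m@year, m@replicate, embeddingVectors(m) %*% Q,
                     tokenCounts(m))
    }), anchorId = integer(0))
  }
  for (tok in c("w02", "w11")) {
    expect_equal(intraYearDistance(rot(a), tok), intraYearDistance(a, tok),
                 tolerance = 1e-12)
    expect_equal(interYearDistance(rot(a), rot(b), tok),
                 interYearDistance(a, b, tok), tolerance = 1e-12)
  }
})
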