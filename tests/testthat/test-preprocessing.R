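test_that("annotated spans are replaced by lowercase type_id entity tokens", {
  doc <- list(
    doc_id = "pmid1",
    text = "severe acute respiratory syndrome emerged",
    annotations = data.frame(start = 0L, end = 33L,
                             type = "mesh", id = "D045169")
  )
  expect_identical(substituteAnnotations(doc), "mesh_d045169 emerged")

  # no annotations: text is returned verbatim
  expect_identical(
    substituteAnnotations(list(doc_id = "x", text = "plain text.")),
    "plain text."
  )
})

test_that("multi-span substitution matches a character-by-character rebuild", {
  set.seed(42)
  alphabet <- c(letters, " ")
  for (rep in 1:25) {
    text <- paste(sample(alphabet, 60, replace = TRUE), collapse = "")
    # draw non-overlapping spans by splitting the text at sorted cut points
    cuts <- sort(sample(0:60, 6))
    spans <- data.frame(
      start = cuts[c(1, 3, 5)], end = cuts[c(2, 4, 6)],
      type = c("gene", "mesh", "species"), id = c("6301", "D045169", "694009")
    )
    spans <- spans[spans$start < spans$end, , drop = FALSE]
    if (!nrow(spans)) next
    doc <- list(doc_id = "r", text = text, annotations = spans)

    # oracle: walk the string once, emitting entity tokens at span starts
    inSpan <- rep(NA_integer_, 60)
    for (i in seq_len(nrow(spans))) {
      inSpan[(spans$start[i] + 1):spans$end[i]] <- i
    }
    pieces <- character(0)
    pos <- 1
    while (pos <= 60) {
      if (is.na(inSpan[pos])) {
        pieces <- c(pieces, substr(text, pos, pos)); pos <- pos + 1
      } else {
        i <- inSpan[pos]
        pieces <- c(pieces, tolower(paste0(spans$type[i], "_", spans$id[i])))
        pos <- spans$end[i] + 1
      }
    }
    expect_identical(substituteAnnotations(doc), paste(pieces, collapse = ""))
  }
})

test_that("invalid annotation spans are rejected, not truncated", {
  base <- list(doc_id = "bad", text = "abcdefghij")
  overlapping <- data.frame(start = c(0L, 3L), end = c(5L, 8L),
                            type = c("a", "b"), id = c("1", "2"))
  expect_error(
    substituteAnnotations(c(base, list(annotations = overlapping))),
    "overlapping"
  )
  outside <- data.frame(start = 5L, end = 15L, type = "a", id = "1")
  expect_error(
    substituteAnnotations(c(base, list(annotations = outside))),
    "outside"
  )
  inverted <- data.frame(start = 5L, end = 5L, type = "a", id = "1")
  expect_error(
    substituteAnnotations(c(base, list(annotations = inverted))),
    "start >= end"
  )
})

test_that("tokenization splits sentences, lowercases, and keeps entity tokens whole", {
  expect_identical(
    tokenizeAndNormalize("Viruses evolve. Cells respond."),
    list(c("viruses", "evolve"), c("cells", "respond"))
  )
  expect_identical(
    tokenizeAndNormalize("mesh_d045169 emerged"),
    list(c("mesh_d045169", "emerged"))
  )
  expect_identical(tokenizeAndNormalize("..."), list())
})

test_that("tokenizer agrees with an independent regex token count", {
  set.seed(7)
  pieces <- c("Gene", "mesh_d045169", "cells.", "Respond!", "to", "IL-2,",
              "stress;", "rapidly?")
  for (rep in 1:20) {
    text <- paste(sample(pieces, 12, replace = TRUE), collapse = " ")
    got <- unlist(tokenizeAndNormalize(text))
    # oracle: strip sentence structure entirely, extract token runs
    expected <- tolower(unlist(strsplit(text, "[^A-Za-z0-9_']+")))
    expected <- expected[nzchar(expected)]
    expect_identical(got, expected)
  }
})

test_that("normalization is idempotent on every emitted token", {
  norm <- lowercaseNormalizer()
  toks <- unlist(tokenizeAndNormalize("Heterogeneous TEXT with mesh_D045169."))
  expect_identical(norm(toks), toks)
})

test_that("version deduplication keeps the highest version per doc_id", {
  mk <- function(id, v, year = 2020L) {
    list(doc_id = id, year = year, version = v, text = "x.")
  }
  docs <- list(mk("A", 1L), mk("A", 2L), mk("B", 1L))
  kept <- deduplicateVersions(docs)
  key <- vapply(kept, function(d) paste0(d$doc_id, "v", d$version), "")
  expect_setequal(key, c("Av2", "Bv1"))

  expect_length(deduplicateVersions(list(mk("solo", 3L))), 1L)
  expect_error(deduplicateVersions(list(mk("A", 1L), mk("A", 1L))),
               "duplicate")
})

test_that("deduplication matches a group-by/argmax oracle on random documents", {
  set.seed(11)
  ids <- sample(LETTERS[1:12], 100, replace = TRUE)
  docs <- list()
  seen <- character(0)
  for (i in seq_along(ids)) {
    v <- sample(1:20, 1)
    while (paste(ids[i], v) %in% seen) v <- sample(1:20, 1)
    seen <- c(seen, paste(ids[i], v))
    docs[[i]] <- list(doc_id = ids[i], year = 2020L, version = v, text = "x.")
  }
  kept <- deduplicateVersions(docs)
  keptKey <- sort(vapply(kept, function(d) paste(d$doc_id, d$version), ""))
  df <- data.frame(id = ids, v = vapply(docs, `[[`, 1, "version"))
  oracle <- sort(unname(vapply(split(df, df$id), function(g) {
    paste(g$id[1], max(g$v))
  }, "")))
  expect_identical(keptKey, oracle)
})

test_that("year binning partitions sentences and conserves token counts", {
  mk <- function(id, year, text) list(doc_id = id, year = year, text = text)
  docs <- list(
    mk("a", 2020L, "alpha beta. gamma delta."),
    mk("b", 2020L, "epsilon zeta."),
    mk("c", 2021L, "eta theta.")
  )
  slices <- binByYear(docs)
  expect_named(slices, c("2020", "2021"))
  expect_length(slices[["2020"]]@sentences, 3L)
  expect_length(slices[["2021"]]@sentences, 1L)

  # conservation: per-year totals sum to the total over accepted documents
  totalIn <- sum(lengths(lapply(docs, function(d) {
    unlist(tokenizeAndNormalize(d$text))
  })))
  expect_identical(sum(vapply(slices, totalTokens, integer(1))), totalIn)

  # slice counts agree with a recount of their own sentences
  for (sl in slices) {
    recount <- table(unlist(sl@sentences))
    expect_identical(sl@tokenCounts[sort(names(recount))],
                     stats::setNames(as.integer(recount), sort(names(recount))))
  }

  expect_identical(binByYear(list()), list())
})

test_that("documents outside the analysis range are skipped with a message", {
  docs <- list(
    list(doc_id = "a", year = 1999L, text = "too early."),
    list(doc_id = "b", year = 2020L, text = "in range.")
  )
  expect_message(
    slices <- binByYear(docs, minYear = 2000L, maxYear = 2021L),
    "skipped"
  )
  expect_named(slices, "2020")
})

test_that("jsonl corpora and slice directories round-trip", {
  tmp <- withr::local_tempdir()
  jsonl <- file.path(tmp, "corpus.jsonl")
  writeLines(c(
    paste0('{"doc_id":"d1","year":2020,"version":2,',
           '"text":"severe acute respiratory syndrome spread.",',
           '"annotations":[{"start":0,"end":33,"type":"mesh","id":"D045169"}]}'),
    '{"doc_id":"d2","year":2021,"text":"cells respond."}'
  ), jsonl)
  docs <- readCorpusJsonl(jsonl)
  expect_length(docs, 2L)
  expect_identical(substituteAnnotations(docs[[1]]), "mesh_d045169 spread.")

  slices <- binByYear(docs)
  writeSlices(slices, file.path(tmp, "slices"))
  back <- readSlices(file.path(tmp, "slices"))
  expect_identical(names(back), names(slices))
  for (nm in names(slices)) {
    expect_identical(back[[nm]]@sentences, slices[[nm]]@sentences)
    expect_identical(back[[nm]]@tokenCounts, slices[[nm]]@tokenCounts)
  }
})
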