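# Replicate CBOW ensembles per year.

#' Training configuration for yearly CBOW ensembles
#'
#' Defaults follow the hyperparameters commonly used for year-binned
#' biomedical text: vector size 300, 10 epochs, minimum frequency cutoff 5,
#' context window 16, and ten replicate models per year so that intra-year
#' model instability can be measured. Negative sampling (5 negatives) with
#' standard 1e-3 frequency subsampling and a linearly decaying learning rate
#' are the classic word2vec defaults of that era.
#'
#' @param dim vector dimensionality (>= 2).
#' @param epochs training passes over the corpus.
#' @param minCount minimum token frequency; rarer tokens are dropped from the
#'   vocabulary (>= 1).
#' @param window one-sided context window size.
#' @param replicates models trained per year (>= 2: intra-year distances need
#'   at least one model pair).
#' @param baseSeed replicate r is trained with seed `baseSeed + r`; training
#'   is single-threaded, so a seed fully determines the vectors.
#' @param negative negative samples per positive example.
#' @param sample subsampling threshold for frequent tokens (0 disables).
#' @param alpha,minAlpha initial and final learning rate (linear decay).
#' @return A list of class `TrainingConfig`.
#' @export
trainingConfig <- function(dim = 300L, epochs = 10L, minCount = 5L,
                           window = 16L, replicates = 10L, baseSeed = 42L,
                           negative = 5L, sample = 1e-3,
                           alpha = 0.025, minAlpha = 1e-4) {
  stopifnot(dim >= 2L, replicates >= 2L, minCount >= 1L, window >= 1L,
            epochs >= 1L, negative >= 1L)
  structure(
    list(
      dim = as.integer(dim), epochs = as.integer(epochs),
      minCount = as.integer(minCount), window = as.integer(window),
      replicates = as.integer(replicates), baseSeed = as.integer(baseSeed),
      negative = as.integer(negative), sample = sample,
      alpha = alpha, minAlpha = minAlpha
    ),
    class = "TrainingConfig"
  )
}

#' @export
print.TrainingConfig <- function(x, ...) {
  cat(sprintf(
    "TrainingConfig: dim %d, %d epochs, minCount %d, window %d, %d replicates, baseSeed %d\n",
    x$dim, x$epochs, x$minCount, x$window, x$replicates, x$baseSeed
  ))
  invisible(x)
}

# Encode a slice's sentences as 0-based integer ids over the minCount vocab.
encodeSentences <- function(slice, minCount) {
  counts <- slice@tokenCounts
  vocab <- sort(names(counts)[counts >= minCount])
  if (length(vocab) == 0L) {
    stop("year ", slice@year, ": vocabulary empty after minCount filter")
  }
  idx <- seq_along(vocab)
  names(idx) <- vocab
  ids <- lapply(slice@sentences, function(s) {
    v <- idx[s]
    as.integer(v[!is.na(v)] - 1L)
  })
  list(vocab = vocab, counts = counts[vocab], ids = ids)
}

#' Train one replicate CBOW model
#'
#' @param slice a [CorpusSlice-class].
#' @param cfg a [trainingConfig()].
#' @param replicate 0-based replicate index; the training seed is
#'   `cfg$baseSeed + replicate`.
#' @return An [EmbeddingModel-class].
#' @export
trainModel <- function(slice, cfg = trainingConfig(), replicate = 0L) {
  enc <- encodeSentences(slice, cfg$minCount)
  mat <- .cbow_train_cpp(
    enc$ids, as.numeric(enc$counts), cfg$dim, cfg$window, cfg$epochs,
    cfg$negative, cfg$sample, cfg$alpha, cfg$minAlpha,
    as.numeric(cfg$baseSeed + replicate)
  )
  rownames(mat) <- enc$vocab
  embeddingModel(slice@year, replicate, mat, enc$counts,
                 totalTokens = slice@totalTokens)
}

#' Train the replicate ensemble for one year
#'
#' Trains `cfg$replicates` CBOW models on the same slice, replicate r seeded
#' with `cfg$baseSeed + r`. All replicates share the vocabulary (same corpus,
#' same frequency cutoff); they differ only through the seeded stochasticity
#' of initialization, window sampling, subsampling and negative sampling,
#' which is exactly the run-to-run variability the intra-year distance is
#' designed to measure.
#'
#' @inheritParams trainModel
#' @return A [YearEnsemble-class] (unaligned).
#' @export
trainYearEnsemble <- function(slice, cfg = trainingConfig()) {
  mods <- lapply(seq_len(cfg$replicates) - 1L, function(r) {
    trainModel(slice, cfg, replicate = r)
  })
  new("YearEnsemble", year = slice@year, models = mods, anchorId = integer(0))
}

#' Train ensembles for every year
#'
#' @param slices named list year -> [CorpusSlice-class].
#' @param cfg a [trainingConfig()].
#' @param verbose print one line per year.
#' @return A named list year -> [YearEnsemble-class].
#' @export
trainAllYears <- function(slices, cfg = trainingConfig(), verbose = FALSE) {
  out <- lapply(slices, function(sl) {
    if (verbose) message("training year ", sl@year)
    trainYearEnsemble(sl, cfg)
  })
  names(out) <- names(slices)
  out
}

#' Relative token frequency
#'
#' `count(token) / totalTokens` of a slice or model. For an
#' [EmbeddingModel-class] the denominator is the full corpus size of the
#' training slice (not just the retained vocabulary), so frequencies are
#' comparable across years with very different corpus sizes.
#'
#' @param x a [CorpusSlice-class] or [EmbeddingModel-class].
#' @param token token string (vectorized).
#' @return Numeric in \[0, 1\]; `NA` for tokens absent from the counts (a
#'   missing token is unknown, not frequency zero).
#' @export
relativeFrequency <- function(x, token) {
  counts <- tokenCounts(x)
  unname(counts[token]) / totalTokens(x)
}

# ---- word2vec text format --------------------------------------------------

#' Write / read embedding vectors in word2vec text format
#'
#' The interchange format is the classic word2vec text layout: a header line
#' `"V dim"`, then one line per token: the token followed by its `dim`
#' vector components, space-separated. Token counts travel in a
#' `<path>.counts.tsv` sidecar (token, count, plus a `__total__` row holding
#' the full corpus size).
#'
#' @param model an [EmbeddingModel-class].
#' @param path output path (conventionally `<year>_<replicate>.w2v`).
#' @return `writeWord2vec` returns `path` invisibly. `readWord2vec` returns
#'   an [EmbeddingModel-class]; vectors round-trip to within 1e-6.
#' @export
writeWord2vec <- function(model, path) {
  vocab <- rownames(model@vectors)
  if (any(grepl("[[:space:]]", vocab))) {
    stop("tokens containing whitespace cannot be saved in word2vec text format")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model@vectors), ncol(model@vectors)), con)
  body <- apply(model@vectors, 1L, function(v) {
    paste(format(v, digits = 9, scientific = TRUE, trim = TRUE), collapse = " ")
  })
  writeLines(paste(vocab, body), con)
  utils::write.table(
    rbind(
      data.frame(token = vocab, count = unname(model@tokenCounts[vocab])),
      data.frame(token = "__total__", count = model@totalTokens)
    ),
    paste0(path, ".counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeWord2vec
#' @param year,replicate metadata to attach on read (defaults parsed from the
#'   filename pattern `<year>_<replicate>.w2v` when possible).
#' @export
readWord2vec <- function(path, year = NA_integer_, replicate = NA_integer_) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed word2vec header at line 1: ", lines[1L])
  }
  V <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (length(lines) - 1L != V) {
    stop("header declares ", V, " rows but file has ", length(lines) - 1L)
  }
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad)) {
    stop("ragged vector row at line ", bad[1L] + 1L)
  }
  vocab <- vapply(parts, `[[`, character(1), 1L)
  mat <- matrix(
    as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
    nrow = V, ncol = d, byrow = TRUE, dimnames = list(vocab, NULL)
  )
  if (anyNA(mat)) stop("non-numeric vector component in ", path)

  if (is.na(year) || is.na(replicate)) {
    m <- regmatches(basename(path),
                    regexec("^([0-9]+)_([0-9]+)\\.w2v$", basename(path)))[[1L]]
    if (length(m) == 3L) {
      if (is.na(year)) year <- as.integer(m[2L])
      if (is.na(replicate)) replicate <- as.integer(m[3L])
    }
  }

  sidecar <- paste0(path, ".counts.tsv")
  if (file.exists(sidecar)) {
    tab <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             quote = "", comment.char = "",
                             colClasses = c("character", "integer"))
    total <- tab$count[tab$token == "__total__"]
    tab <- tab[tab$token != "__total__", , drop = FALSE]
    counts <- structure(tab$count, names = tab$token)[vocab]
    total <- if (length(total)) total[1L] else sum(counts)
  } else {
    counts <- structure(rep(1L, V), names = vocab)
    total <- V
  }
  embeddingModel(year, replicate, mat, counts, totalTokens = total)
}

#' Save / load yearly ensembles to a directory
#'
#' One `<year>_<replicate>.w2v` file (plus counts sidecar) per model.
#'
#' @param ensembles named list year -> [YearEnsemble-class].
#' @param dir directory.
#' @return `writeEnsembles` returns `dir` invisibly; `readEnsembles` the
#'   named ensemble list (unaligned flag; alignment metadata is not stored in
#'   the text format).
#' @export
writeEnsembles <- function(ensembles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ens in ensembles) {
    for (m in ens@models) {
      writeWord2vec(m, file.path(dir, sprintf("%d_%d.w2v", m@year, m@replicate)))
    }
  }
  invisible(dir)
}

#' @rdname writeEnsembles
#' @export
readEnsembles <- function(dir) {
  files <- list.files(dir, pattern = "^[0-9]+_[0-9]+\\.w2v$", full.names = TRUE)
  if (!length(files)) stop("no <year>_<replicate>.w2v files in ", dir)
  mods <- lapply(files, readWord2vec)
  yrs <- vapply(mods, function(m) m@year, integer(1))
  out <- lapply(sort(unique(yrs)), function(y) {
    ms <- mods[yrs == y]
    ms <- ms[order(vapply(ms, function(m) m@replicate, integer(1)))]
    new("YearEnsemble", year = y, models = ms, anchorId = integer(0))
  })
  names(out) <- sort(unique(yrs))
  out
}
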