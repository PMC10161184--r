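#' @import methods
NULL

#' CorpusSlice: one year's preprocessed corpus
#'
#' Holds the ordered token sentences of a single calendar year together with
#' the token counts implied by those sentences. Slices are the unit that
#' embedding models are trained on and that frequency statistics are read
#' from.
#'
#' @slot year single integer calendar year.
#' @slot sentences list of character vectors, one vector per sentence, tokens
#'   in order.
#' @slot tokenCounts named integer vector, token -> occurrence count.
#' @slot totalTokens single integer, the sum of `tokenCounts`.
#'
#' @seealso [corpusSlice()], [binByYear()], [relativeFrequency()]
#' @export
setClass("CorpusSlice",
  representation(
    year = "integer",
    sentences = "list",
    tokenCounts = "integer",
    totalTokens = "integer"
  )
)

setValidity("CorpusSlice", function(object) {
  msg <- character()
  if (length(object@year) != 1L) msg <- c(msg, "year must be a single integer")
  if (length(object@totalTokens) != 1L ||
      object@totalTokens != sum(object@tokenCounts)) {
    msg <- c(msg, "totalTokens must equal sum(tokenCounts)")
  }
  if (length(object@tokenCounts) &&
      (is.null(names(object@tokenCounts)) || anyNA(names(object@tokenCounts)))) {
    msg <- c(msg, "tokenCounts must be named")
  }
  if (any(object@tokenCounts < 0L)) msg <- c(msg, "tokenCounts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EmbeddingModel: one trained replicate for one year
#'
#' A CBOW word-embedding model: the vocabulary, a V x d matrix of vectors
#' (row i is the vector of `vocabulary(x)[i]`), and the corpus counts of the
#' vocabulary tokens.
#'
#' @slot year integer year the model was trained on.
#' @slot replicate 0-based replicate index within the year's ensemble.
#' @slot vectors numeric matrix, rownames are the vocabulary.
#' @slot tokenCounts named integer vector over the vocabulary.
#' @slot totalTokens total token count of the training slice (including
#'   tokens below the frequency cutoff, so relative frequencies are
#'   corpus-size-normalized).
#'
#' @seealso [trainYearEnsemble()], [readWord2vec()], [writeWord2vec()]
#' @export
setClass("EmbeddingModel",
  representation(
    year = "integer",
    replicate = "integer",
    vectors = "matrix",
    tokenCounts = "integer",
    totalTokens = "integer"
  )
)

setValidity("EmbeddingModel", function(object) {
  msg <- character()
  vocab <- rownames(object@vectors)
  if (is.null(vocab) || anyDuplicated(vocab)) {
    msg <- c(msg, "vectors must have unique rownames (the vocabulary)")
  }
  if (!is.numeric(object@vectors)) msg <- c(msg, "vectors must be numeric")
  if (nrow(object@vectors) > 0) {
    nrm <- sqrt(rowSums(object@vectors^2))
    if (any(nrm == 0)) msg <- c(msg, "zero-norm vector rows are not allowed")
  }
  if (!identical(sort(names(object@tokenCounts)), sort(vocab))) {
    msg <- c(msg, "tokenCounts must be named by the vocabulary")
  }
  if (length(msg)) msg else TRUE
})

#' YearEnsemble: the replicate models of one year
#'
#' The set of replicate [EmbeddingModel-class] objects trained on one year's
#' corpus, before or after rotation into an anchor model's coordinate space.
#' `anchorId` is `integer(0)` for an unaligned ensemble and `c(year,
#' replicate)` of the anchor after alignment.
#'
#' @slot year integer year.
#' @slot models list of [EmbeddingModel-class], all sharing year and
#'   dimensionality.
#' @slot anchorId integer(0) or c(anchor year, anchor replicate).
#' @export
setClass("YearEnsemble",
  representation(
    year = "integer",
    models = "list",
    anchorId = "integer"
  )
)

setValidity("YearEnsemble", function(object) {
  msg <- character()
  if (!length(object@models)) msg <- c(msg, "ensemble must contain >= 1 model")
  yrs <- vapply(object@models, function(m) m@year, integer(1))
  if (length(yrs) && any(yrs != object@year)) {
    msg <- c(msg, "all member models must share the ensemble year")
  }
  dims <- vapply(object@models, function(m) ncol(m@vectors), integer(1))
  if (length(unique(dims)) > 1) msg <- c(msg, "members must share dimensionality")
  if (!length(object@anchorId) %in% c(0L, 2L)) {
    msg <- c(msg, "anchorId must be integer(0) or c(year, replicate)")
  }
  if (length(msg)) msg else TRUE
})

# ---- constructors ----------------------------------------------------------

#' Construct a CorpusSlice from token sentences
#'
#' Counts tokens from the sentences so the count invariants hold by
#' construction.
#'
#' @param year integer calendar year.
#' @param sentences list of character vectors (token sentences).
#' @return A [CorpusSlice-class].
#' @examples
#' corpusSlice(2020L, list(c("viruses", "evolve"), c("cells", "respond")))
#' @export
corpusSlice <- function(year, sentences) {
  stopifnot(is.list(sentences))
  toks <- unlist(sentences, use.names = FALSE)
  counts <- if (length(toks)) {
    tab <- table(toks)
    structure(as.integer(tab), names = names(tab))
  } else {
    structure(integer(0), names = character(0))
  }
  new("CorpusSlice",
    year = as.integer(year), sentences = sentences,
    tokenCounts = counts, totalTokens = length(toks)
  )
}

#' @rdname EmbeddingModel-class
#' @param year,replicate year and replicate index of the model.
#' @param vectors V x d numeric matrix with the vocabulary as rownames.
#' @param tokenCounts named integer counts for the vocabulary.
#' @param totalTokens total token count of the training corpus; defaults to
#'   `sum(tokenCounts)`.
#' @export
embeddingModel <- function(year, replicate, vectors, tokenCounts,
                           totalTokens = sum(tokenCounts)) {
  new("EmbeddingModel",
    year = as.integer(year), replicate = as.integer(replicate),
    vectors = vectors,
    tokenCounts = structure(as.integer(tokenCounts), names = names(tokenCounts)),
    totalTokens = as.integer(totalTokens)
  )
}

# ---- accessors -------------------------------------------------------------

#' Accessors for corpus and embedding objects
#'
#' `vocabulary()` returns the token list; `tokenCounts()` the per-token
#' counts; `totalTokens()` the corpus size; `embeddingVectors()` the V x d
#' matrix; `models()` the replicate list of an ensemble; `isAligned()` whether
#' an ensemble has been rotated into an anchor space.
#'
#' @param x a [CorpusSlice-class], [EmbeddingModel-class] or
#'   [YearEnsemble-class].
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname accessors
#' @export
setGeneric("tokenCounts", function(x) standardGeneric("tokenCounts"))

#' @rdname accessors
#' @export
setGeneric("totalTokens", function(x) standardGeneric("totalTokens"))

#' @rdname accessors
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @rdname accessors
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' @rdname accessors
#' @export
setMethod("vocabulary", "CorpusSlice", function(x) names(x@tokenCounts))

#' @rdname accessors
#' @export
setMethod("vocabulary", "EmbeddingModel", function(x) rownames(x@vectors))

#' @rdname accessors
#' @export
setMethod("vocabulary", "YearEnsemble", function(x) vocabulary(x@models[[1L]]))

#' @rdname accessors
#' @export
setMethod("tokenCounts", "CorpusSlice", function(x) x@tokenCounts)

#' @rdname accessors
#' @export
setMethod("tokenCounts", "EmbeddingModel", function(x) x@tokenCounts)

#' @rdname accessors
#' @export
setMethod("totalTokens", "CorpusSlice", function(x) x@totalTokens)

#' @rdname accessors
#' @export
setMethod("totalTokens", "EmbeddingModel", function(x) x@totalTokens)

#' @rdname accessors
#' @export
setMethod("embeddingVectors", "EmbeddingModel", function(x) x@vectors)

#' @rdname accessors
#' @export
setMethod("models", "YearEnsemble", function(x) x@models)

#' @rdname accessors
#' @export
setMethod("isAligned", "YearEnsemble", function(x) length(x@anchorId) == 2L)

# ---- show ------------------------------------------------------------------

setMethod("show", "CorpusSlice", function(object) {
  cat(sprintf(
    "CorpusSlice (year %d): %d sentences, %d tokens, %d types\n",
    object@year, length(object@sentences), object@totalTokens,
    length(object@tokenCounts)
  ))
})

setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf(
    "EmbeddingModel (year %d, replicate %d): %d tokens x %d dims\n",
    object@year, object@replicate, nrow(object@vectors), ncol(object@vectors)
  ))
})

setMethod("show", "YearEnsemble", function(object) {
  al <- if (isAligned(object)) {
    sprintf("aligned to (%d, %d)", object@anchorId[1L], object@anchorId[2L])
  } else {
    "unaligned"
  }
  cat(sprintf(
    "YearEnsemble (year %d): %d replicates, %d x %d vectors, %s\n",
    object@year, length(object@models),
    nrow(object@models[[1L]]@vectors), ncol(object@models[[1L]]@vectors), al
  ))
})
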