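# Preprocessing: entity substitution, tokenization, deduplication, year binning.
#
# Documents are plain lists with fields doc_id, year, version (optional),
# text, and annotations (a data.frame with 0-based, end-exclusive character
# offsets: start, end, type, id). This mirrors the JSON-lines interchange
# format read by readCorpusJsonl().

#' Unicode-lowercasing token normalizer
#'
#' The default normalizer: maps every token to its lowercase form. Any
#' idempotent `function(token) token` can stand in for it, e.g. a lemmatizer
#' backed by an external NLP runtime; the pipeline only relies on the
#' contract, not on a particular linguistic engine.
#'
#' @return A function mapping a character vector of tokens to normalized
#'   tokens; idempotent by construction.
#' @examples
#' norm <- lowercaseNormalizer()
#' norm("Viruses")
#' @export
lowercaseNormalizer <- function() {
  function(tokens) tolower(tokens)
}

validateAnnotations <- function(ann, textLen, docId = "<unknown>") {
  if (is.null(ann) || nrow(ann) == 0L) {
    return(data.frame(
      start = integer(0), end = integer(0),
      type = character(0), id = character(0)
    ))
  }
  stopifnot(all(c("start", "end", "type", "id") %in% names(ann)))
  if (any(ann$start >= ann$end)) {
    stop("document ", docId, ": annotation with start >= end")
  }
  if (any(ann$start < 0L) || any(ann$end > textLen)) {
    stop("document ", docId, ": annotation span outside [0, nchar(text)]")
  }
  if (any(!nzchar(ann$type)) || any(!nzchar(ann$id))) {
    stop("document ", docId, ": empty annotation type or id")
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] < ann$end[-nrow(ann)])) {
    stop("document ", docId, ": overlapping annotation spans")
  }
  ann
}

#' Replace annotated spans by synthetic entity tokens
#'
#' Each annotated span of the document text is replaced by the single token
#' `type_id`, lowercased (e.g. a disease mention tagged `mesh` / `D045169`
#' becomes `mesh_d045169`), so every surface variant of a concept shares one
#' vocabulary entry. Replacements are applied right to left so earlier
#' offsets stay valid; text outside annotated spans is untouched. Offsets are
#' 0-based and end-exclusive.
#'
#' @param doc a document list with `text` and optionally `annotations`
#'   (data.frame with columns start, end, type, id).
#' @return The substituted text as a single string.
#' @details Documents with overlapping or out-of-range spans are rejected
#'   with an error naming the document rather than silently truncated.
#' @examples
#' doc <- list(
#'   doc_id = "x", text = "severe acute respiratory syndrome",
#'   annotations = data.frame(start = 0, end = 33, type = "mesh", id = "D045169")
#' )
#' substituteAnnotations(doc)
#' @export
substituteAnnotations <- function(doc) {
  text <- doc$text
  ann <- validateAnnotations(doc$annotations, nchar(text),
    docId = if (!is.null(doc$doc_id)) doc$doc_id else "<unknown>"
  )
  if (nrow(ann) == 0L) return(text)
  for (i in rev(seq_len(nrow(ann)))) {
    entity <- tolower(paste0(ann$type[i], "_", ann$id[i]))
    # 0-based end-exclusive [start, end) -> 1-based substr bounds
    before <- if (ann$start[i] > 0L) substr(text, 1L, ann$start[i]) else ""
    after <- substr(text, ann$end[i] + 1L, nchar(text))
    text <- paste0(before, entity, after)
  }
  text
}

#' Split text into normalized token sentences
#'
#' Sentences are split at sentence-final punctuation (`.`, `!`, `?`); tokens
#' are maximal runs of letters, digits, underscore or apostrophe, so the
#' synthetic entity tokens produced by [substituteAnnotations()] (e.g.
#' `mesh_d045169`) pass through unsplit. Every token is passed through the
#' normalizer.
#'
#' @param text a single string.
#' @param norm a normalizer function (default [lowercaseNormalizer()]).
#' @return A list of character vectors, one per non-empty sentence.
#' @examples
#' tokenizeAndNormalize("Viruses evolve. Cells respond.")
#' @export
tokenizeAndNormalize <- function(text, norm = lowercaseNormalizer()) {
  stopifnot(is.character(text), length(text) == 1L)
  sents <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1L]]
  out <- lapply(sents, function(s) {
    m <- regmatches(s, gregexpr("[\\p{L}\\p{N}_']+", s, perl = TRUE))[[1L]]
    if (length(m)) norm(m) else character(0)
  })
  out[lengths(out) > 0L]
}

#' Keep only the most recent version of each document
#'
#' Preprint servers store every posted revision; training on all of them
#' would overweight repeatedly revised manuscripts, so each `doc_id` is
#' filtered to its highest `version`. Documents without a version field are
#' kept as-is.
#'
#' @param docs list of document lists.
#' @return The filtered document list, original order of the surviving
#'   documents preserved.
#' @export
deduplicateVersions <- function(docs) {
  ids <- vapply(docs, function(d) as.character(d$doc_id), character(1))
  ver <- vapply(docs, function(d) {
    if (is.null(d$version)) NA_real_ else as.numeric(d$version)
  }, numeric(1))
  key <- paste(ids, ver)
  if (anyDuplicated(key[!is.na(ver)])) {
    dup <- key[!is.na(ver)][duplicated(key[!is.na(ver)])][1L]
    stop("duplicate (doc_id, version) pair: ", dup)
  }
  keep <- rep(TRUE, length(docs))
  for (id in unique(ids[!is.na(ver)])) {
    idx <- which(ids == id & !is.na(ver))
    if (length(idx) > 1L) keep[idx[-which.max(ver[idx])]] <- FALSE
  }
  docs[keep]
}

#' Bin documents into per-year corpus slices
#'
#' Runs entity substitution and tokenization on every document and partitions
#' the resulting sentences by publication year. Documents outside
#' `[minYear, maxYear]` are skipped (counted in a message), mirroring the
#' removal of sparsely covered early years from a corpus.
#'
#' @param docs list of (deduplicated) document lists.
#' @param norm normalizer passed to [tokenizeAndNormalize()].
#' @param minYear,maxYear inclusive analysis range; `NULL` means unbounded.
#' @return A named list year -> [CorpusSlice-class], years sorted ascending.
#' @export
binByYear <- function(docs, norm = lowercaseNormalizer(),
                      minYear = NULL, maxYear = NULL) {
  years <- vapply(docs, function(d) as.integer(d$year), integer(1))
  inRange <- rep(TRUE, length(docs))
  if (!is.null(minYear)) inRange <- inRange & years >= minYear
  if (!is.null(maxYear)) inRange <- inRange & years <= maxYear
  if (any(!inRange)) {
    message(sum(!inRange), " document(s) outside the analysis range skipped")
  }
  docs <- docs[inRange]
  years <- years[inRange]
  out <- list()
  for (y in sort(unique(years))) {
    sents <- list()
    for (d in docs[years == y]) {
      sents <- c(sents, tokenizeAndNormalize(substituteAnnotations(d), norm))
    }
    out[[as.character(y)]] <- corpusSlice(y, sents)
  }
  out
}

# ---- interchange formats ---------------------------------------------------

#' Read a JSON-lines corpus
#'
#' One document per line:
#' `{"doc_id": str, "year": int, "version": int?, "text": str,
#'   "annotations": [{"start": int, "end": int, "type": str, "id": str}]}`.
#'
#' @param path path to the `.jsonl` file.
#' @return A list of document lists suitable for [deduplicateVersions()] and
#'   [binByYear()].
#' @export
readCorpusJsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    d <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    if (!is.null(d$annotations) && length(d$annotations)) {
      d$annotations <- as.data.frame(d$annotations)
    } else {
      d$annotations <- NULL
    }
    d
  })
}

#' Write / read preprocessed corpus slices
#'
#' Each slice is stored as `<year>.txt` (one sentence per line, tokens
#' space-separated) with a `<year>.counts.tsv` sidecar (token, count).
#'
#' @param slices named list year -> [CorpusSlice-class].
#' @param dir output directory, created if missing.
#' @return `writeSlices` returns `dir` invisibly; `readSlices` returns the
#'   named slice list.
#' @export
writeSlices <- function(slices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(slices)) {
    sl <- slices[[nm]]
    writeLines(
      vapply(sl@sentences, paste, character(1), collapse = " "),
      file.path(dir, paste0(nm, ".txt"))
    )
    utils::write.table(
      data.frame(token = names(sl@tokenCounts), count = sl@tokenCounts),
      file.path(dir, paste0(nm, ".counts.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(dir)
}

#' @rdname writeSlices
#' @export
readSlices <- function(dir) {
  files <- list.files(dir, pattern = "^[0-9]+\\.txt$", full.names = TRUE)
  out <- list()
  for (f in files) {
    year <- as.integer(sub("\\.txt$", "", basename(f)))
    lines <- readLines(f, warn = FALSE, encoding = "UTF-8")
    sents <- strsplit(lines, " ", fixed = TRUE)
    out[[as.character(year)]] <- corpusSlice(year, sents)
  }
  out[order(as.integer(names(out)))]
}
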