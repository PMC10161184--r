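# Orthogonal Procrustes alignment of embedding models onto an anchor.
#
# Every trained model lives in its own arbitrary coordinate space (random
# initialization plus stochastic updates), so raw vectors from two models are
# not comparable even when the models encode the same geometry. Rotating each
# model onto a designated anchor model with the closed-form orthogonal
# Procrustes solution makes cross-model comparisons meaningful while leaving
# all within-model cosine distances untouched (orthogonal invariance).

#' Shared vocabulary of two models
#'
#' The sorted intersection of two models' vocabularies: the row-matched token
#' set a Procrustes fit is computed on. Sorting makes the order (and hence the
#' fit) deterministic.
#'
#' @param a,b [EmbeddingModel-class] objects.
#' @return Character vector of shared tokens, sorted.
#' @details Fewer shared tokens than dimensions leaves the rotation
#'   under-determined (warning); fewer than 2 is an error.
#' @export
sharedVocabulary <- function(a, b) {
  shared <- sort(intersect(vocabulary(a), vocabulary(b)))
  if (length(shared) < 2L) {
    stop("models share fewer than 2 tokens; cannot fit a rotation")
  }
  if (length(shared) < ncol(a@vectors)) {
    warning("shared vocabulary (", length(shared),
            ") smaller than dimensionality (", ncol(a@vectors),
            "); rotation is under-determined")
  }
  shared
}

#' Orthogonal Procrustes rotation
#'
#' The orthogonal matrix Q minimizing ||XQ - Y||_F over all orthogonal
#' matrices, via the closed form Q = U V' where X'Y = U S V' is the SVD. No
#' scaling or translation is applied.
#'
#' @param X,Y n x d matrices with matched rows (row i of both is the same
#'   token).
#' @return d x d orthogonal matrix Q.
#' @details A rank-deficient cross-covariance X'Y still yields U V' (the
#'   minimizer is then not unique); a degeneracy warning is emitted.
#' @examples
#' theta <- 0.7
#' R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
#' X <- matrix(rnorm(20), 10, 2)
#' Q <- procrustesRotation(X, X %*% R)
#' max(abs(Q - R))
#' @export
procrustesRotation <- function(X, Y) {
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)), nrow(X) >= 2L)
  M <- crossprod(X, Y)
  sv <- svd(M)
  if (min(sv$d) < max(sv$d) * 1e-12) {
    warning("rank-deficient cross-covariance; rotation not unique")
  }
  sv$u %*% t(sv$v)
}

#' Rotate one model into an anchor's coordinate space
#'
#' The rotation is fit on the shared vocabulary with the anchor but applied
#' to all of the model's rows, so tokens absent from the anchor year keep
#' their (rotated) vectors.
#'
#' @param model,anchor [EmbeddingModel-class] objects.
#' @return The rotated [EmbeddingModel-class].
#' @export
alignModel <- function(model, anchor) {
  shared <- sharedVocabulary(model, anchor)
  Q <- procrustesRotation(model@vectors[shared, , drop = FALSE],
                          anchor@vectors[shared, , drop = FALSE])
  rotated <- model@vectors %*% Q
  rownames(rotated) <- rownames(model@vectors)
  embeddingModel(model@year, model@replicate, rotated, model@tokenCounts,
                 totalTokens = model@totalTokens)
}

#' Align every model of every year onto one anchor model
#'
#' The anchor defaults to replicate 0 of the latest year. The anchor model
#' itself is left untouched. Models sharing fewer than 2 tokens with the
#' anchor are dropped from their ensemble with a warning.
#'
#' @param ensembles named list year -> [YearEnsemble-class].
#' @param anchorYear,anchorReplicate identify the anchor model; defaults:
#'   latest year, replicate 0.
#' @return A named list year -> aligned [YearEnsemble-class] (`anchorId` set).
#' @export
alignAll <- function(ensembles, anchorYear = NULL, anchorReplicate = 0L) {
  yrs <- vapply(ensembles, function(e) e@year, integer(1))
  if (is.null(anchorYear)) anchorYear <- max(yrs)
  hit <- which(yrs == anchorYear)
  if (!length(hit)) stop("anchor year ", anchorYear, " not found")
  anchorEns <- ensembles[[hit[1L]]]
  reps <- vapply(anchorEns@models, function(m) m@replicate, integer(1))
  if (!anchorReplicate %in% reps) {
    stop("anchor replicate ", anchorReplicate, " not found in year ", anchorYear)
  }
  anchor <- anchorEns@models[[which(reps == anchorReplicate)[1L]]]

  lapply(ensembles, function(ens) {
    mods <- lapply(ens@models, function(m) {
      if (m@year == anchor@year && m@replicate == anchor@replicate) return(m)
      tryCatch(alignModel(m, anchor), error = function(e) {
        warning("dropping model (", m@year, ", ", m@replicate, "): ",
                conditionMessage(e))
        NULL
      })
    })
    mods <- mods[!vapply(mods, is.null, logical(1))]
    new("YearEnsemble", year = ens@year, models = mods,
        anchorId = c(anchor@year, anchor@replicate))
  })
}
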