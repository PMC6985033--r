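#' @include AllClasses.R
NULL

#' Fuse window probabilities into per-frame classifications
#'
#' For every frame, the class-probability vectors of all windows containing
#' that frame are averaged arithmetically and the frame is assigned the
#' argmax class (ties broken by the lowest class index).  Frames covered by
#' no window (e.g. trailing frames dropped during windowing) inherit the
#' distribution of the nearest covered frame.
#'
#' @param windowProbs n x K matrix of window class probabilities.
#' @param windowStarts 1-based start frame of each window.
#' @param sws Window size in frames.
#' @param nFrames Total frames to label.
#' @return List with \code{classIdx} (integer per frame) and \code{probs}
#'   (nFrames x K averaged probabilities).
#' @export
frameFusion <- function(windowProbs, windowStarts, sws, nFrames) {
  windowProbs <- as.matrix(windowProbs)
  nw <- nrow(windowProbs)
  if (nw == 0L) stop("no windows to fuse")
  stopifnot(length(windowStarts) == nw, sws >= 1)
  K <- ncol(windowProbs)
  acc <- matrix(0, nFrames, K)
  cover <- integer(nFrames)
  for (w in seq_len(nw)) {
    idx <- windowStarts[w]:min(windowStarts[w] + sws - 1L, nFrames)
    acc[idx, ] <- acc[idx, ] + matrix(windowProbs[w, ], length(idx), K,
                                      byrow = TRUE)
    cover[idx] <- cover[idx] + 1L
  }
  covered <- cover > 0L
  if (!any(covered)) stop("no frame is covered by any window")
  probs <- acc
  probs[covered, ] <- acc[covered, , drop = FALSE] / cover[covered]
  if (any(!covered)) {
    covIdx <- which(covered)
    for (f in which(!covered)) {
      nearest <- covIdx[which.min(abs(covIdx - f))]
      probs[f, ] <- probs[nearest, ]
    }
  }
  list(classIdx = max.col(probs, ties.method = "first"), probs = probs)
}

#' Frame-level confusion matrix
#'
#' @param trueLabels,predLabels Equal-length label vectors.
#' @param vocabulary Class vocabulary defining row/column order; every label
#'   must belong to it.
#' @return Integer counts matrix, \code{counts[i, j]} = frames of true
#'   class i predicted as class j.
#' @export
confusionMatrix <- function(trueLabels, predLabels, vocabulary) {
  stopifnot(length(trueLabels) == length(predLabels))
  bad <- setdiff(unique(c(trueLabels, predLabels)), vocabulary)
  if (length(bad))
    stop("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  m <- table(factor(trueLabels, levels = vocabulary),
             factor(predLabels, levels = vocabulary))
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(vocabulary, vocabulary))
  m
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2pr/(p+r), with 0/0 defined as 0.  Micro averages pool all
#' individual predictions, so in single-label multiclass classification
#' micro-F1 = micro-precision = micro-recall = accuracy; macro averages are
#' unweighted means over classes.
#'
#' @param confusion Nonnegative counts matrix, rows = true classes.
#' @return An \linkS4class{EvaluationReport}.
#' @export
precisionRecallF1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is empty (all zero)")
  tp <- diag(confusion)
  colS <- colSums(confusion)
  rowS <- rowSums(confusion)
  safeDiv <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safeDiv(tp, colS)
  rec <- safeDiv(tp, rowS)
  f1 <- safeDiv(2 * prec * rec, prec + rec)
  microAcc <- sum(tp) / total
  vocab <- rownames(confusion)
  if (is.null(vocab)) vocab <- as.character(seq_len(nrow(confusion)))
  perClass <- data.frame(class = vocab, precision = prec, recall = rec,
                         f1 = f1, support = as.integer(rowS),
                         row.names = NULL)
  new("EvaluationReport",
      confusion = confusion,
      perClass = perClass,
      micro = c(precision = microAcc, recall = microAcc, f1 = microAcc),
      macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
      nFrames = as.integer(total))
}
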