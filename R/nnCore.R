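#' @include AllClasses.R synthesize.R
NULL

# Low-level ConvLSTM computations.  Between layers, activations live in a
# flat (B*T) x C matrix whose rows are ordered batch-fastest, time-slower
# (so a B x T x C array reshapes to it for free, column-major).  Temporal
# convolutions are "valid" (no padding) with ReLU activations, implemented
# as one indexed gather (im2col) plus one BLAS product per layer; the
# convolution weight rows are ordered kernel-offset fastest, input-channel
# slower.  Two stacked LSTM layers follow; the last time step's hidden
# state feeds one linear layer and a softmax.  Backward passes are
# hand-derived, so training is exactly reproducible from a seed.

.addBias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

.convForward <- function(A2, B, Tin, W, b) {
  Cin <- ncol(A2)
  k <- nrow(W) / Cin
  Tout <- Tin - k + 1L
  Xcol <- .cppIm2col(A2, B, Tin, k)
  br <- .cppBiasRelu(Xcol %*% W, b)
  list(out = br$out, Tout = Tout, Xcol = Xcol, neg = br$neg, Tin = Tin,
       k = k, Cin = Cin, B = B)
}

.convBackward <- function(cache, W, dOut) {
  dZ <- dOut
  dZ[cache$neg] <- 0
  list(dW = crossprod(cache$Xcol, dZ), db = colSums(dZ),
       dA = .cppCol2im(dZ %*% t(W), cache$B, cache$Tin, cache$Cin, cache$k))
}

.lstmForward <- function(A2, B, Tn, Wx, Wh, b) {
  fw <- .cppLstmForward(A2, B, Tn, Wx, Wh, b)
  fw$A2 <- A2
  fw$L <- ncol(Wh) / 4L
  fw$B <- B
  fw$Tn <- Tn
  fw
}

.lstmBackward <- function(fw, Wx, Wh, dH) {
  .cppLstmBackward(fw$A2, fw$out, fw$i, fw$f, fw$g, fw$o, fw$tc, fw$cPrev,
                   Wx, Wh, dH, fw$B, fw$Tn)
}

# full forward pass; X is a B x T x N array (or pre-flattened matrix with
# batch attribute); returns probabilities and (optionally) all caches
.nnForward <- function(params, X, cfg, training = FALSE, keepCache = FALSE) {
  d <- dim(X)
  B <- d[1]; Tn <- d[2]
  A <- X
  dim(A) <- c(B * Tn, d[3])
  convCaches <- if (keepCache) vector("list", cfg@convLayers)
  for (l in seq_len(cfg@convLayers)) {
    cv <- .convForward(A, B, Tn, params$conv[[l]]$W, params$conv[[l]]$b)
    Tn <- cv$Tout
    A <- cv$out
    if (keepCache) convCaches[[l]] <- cv else cv$Xcol <- NULL
  }
  lstmFws <- if (keepCache) vector("list", cfg@lstmLayers)
  for (l in seq_len(cfg@lstmLayers)) {
    fw <- .lstmForward(A, B, Tn, params$lstm[[l]]$Wx, params$lstm[[l]]$Wh,
                       params$lstm[[l]]$b)
    A <- fw$out
    if (keepCache) lstmFws[[l]] <- fw
  }
  hLast <- A[((Tn - 1L) * B + 1L):(Tn * B), , drop = FALSE]
  dropMask <- NULL
  if (training && cfg@dropoutRate > 0) {
    keep <- 1 - cfg@dropoutRate
    dropMask <- matrix(stats::rbinom(length(hLast), 1, keep) / keep,
                       nrow(hLast))
    hLast <- hLast * dropMask
  }
  logits <- .addBias(hLast %*% params$fc$W, params$fc$b)
  m <- logits[cbind(seq_len(B), max.col(logits, ties.method = "first"))]
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs, hLast = hLast, B = B)
  if (keepCache)
    out <- c(out, list(convCaches = convCaches, lstmFws = lstmFws,
                       dropMask = dropMask, Tn = Tn))
  out
}

# backward pass from the softmax cross-entropy; y is 1-based class index
.nnBackward <- function(params, fwd, cfg, y) {
  B <- fwd$B
  dLogits <- fwd$probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  grads <- list(conv = vector("list", cfg@convLayers),
                lstm = vector("list", cfg@lstmLayers),
                fc = list(W = crossprod(fwd$hLast, dLogits),
                          b = colSums(dLogits)))
  dHlast <- dLogits %*% t(params$fc$W)
  if (!is.null(fwd$dropMask)) dHlast <- dHlast * fwd$dropMask
  Tn <- fwd$Tn
  dNext <- NULL
  for (l in rev(seq_len(cfg@lstmLayers))) {
    fwL <- fwd$lstmFws[[l]]
    if (l == cfg@lstmLayers) {
      dH <- matrix(0, B * Tn, fwL$L)
      dH[((Tn - 1L) * B + 1L):(Tn * B), ] <- dHlast
    } else {
      dH <- dNext
    }
    bw <- .lstmBackward(fwL, params$lstm[[l]]$Wx, params$lstm[[l]]$Wh, dH)
    grads$lstm[[l]] <- list(Wx = bw$dWx, Wh = bw$dWh, b = bw$db)
    dNext <- bw$dA
  }
  for (l in rev(seq_len(cfg@convLayers))) {
    bw <- .convBackward(fwd$convCaches[[l]], params$conv[[l]]$W, dNext)
    grads$conv[[l]] <- list(W = bw$dW, b = bw$db)
    dNext <- bw$dA
  }
  grads
}

.crossEntropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

# elementwise tree operations over the parameter list structure
.treeMap <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- .treeMap(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

# one SGD-with-momentum step (velocity v <- mu v + g; p <- p - lr v),
# applied in place over the parameter tree: params and velocity must be
# uniquely referenced (deep-copied before the loop)
.sgdStepInPlace <- function(params, velocity, grads, lr, mu) {
  for (i in seq_along(params)) {
    if (is.list(params[[i]]))
      .sgdStepInPlace(params[[i]], velocity[[i]], grads[[i]], lr, mu)
    else
      .cppSgdUpdate(params[[i]], velocity[[i]], grads[[i]], lr, mu)
  }
  invisible(NULL)
}

# deep copy of a parameter tree (forces fresh, uniquely referenced arrays)
.deepCopy <- function(params) .treeMap(function(p) p + 0, params)
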