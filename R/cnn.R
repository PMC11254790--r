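#' Model architecture specification
#'
#' The compact identification network: conv(16, 3) + ReLU, max-pool(2),
#' conv(32, 3) + ReLU, max-pool(2), flatten, dense(100) + ReLU,
#' dropout(0.2), dense softmax over the enrolled subjects.
#'
#' @param nClasses number of enrolled subjects.
#' @param inputLen beat length (default 150).
#' @param conv1Kernels,conv2Kernels kernel counts (defaults 16 and 32).
#' @param kernelSize filter length (default 3).
#' @param poolSize pooling window (default 2).
#' @param denseUnits dense layer width (default 100).
#' @param dropoutRate dropout fraction (default 0.2).
#' @param padding \code{"valid"} (default) or \code{"same"}.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(nClasses, inputLen = 150L, conv1Kernels = 16L,
                      conv2Kernels = 32L, kernelSize = 3L, poolSize = 2L,
                      denseUnits = 100L, dropoutRate = 0.2,
                      padding = c("valid", "same")) {
  new("ModelSpec", inputLen = as.integer(inputLen),
      conv1Kernels = as.integer(conv1Kernels),
      conv2Kernels = as.integer(conv2Kernels),
      kernelSize = as.integer(kernelSize), poolSize = as.integer(poolSize),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      nClasses = as.integer(nClasses), padding = match.arg(padding))
}

#' Per-layer feature lengths
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return named list: conv1, pool1, conv2, pool2 feature lengths and
#'   \code{flatten} width.
#' @export
layerShapes <- function(spec) {
  convLen <- function(L) if (spec@padding == "valid")
    L - spec@kernelSize + 1L else L
  L1 <- convLen(spec@inputLen)
  P1 <- L1 %/% spec@poolSize
  L2 <- convLen(P1)
  P2 <- L2 %/% spec@poolSize
  stopIf(min(L1, P1, L2, P2) < 1L,
         "inputLen %d too short to survive two conv+pool stages",
         spec@inputLen)
  list(conv1 = L1, pool1 = P1, conv2 = L2, pool2 = P2,
       flatten = P2 * spec@conv2Kernels)
}

#' Build an untrained classifier
#'
#' Initializes all weights (Glorot-uniform, seeded) for the architecture
#' in \code{spec}. The returned object is a \linkS4class{TrainedClassifier}
#' with an empty training history; fit it with
#' \code{\link{trainClassifier}}.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param seed integer seed for weight initialization.
#' @return an untrained \linkS4class{TrainedClassifier}.
#' @export
buildModel <- function(spec, seed = 1L) {
  sh <- layerShapes(spec)
  K <- spec@kernelSize
  glorot <- function(fanIn, fanOut, nIn, nOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    matrix(stats::runif(nIn * nOut, -lim, lim), nIn, nOut)
  }
  weights <- withSeed(seed, list(
    W1 = glorot(K, K * spec@conv1Kernels, K, spec@conv1Kernels),
    b1 = numeric(spec@conv1Kernels),
    W2 = glorot(K * spec@conv1Kernels, K * spec@conv2Kernels,
                K * spec@conv1Kernels, spec@conv2Kernels),
    b2 = numeric(spec@conv2Kernels),
    W3 = glorot(sh$flatten, spec@denseUnits, sh$flatten, spec@denseUnits),
    b3 = numeric(spec@denseUnits),
    W4 = glorot(spec@denseUnits, spec@nClasses, spec@denseUnits,
                spec@nClasses),
    b4 = numeric(spec@nClasses)
  ))
  new("TrainedClassifier", spec = spec, weights = weights,
      labelOrder = character(0),
      history = data.frame(epoch = integer(0), loss = numeric(0),
                           acc = numeric(0), valLoss = numeric(0),
                           valAcc = numeric(0)))
}

#' Count trainable parameters
#'
#' @param model a \linkS4class{TrainedClassifier} or \linkS4class{ModelSpec}.
#' @return total number of trainable scalars.
#' @export
countParameters <- function(model) {
  if (is(model, "ModelSpec")) model <- buildModel(model, seed = 0L)
  sum(vapply(model@weights, length, numeric(1)))
}

# ---- internal forward/backward machinery --------------------------------
# Activations are (batch x L*C) matrices, channel-major: feature t of
# channel c lives in column (c-1)*L + t.

im2col <- function(A, L, C, K, Lout, pad) {
  B <- nrow(A)
  if (pad > 0) {
    Ap <- matrix(0, B, (L + 2 * pad) * C)
    for (c in seq_len(C))
      Ap[, (c - 1) * (L + 2 * pad) + pad + seq_len(L)] <-
        A[, (c - 1) * L + seq_len(L)]
    A <- Ap
    L <- L + 2 * pad
  }
  M <- matrix(0, B * Lout, K * C)
  for (c in seq_len(C)) for (k in seq_len(K))
    M[, (c - 1) * K + k] <- as.vector(A[, (c - 1) * L + k - 1 + seq_len(Lout)])
  M
}

col2im <- function(dM, B, L, C, K, Lout, pad) {
  Lp <- L + 2 * pad
  dA <- matrix(0, B, Lp * C)
  for (c in seq_len(C)) for (k in seq_len(K)) {
    cols <- (c - 1) * Lp + k - 1 + seq_len(Lout)
    dA[, cols] <- dA[, cols] + matrix(dM[, (c - 1) * K + k], B, Lout)
  }
  if (pad > 0) {
    out <- matrix(0, B, L * C)
    for (c in seq_len(C))
      out[, (c - 1) * L + seq_len(L)] <- dA[, (c - 1) * Lp + pad + seq_len(L)]
    out
  } else dA
}

convForward <- function(A, W, b, L, C, K, Lout, pad) {
  B <- nrow(A)
  M <- im2col(A, L, C, K, Lout, pad)
  Zm <- sweep(M %*% W, 2L, b, "+")
  Cout <- ncol(W)
  Z <- matrix(0, B, Lout * Cout)
  for (c in seq_len(Cout))
    Z[, (c - 1) * Lout + seq_len(Lout)] <- matrix(Zm[, c], B, Lout)
  list(Z = Z, M = M)
}

convBackward <- function(dZ, M, W, B, L, C, K, Lout, pad, needInputGrad) {
  Cout <- ncol(W)
  dZm <- matrix(0, B * Lout, Cout)
  for (c in seq_len(Cout))
    dZm[, c] <- as.vector(dZ[, (c - 1) * Lout + seq_len(Lout)])
  dW <- crossprod(M, dZm)
  db <- colSums(dZm)
  dA <- if (needInputGrad)
    col2im(dZm %*% t(W), B, L, C, K, Lout, pad) else NULL
  list(dW = dW, db = db, dA = dA)
}

poolForward <- function(A, L, C, P) {
  B <- nrow(A)
  Lout <- L %/% P
  Z <- matrix(0, B, Lout * C)
  argm <- matrix(0L, B, Lout * C)  # offset (0..P-1) of the max in each window
  for (c in seq_len(C)) {
    base <- (c - 1) * L
    obase <- (c - 1) * Lout
    cur <- A[, base + seq(1, P * Lout, by = P), drop = FALSE]
    off <- matrix(0L, B, Lout)
    for (p in seq_len(P - 1)) {
      nxt <- A[, base + seq(1 + p, P * Lout, by = P), drop = FALSE]
      better <- nxt > cur
      cur[better] <- nxt[better]
      off[better] <- p
    }
    Z[, obase + seq_len(Lout)] <- cur
    argm[, obase + seq_len(Lout)] <- off
  }
  list(Z = Z, argm = argm, Lout = Lout)
}

poolBackward <- function(dZ, argm, L, C, P, Lout) {
  B <- nrow(dZ)
  dA <- matrix(0, B, L * C)
  for (c in seq_len(C)) {
    base <- (c - 1) * L
    obase <- (c - 1) * Lout
    for (p in seq_len(P) - 1L) {
      sel <- argm[, obase + seq_len(Lout), drop = FALSE] == p
      block <- dZ[, obase + seq_len(Lout), drop = FALSE] * sel
      cols <- base + seq(1 + p, P * Lout, by = P)
      dA[, cols] <- dA[, cols] + block
    }
  }
  dA
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

cnnForward <- function(weights, spec, X, dropMask = NULL) {
  sh <- layerShapes(spec)
  K <- spec@kernelSize; P <- spec@poolSize
  pad <- if (spec@padding == "same") (K - 1L) %/% 2L else 0L
  c1 <- convForward(X, weights$W1, weights$b1, spec@inputLen, 1L, K,
                    sh$conv1, pad)
  A1 <- pmax(c1$Z, 0)
  p1 <- poolForward(A1, sh$conv1, spec@conv1Kernels, P)
  c2 <- convForward(p1$Z, weights$W2, weights$b2, sh$pool1,
                    spec@conv1Kernels, K, sh$conv2, pad)
  A2 <- pmax(c2$Z, 0)
  p2 <- poolForward(A2, sh$conv2, spec@conv2Kernels, P)
  H <- sweep(p2$Z %*% weights$W3, 2L, weights$b3, "+")
  Hr <- pmax(H, 0)
  Hd <- if (is.null(dropMask)) Hr else Hr * dropMask
  logits <- sweep(Hd %*% weights$W4, 2L, weights$b4, "+")
  probs <- softmaxRows(logits)
  list(probs = probs, c1 = c1, A1 = A1, p1 = p1, c2 = c2, A2 = A2,
       p2 = p2, Hr = Hr, Hd = Hd, sh = sh, pad = pad)
}

cnnBackward <- function(weights, spec, X, fwd, Y, dropMask) {
  B <- nrow(X)
  sh <- fwd$sh; K <- spec@kernelSize; P <- spec@poolSize; pad <- fwd$pad
  dlog <- (fwd$probs - Y) / B
  gW4 <- crossprod(fwd$Hd, dlog); gb4 <- colSums(dlog)
  dHd <- dlog %*% t(weights$W4)
  dHr <- if (is.null(dropMask)) dHd else dHd * dropMask
  dH <- dHr * (fwd$Hr > 0)
  gW3 <- crossprod(fwd$p2$Z, dH); gb3 <- colSums(dH)
  dP2 <- dH %*% t(weights$W3)
  dA2 <- poolBackward(dP2, fwd$p2$argm, sh$conv2, spec@conv2Kernels, P,
                      sh$pool2)
  dZ2 <- dA2 * (fwd$c2$Z > 0)
  bk2 <- convBackward(dZ2, fwd$c2$M, weights$W2, B, sh$pool1,
                      spec@conv1Kernels, K, sh$conv2, pad, TRUE)
  dA1 <- poolBackward(bk2$dA, fwd$p1$argm, sh$conv1, spec@conv1Kernels, P,
                      sh$pool1)
  dZ1 <- dA1 * (fwd$c1$Z > 0)
  bk1 <- convBackward(dZ1, fwd$c1$M, weights$W1, B, spec@inputLen, 1L, K,
                      sh$conv1, pad, FALSE)
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

ceLoss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

# ---- training ------------------------------------------------------------

#' Training configuration
#'
#' The fixed recipe: Adam at learning rate 0.001, batch size 32,
#' categorical cross-entropy, at most 500 epochs, early stopping on
#' validation loss with patience 20 and best-weights restoration.
#'
#' @param learningRate Adam step size.
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed integer seed governing shuffling, dropout and weight init.
#' @param normalize \code{"none"} (beats fed in mV, the default) or
#'   \code{"zscore"} (per-beat standardization, for robustness studies).
#' @return a validated config list.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 32L,
                        maxEpochs = 500L, patience = 20L, seed = 1L,
                        normalize = c("none", "zscore")) {
  stopIf(learningRate <= 0, "learningRate must be positive")
  stopIf(batchSize < 1, "batchSize must be >= 1")
  stopIf(patience < 1, "patience must be >= 1")
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed), normalize = match.arg(normalize))
}

normalizeBeats <- function(X, mode) {
  if (mode != "zscore") return(X)
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowMeans((X - mu)^2), 1e-12))
  (X - mu) / sdv
}

oneHot <- function(labels, labelOrder) {
  j <- match(labels, labelOrder)
  stopIf(anyNA(j), "label(s) %s absent from the training label set",
         paste(unique(labels[is.na(j)]), collapse = ", "))
  Y <- matrix(0, length(labels), length(labelOrder))
  Y[cbind(seq_along(labels), j)] <- 1
  Y
}

#' Fit the classifier
#'
#' Mini-batch Adam optimization of the categorical cross-entropy, with the
#' Table-style fixed recipe in \code{cfg} (lr 0.001, batch 32, at most 500
#' epochs) and early stopping on validation loss (patience epochs, best
#' weights restored). Label order is the sorted set of training subject
#' ids; a validation label outside it is an error (closed-set contract).
#' Deterministic for a fixed seed on a single thread.
#'
#' @param model an untrained \linkS4class{TrainedClassifier} from
#'   \code{\link{buildModel}}, or a \linkS4class{ModelSpec} (a model is
#'   then built with the config seed).
#' @param train,val \linkS4class{BeatDataset} partitions sharing a label
#'   set.
#' @param cfg a \code{\link{trainConfig}}.
#' @param quiet suppress per-epoch progress.
#' @return the fitted \linkS4class{TrainedClassifier}.
#' @export
trainClassifier <- function(model, train, val, cfg = trainConfig(),
                            quiet = TRUE) {
  if (is(model, "ModelSpec")) model <- buildModel(model, seed = cfg$seed)
  spec <- model@spec
  labelOrd <- sort(unique(train@labels))
  stopIf(length(labelOrd) != spec@nClasses,
         "training set has %d classes but the model expects %d",
         length(labelOrd), spec@nClasses)
  Xtr <- normalizeBeats(train@beats, cfg$normalize)
  Ytr <- oneHot(train@labels, labelOrd)
  Xva <- normalizeBeats(val@beats, cfg$normalize)
  Yva <- oneHot(val@labels, labelOrd)
  stopIf(ncol(Xtr) != spec@inputLen,
         "beat length %d does not match model input %d",
         ncol(Xtr), spec@inputLen)

  w <- model@weights
  mAdam <- lapply(w, function(p) p * 0)
  vAdam <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  tAdam <- 0L
  n <- nrow(Xtr)
  history <- data.frame()
  best <- list(loss = Inf, weights = w, epoch = 0L)
  dropP <- spec@dropoutRate

  evalSet <- function(weights, X, Y) {
    nloc <- nrow(X)
    chunks <- split(seq_len(nloc), ceiling(seq_len(nloc) / 512))
    loss <- 0; correct <- 0
    for (ix in chunks) {
      fw <- cnnForward(weights, spec, X[ix, , drop = FALSE])
      loss <- loss + ceLoss(fw$probs, Y[ix, , drop = FALSE]) * length(ix)
      correct <- correct +
        sum(max.col(fw$probs, ties.method = "first") ==
              max.col(Y[ix, , drop = FALSE], ties.method = "first"))
    }
    c(loss = loss / nloc, acc = correct / nloc)
  }

  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batchSize))
      epLoss <- 0; epCorrect <- 0
      for (ix in batches) {
        Xb <- Xtr[ix, , drop = FALSE]
        Yb <- Ytr[ix, , drop = FALSE]
        dropMask <- if (dropP > 0)
          matrix(stats::rbinom(length(ix) * spec@denseUnits, 1L, 1 - dropP),
                 length(ix), spec@denseUnits) / (1 - dropP)
        else NULL
        fw <- cnnForward(w, spec, Xb, dropMask)
        epLoss <- epLoss + ceLoss(fw$probs, Yb) * length(ix)
        epCorrect <- epCorrect +
          sum(max.col(fw$probs, ties.method = "first") ==
                max.col(Yb, ties.method = "first"))
        g <- cnnBackward(w, spec, Xb, fw, Yb, dropMask)
        tAdam <- tAdam + 1L
        corr <- cfg$learningRate *
          sqrt(1 - beta2^tAdam) / (1 - beta1^tAdam)
        for (nm in names(w)) {
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g[[nm]]
          vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g[[nm]]^2
          w[[nm]] <- w[[nm]] - corr * mAdam[[nm]] / (sqrt(vAdam[[nm]]) + eps)
        }
      }
      vl <- evalSet(w, Xva, Yva)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epLoss / n, acc = epCorrect / n,
        valLoss = vl["loss"], valAcc = vl["acc"], row.names = NULL))
      if (!quiet)
        logMsg("epoch %3d: loss %.4f acc %.4f | val loss %.4f val acc %.4f",
               epoch, epLoss / n, epCorrect / n, vl["loss"], vl["acc"])
      if (vl["loss"] < best$loss - 1e-9) {
        best <- list(loss = vl["loss"], weights = w, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  new("TrainedClassifier", spec = spec, weights = best$weights,
      labelOrder = labelOrd, history = history)
}

#' Class-probability predictions
#'
#' @param model a fitted \linkS4class{TrainedClassifier}.
#' @param beats a \linkS4class{BeatDataset} or numeric matrix of beat rows.
#' @param normalize input scaling; must match the training setting.
#' @return matrix of class probabilities (rows sum to 1), columns in
#'   \code{labelOrder(model)} order.
#' @export
predictProba <- function(model, beats, normalize = "none") {
  X <- if (is(beats, "BeatDataset")) beats@beats else as.matrix(beats)
  stopIf(ncol(X) != model@spec@inputLen,
         "beat length %d does not match model input %d",
         ncol(X), model@spec@inputLen)
  X <- normalizeBeats(X, normalize)
  chunks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / 512))
  out <- matrix(0, nrow(X), model@spec@nClasses)
  for (ix in chunks)
    out[ix, ] <- cnnForward(model@weights, model@spec,
                            X[ix, , drop = FALSE])$probs
  colnames(out) <- model@labelOrder
  out
}

#' Predicted subject labels
#'
#' Argmax of the softmax output; ties resolved toward the lowest class
#' index.
#'
#' @inheritParams predictProba
#' @return character vector of predicted subject ids.
#' @export
predictLabels <- function(model, beats, normalize = "none") {
  p <- predictProba(model, beats, normalize)
  model@labelOrder[max.col(p, ties.method = "first")]
}

#' @describeIn predictLabels S4 predict method returning labels
#'   (\code{type = "class"}) or probabilities (\code{type = "prob"}).
#' @param object a fitted \linkS4class{TrainedClassifier}.
#' @param type \code{"class"} or \code{"prob"}.
#' @param ... passed through (\code{beats}, \code{normalize}).
#' @export
setMethod("predict", "TrainedClassifier",
          function(object, beats, type = c("class", "prob"), ...) {
            type <- match.arg(type)
            if (type == "class") predictLabels(object, beats, ...)
            else predictProba(object, beats, ...)
          })
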