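# Shared fixtures, all generated in code.

# Quick labeled beat rows without running the signal chain: class-specific
# sinusoid morphology plus small noise, 150 samples per row.
syntheticBeatClass <- function(label, n, shape = 1, noiseSd = 0.05,
                               seed = 1L, len = 150L) {
  t <- seq(0, 1, length.out = len)
  base <- sin(2 * pi * (2 + shape) * t) + 0.3 * cos(2 * pi * shape * t)
  set.seed(seed)
  X <- matrix(rep(base, each = n), n, len) + rnorm(n * len, 0, noiseSd)
  beatDataset(X, rep(label, n), rep(paste0(label, "_rec"), n))
}

syntheticBeatCohort <- function(counts, noiseSd = 0.05, seed = 1L) {
  parts <- lapply(seq_along(counts), function(i)
    syntheticBeatClass(sprintf("c%02d", i), counts[i], shape = i,
                       noiseSd = noiseSd, seed = seed + i))
  mergeDatasets(parts)
}

# A no-noise, constant-RR synthetic record: every stage's behavior on it is
# predictable from the construction.
cleanRecord <- function(seed = 7L, meanRR = 800, duration = 45,
                        fsHz = 500, sdnn = 0, noise = NULL) {
  tpl <- sampleSubject(seed, subjectId = sprintf("S%03d", seed))
  if (is.null(noise)) noise <- noiseSpec(0, 0.25, 0, 50, 0)
  generateRecord(tpl, subjectPhysiology(meanRR, sdnn, 400), noise,
                 duration = duration, fsHz = fsHz, seed = seed)
}

# Brute-force metric oracle: direct pair scan over (true, pred), one-vs-rest
# counting per class, no reuse of the package's evaluation path.
oracleMetrics <- function(yTrue, yPred, labels) {
  k <- length(labels)
  cm <- matrix(0L, k, k)
  for (i in seq_along(yTrue)) {
    r <- which(labels == yTrue[i])
    c <- which(labels == yPred[i])
    cm[r, c] <- cm[r, c] + 1L
  }
  total <- length(yTrue)
  prec <- sens <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- sum(yTrue == labels[c] & yPred == labels[c])
    fp <- sum(yTrue != labels[c] & yPred == labels[c])
    fn <- sum(yTrue == labels[c] & yPred != labels[c])
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + sens[c] == 0) 0 else
      2 * prec[c] * sens[c] / (prec[c] + sens[c])
  }
  list(cm = cm, accuracy = sum(diag(cm)) / total,
       macroPrecision = mean(prec), macroSensitivity = mean(sens),
       macroF1 = mean(f1))
}

# Match detected to true peak indices within a tolerance; each true peak can
# absorb one detection. Returns TP / FP / FN counts.
matchPeaks <- function(detected, truth, tol) {
  usedT <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!usedT & abs(truth - d) <= tol)
    if (length(j)) {
      usedT[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}
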