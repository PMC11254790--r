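#' Balancing configuration
#'
#' Per-subject beat counts are equalized to a common target: the rounded
#' mean of the original class sizes (\code{policy = "mean"}) or their
#' maximum (\code{policy = "max"}). Minority classes are up-sampled with
#' SMOTE (k = 5 nearest same-class neighbors, Euclidean distance on the
#' beat vectors); majority classes are randomly down-sampled. With the
#' default \code{scope = "train_only"} balancing is applied to the
#' training partition only, so no SMOTE interpolant of a test beat can
#' leak into training; \code{"whole_dataset"} balances before splitting.
#'
#' @param policy \code{"mean"} or \code{"max"}.
#' @param kNeighbors SMOTE neighborhood size.
#' @param seed integer seed.
#' @param scope \code{"train_only"} or \code{"whole_dataset"}.
#' @return a validated config list.
#' @export
balanceConfig <- function(policy = c("max", "mean"), kNeighbors = 5L,
                          seed = 1L, scope = c("train_only", "whole_dataset")) {
  stopIf(kNeighbors < 1, "kNeighbors must be >= 1")
  list(policy = match.arg(policy), kNeighbors = as.integer(kNeighbors),
       seed = as.integer(seed), scope = match.arg(scope))
}

#' Common per-class target count
#'
#' @param counts named integer vector of per-class sizes.
#' @param policy \code{"mean"} (rounded arithmetic mean) or \code{"max"}.
#' @return the target count (integer).
#' @export
targetCount <- function(counts, policy = c("max", "mean")) {
  policy <- match.arg(policy)
  stopIf(length(counts) == 0, "counts must be non-empty")
  if (policy == "max") as.integer(max(counts))
  else as.integer(round(mean(counts)))
}

#' SMOTE over-sampling of one class
#'
#' Generates \code{nNew} synthetic rows. Each synthetic row is
#' \code{s = x + lambda * (x_nn - x)} where \code{x} is a class row
#' (cycled in order), \code{x_nn} one of its k nearest same-class
#' neighbors (Euclidean), and \code{lambda ~ U[0, 1]}. The provenance of
#' every synthetic row (seed row, neighbor row, lambda) is returned so the
#' interpolation can be replayed and verified.
#'
#' @param X numeric matrix of same-class rows (>= 2 rows).
#' @param nNew number of synthetic rows to generate.
#' @param k neighborhood size; effective k is \code{min(k, nrow(X) - 1)}.
#' @param seed integer seed.
#' @return list with \code{rows} (nNew x ncol matrix) and
#'   \code{provenance} (data.frame seedRow, neighborRow, lambda).
#' @export
smoteOversample <- function(X, nNew, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopIf(n < 2, "SMOTE needs at least 2 rows in the class; got %d", n)
  kEff <- min(k, n - 1L)
  if (nNew == 0)
    return(list(rows = X[0, , drop = FALSE],
                provenance = data.frame(seedRow = integer(0),
                                        neighborRow = integer(0),
                                        lambda = numeric(0))))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nnIdx <- matrix(0L, n, kEff)
  for (i in seq_len(n)) nnIdx[i, ] <- order(D[i, ])[seq_len(kEff)]
  withSeed(seed, {
    seedRow <- ((seq_len(nNew) - 1L) %% n) + 1L
    pick <- sample.int(kEff, nNew, replace = TRUE)
    neighborRow <- nnIdx[cbind(seedRow, pick)]
    lambda <- stats::runif(nNew)
    rows <- X[seedRow, , drop = FALSE] +
      lambda * (X[neighborRow, , drop = FALSE] - X[seedRow, , drop = FALSE])
    list(rows = rows,
         provenance = data.frame(seedRow = seedRow,
                                 neighborRow = neighborRow,
                                 lambda = lambda))
  })
}

#' Random down-sampling without replacement
#'
#' @param X numeric matrix of class rows.
#' @param n target row count (<= nrow(X)).
#' @param seed integer seed.
#' @return integer vector of retained row indices (sorted).
#' @export
downsampleRows <- function(X, n, seed = 1L) {
  m <- nrow(as.matrix(X))
  stopIf(n > m, "cannot down-sample %d rows to %d", m, n)
  if (n == m) return(seq_len(m))
  withSeed(seed, sort(sample.int(m, n)))
}

#' Balance a beat dataset to a 1:1 class ratio
#'
#' Every class ends at exactly the policy target count: minorities via
#' SMOTE (all original rows retained), majorities via random
#' down-sampling. Synthetic rows keep their class label and a
#' \code{"SMOTE"} record id; the full provenance is attached as the
#' \code{"smoteProvenance"} attribute for replay verification.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param cfg a \code{\link{balanceConfig}}.
#' @return the balanced \linkS4class{BeatDataset}.
#' @export
balanceDataset <- function(ds, cfg = balanceConfig()) {
  labs <- ds@labels
  classes <- sort(unique(labs))
  counts <- vapply(classes, function(cl) sum(labs == cl), integer(1))
  tgt <- targetCount(counts, cfg$policy)
  stopIf(any(counts < tgt) && length(classes) < 2,
         "SMOTE needs at least 2 classes")
  parts <- list()
  prov <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    idx <- which(labs == cl)
    sd <- childSeed(cfg$seed, ci)
    if (length(idx) > tgt) {
      keep <- idx[downsampleRows(ds@beats[idx, , drop = FALSE], tgt, sd)]
      parts[[cl]] <- subsetBeats(ds, keep)
    } else if (length(idx) < tgt) {
      sm <- smoteOversample(ds@beats[idx, , drop = FALSE],
                            tgt - length(idx), cfg$kNeighbors, sd)
      synth <- beatDataset(sm$rows, rep(cl, nrow(sm$rows)),
                           rep("SMOTE", nrow(sm$rows)))
      parts[[cl]] <- bindBeats(list(subsetBeats(ds, idx), synth))
      p <- sm$provenance
      p$class <- cl
      p$seedRow <- idx[p$seedRow]        # indices into the input dataset
      p$neighborRow <- idx[p$neighborRow]
      prov[[cl]] <- p
    } else {
      parts[[cl]] <- subsetBeats(ds, idx)
    }
  }
  out <- bindBeats(unname(parts))
  attr(out, "smoteProvenance") <-
    if (length(prov)) do.call(rbind, unname(prov)) else NULL
  out
}
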