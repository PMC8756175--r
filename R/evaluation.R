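#' Reduce ternary predictions to binary class calls
#'
#' Evaluation is binary (interacting vs negative): the single-protein
#' class is a training device and is excluded. The default policy calls
#' the argmax over the two pair-class probabilities, with ties broken
#' conservatively towards \code{"negative"}. The alternative fixed
#' threshold policy calls \code{"interacting"} when
#' \code{P(interacting) > threshold}.
#'
#' @param results list of \linkS4class{PredictionResult} (or a numeric
#'   matrix of ternary probability rows).
#' @param policy \code{"argmax"} (default) or \code{"threshold"}.
#' @param threshold cut-off on P(interacting) for the threshold policy.
#' @return character vector of \code{"interacting"} / \code{"negative"}.
#' @export
binarizeCalls <- function(results, policy = c("argmax", "threshold"),
                          threshold = 0.5) {
  policy <- match.arg(policy)
  pm <- probMatrix(results)
  if (policy == "argmax")
    ifelse(pm[, 1L] > pm[, 2L], "interacting", "negative")
  else
    ifelse(pm[, 1L] > threshold, "interacting", "negative")
}

probMatrix <- function(results) {
  if (is.matrix(results)) return(results)
  do.call(rbind, lapply(results, probs))
}

#' Confusion counts of binary calls
#'
#' @param calls character vector of predicted classes
#'   (\code{"interacting"} / \code{"negative"}).
#' @param labels character vector of true classes, same length.
#' @return named list with TP, FP, TN, FN (positive class =
#'   interacting).
#' @export
confusionCounts <- function(calls, labels) {
  if (length(calls) != length(labels))
    stopf("calls and labels must have equal length")
  list(TP = sum(calls == "interacting" & labels == "interacting"),
       FP = sum(calls == "interacting" & labels == "negative"),
       TN = sum(calls == "negative" & labels == "negative"),
       FN = sum(calls == "negative" & labels == "interacting"))
}

#' Binary classification metrics
#'
#' Computes accuracy, precision, sensitivity (recall), specificity, F1
#' and the Matthews correlation coefficient from confusion counts, plus
#' threshold-free average precision (step-wise interpolated area under
#' the precision-recall curve, for each class orientation) and ROC AUC
#' (Mann-Whitney rank statistic, ties at half weight) when ranking
#' scores are supplied. Any metric with a zero denominator is reported
#' as NA with a warning, never silently as 0.
#'
#' @param counts list with TP, FP, TN, FN (see
#'   \code{\link{confusionCounts}}).
#' @param scores optional numeric vector of P(interacting) for
#'   threshold-free metrics.
#' @param labels true classes aligned with \code{scores}.
#' @return named list of metrics.
#' @examples
#' metricsReport(list(TP = 40, FP = 10, TN = 45, FN = 5))
#' @export
metricsReport <- function(counts, scores = NULL, labels = NULL) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0L) stopf("no evaluated pairs")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined (zero denominator); reported as NA", what)
      return(NA_real_)
    }
    num / den
  }
  acc <- (TP + TN) / total
  prec <- safeDiv(TP, TP + FP, "precision")
  sens <- safeDiv(TP, TP + FN, "sensitivity")
  spec <- safeDiv(TN, TN + FP, "specificity")
  # count form of the harmonic mean: defined whenever any of TP,FP,FN > 0
  f1 <- safeDiv(2 * TP, 2 * TP + FP + FN, "F1")
  mccDen <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mccDen == 0) {
    warnf("MCC undefined (zero denominator); reported as NA")
    NA_real_
  } else (TP * TN - FP * FN) / mccDen
  out <- list(accuracy = acc, precision = prec, sensitivity = sens,
              specificity = spec, f1 = f1, mcc = mcc)
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(labels))
    out$ap_interacting <- averagePrecision(scores,
                                           labels == "interacting")
    out$ap_negative <- averagePrecision(-scores, labels == "negative")
    out$auc <- rankAUC(scores, labels == "interacting")
  }
  out
}

# step-wise interpolated AP: mean of precision@k over the positive hits
# of the score-descending ranking (ties broken by stable order)
averagePrecision <- function(scores, isPos) {
  nPos <- sum(isPos)
  if (nPos == 0L) {
    warnf("average precision undefined (no positives); reported as NA")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  hits <- isPos[ord]
  precAt <- cumsum(hits) / seq_along(hits)
  sum(precAt[hits]) / nPos
}

# ROC AUC as the normalized Mann-Whitney U statistic
rankAUC <- function(scores, isPos) {
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L) {
    warnf("AUC undefined (single-class input); reported as NA")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Predict and score a pair list against a trained model
#'
#' @param pairs \linkS4class{PairList} (labels optional).
#' @param sequences named \code{AAStringSet} resolving all pair ids.
#' @param params trained \linkS4class{NetworkParams}.
#' @param alphabet residue alphabet.
#' @return data.frame with idA, idB, the three class probabilities, the
#'   binary call and (when present) the true label.
#' @export
evaluatePairs <- function(pairs, sequences, params,
                          alphabet = trioAlphabet()) {
  e <- pairFrame(pairs)
  cfg <- params@config
  seqChar <- as.character(sequences)
  names(seqChar) <- names(sequences)
  used <- unique(c(e$idA, e$idB))
  enc <- lapply(seqChar[used], encodeProtein, lmax = cfg@lmax,
                alphabet = alphabet)
  pm <- t(vapply(seq_len(nrow(e)), function(i)
    probs(predictPair(enc[[e$idA[i]]], enc[[e$idB[i]]], params)),
    numeric(3)))
  data.frame(idA = e$idA, idB = e$idB,
             p_interacting = pm[, 1L], p_negative = pm[, 2L],
             p_single = pm[, 3L],
             call = binarizeCalls(pm), label = e$label,
             stringsAsFactors = FALSE)
}

#' k-fold cross-validated training and evaluation
#'
#' Stratified k-fold protocol: for every fold, a model is trained from
#' scratch on the remaining folds' pairs — with single-protein cases
#' derived from the training folds' sequences only, so no test
#' information leaks through the augmentation — and evaluated on the
#' held-out fold's two-class pairs. Reports per-fold metrics and their
#' mean and sample (n-1) standard deviation.
#'
#' @param pairs labelled \linkS4class{PairList}.
#' @param sequences named \code{AAStringSet}.
#' @param netcfg a \linkS4class{NetworkConfig}.
#' @param traincfg a \linkS4class{TrainConfig}; its \code{folds} and
#'   \code{seed} drive the split, per-fold training seeds are derived.
#' @param verbose log progress.
#' @return list with \code{perFold} (data.frame, one row per fold),
#'   \code{summary} (data.frame with mean and sd rows) and
#'   \code{folds} (the index split).
#' @export
crossValidate <- function(pairs, sequences, netcfg,
                          traincfg = trainConfig(), verbose = FALSE) {
  k <- traincfg@folds
  seeds <- deriveSeeds(traincfg@seed, k + 1L)
  folds <- kfoldSplit(pairs, k = k, seed = seeds[k + 1L])
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- folds[[f]]
    trainPairs <- pairs[-testIdx]
    ds <- buildDataset(trainPairs, sequences, lmax = netcfg@lmax,
                       singles = TRUE, seed = seeds[f])
    tc <- traincfg
    tc@seed <- seeds[f]
    fit <- trainNetwork(ds, netcfg, tc, verbose = verbose)
    ev <- evaluatePairs(pairs[testIdx], sequences, fit$params)
    rep <- metricsReport(confusionCounts(ev$call, ev$label),
                         scores = ev$p_interacting, labels = ev$label)
    rows[[f]] <- data.frame(fold = f, as.data.frame(rep))
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.4f", f, k,
                      rep$accuracy))
  }
  perFold <- do.call(rbind, rows)
  mcols <- setdiff(names(perFold), "fold")
  summary <- data.frame(
    statistic = c("mean", "sd"),
    rbind(vapply(perFold[mcols], mean, 1),
          vapply(perFold[mcols], stats::sd, 1)))
  names(summary)[-1] <- mcols
  list(perFold = perFold, summary = summary, folds = folds)
}
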