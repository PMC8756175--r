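#' Construct a TrainConfig
#'
#' Optimization settings. The AMSGrad step size and decay rates default
#' to lr = 0.001, beta1 = 0.9, beta2 = 0.999; batch size 32 and 30
#' epochs are this package's documented defaults.
#'
#' @param lr learning rate.
#' @param beta1,beta2 first/second-moment exponential decay rates.
#' @param batchSize examples per minibatch.
#' @param epochs passes over the training data.
#' @param seed integer seed driving initialization, per-epoch shuffling
#'   and dropout.
#' @param folds default cross-validation fold count.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                        batchSize = 32L, epochs = 30L, seed = 1L,
                        folds = 5L) {
  new("TrainConfig", lr = lr, beta1 = beta1, beta2 = beta2,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), folds = as.integer(folds))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr=%g beta1=%g beta2=%g batch=%d epochs=%d seed=%d folds=%d\n",
    object@lr, object@beta1, object@beta2, object@batchSize,
    object@epochs, object@seed, object@folds))
})

#' Cross-entropy loss
#'
#' \code{-sum(y * log(c))} with probabilities clipped at 1e-12 before
#' the logarithm. For a batch (both arguments matrices, one example per
#' row) the mean over examples is returned, matching the 1/Z batch
#' normalization of the training objective.
#'
#' @param c probability vector on the simplex, or a matrix of row
#'   vectors.
#' @param y one-hot vector, or a matrix of one-hot rows.
#' @return nonnegative scalar.
#' @examples
#' crossEntropy(rep(1/3, 3), c(1, 0, 0))  # log(3)
#' @export
crossEntropy <- function(c, y) {
  if (is.matrix(c) || is.matrix(y)) {
    c <- rbind(c); y <- rbind(y)
    if (!all(dim(c) == dim(y))) stopf("c and y must have matching shape")
    return(mean(-rowSums(y * log(pmax(c, 1e-12)))))
  }
  if (length(c) != length(y)) stopf("c and y must have matching length")
  -sum(y * log(pmax(c, 1e-12)))
}

# Glorot (Xavier) uniform draw: U(-a, a), a = sqrt(6 / (fanIn + fanOut))
glorotUniform <- function(nrow, ncol, fanIn, fanOut) {
  a <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

#' Initialize network weights (Glorot uniform)
#'
#' Every weight array is drawn from U(-a, a) with
#' a = sqrt(6 / (fan_in + fan_out)). Fan conventions: for \code{We}
#' (23 x d) and the dense matrices, fan_in = rows and fan_out = columns;
#' for a kernel bank of M kernels of shape l x d, fan_in = l*d and
#' fan_out = M. The mask row of \code{We} is zeroed after sampling and
#' stays zero throughout training.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed integer seed; same seed, same weights, bit for bit.
#' @return a \linkS4class{NetworkParams}.
#' @export
initParams <- function(config, seed = 1L) {
  f <- config@filters
  withSeed(seed, {
    We <- glorotUniform(23L, config@d, 23L, config@d)
    We[23L, ] <- 0
    kernels <- lapply(seq_len(nrow(f)), function(n)
      glorotUniform(f$l[n] * config@d, f$M[n], f$l[n] * config@d, f$M[n]))
    P <- sum(f$M)
    Wf1 <- glorotUniform(P, config@f1, P, config@f1)
    Wf2 <- glorotUniform(config@f1, 3L, config@f1, 3L)
    new("NetworkParams", We = We, kernels = kernels, Wf1 = Wf1,
        Wf2 = Wf2, config = config)
  })
}

#' Single-protein training cases
#'
#' One ternary training example per unique sequence: the encoded
#' sequence paired with a fully-masked (blank) partner under the
#' \code{single_protein} label. Which Siamese slot holds the masked
#' partner alternates over a seeded random start so both inputs see
#' masked partners. These cases are used for training only, never for
#' evaluation.
#'
#' @param sequences named \code{AAStringSet} or named character vector;
#'   duplicated residue strings collapse to one case (the first id
#'   wins).
#' @param lmax encoding length.
#' @param seed integer seed for the slot alternation.
#' @param alphabet residue alphabet.
#' @return list of \linkS4class{LabeledPair}.
#' @export
makeSingleProteinCases <- function(sequences, lmax = 1500L, seed = 1L,
                                   alphabet = trioAlphabet()) {
  seqChar <- as.character(sequences)
  uniq <- seqChar[!duplicated(seqChar)]
  if (length(uniq) == 0L) return(list())
  blank <- encodeProtein("", lmax = lmax, alphabet = alphabet)
  maskFirst <- withSeed(seed,
    (sample.int(2L, 1L) + seq_along(uniq)) %% 2L == 0L)
  y <- c(0, 0, 1)
  lapply(seq_along(uniq), function(i) {
    enc <- encodeProtein(uniq[[i]], lmax = lmax, alphabet = alphabet)
    if (maskFirst[i]) new("LabeledPair", encA = blank, encB = enc, y = y)
    else new("LabeledPair", encA = enc, encB = blank, y = y)
  })
}

#' Build a training set of encoded labelled pairs
#'
#' Encodes every referenced sequence once, emits one
#' \linkS4class{LabeledPair} per entry of \code{pairs}, and (by
#' default) appends the single-protein cases derived from the unique
#' sequences referenced by the pair list.
#'
#' @param pairs labelled \linkS4class{PairList} (classes interacting /
#'   negative).
#' @param sequences named \code{AAStringSet} or named character vector.
#' @param lmax encoding length.
#' @param singles include single-protein augmentation cases.
#' @param seed seed for the single-case slot alternation.
#' @param alphabet residue alphabet.
#' @return list of \linkS4class{LabeledPair}.
#' @export
buildDataset <- function(pairs, sequences, lmax = 1500L, singles = TRUE,
                         seed = 1L, alphabet = trioAlphabet()) {
  e <- pairFrame(pairs)
  if (any(is.na(e$label))) stopf("training pairs must be labelled")
  seqChar <- as.character(sequences)
  names(seqChar) <- names(sequences)
  used <- unique(c(e$idA, e$idB))
  enc <- lapply(seqChar[used], encodeProtein, lmax = lmax,
                alphabet = alphabet)
  ymat <- diag(3)
  classIdx <- match(e$label, tripartiteClasses())
  ds <- lapply(seq_len(nrow(e)), function(i)
    new("LabeledPair", encA = enc[[e$idA[i]]], encB = enc[[e$idB[i]]],
        y = ymat[classIdx[i], ]))
  if (singles)
    ds <- c(ds, makeSingleProteinCases(seqChar[used], lmax = lmax,
                                       seed = seed, alphabet = alphabet))
  ds
}

# ---- AMSGrad ----------------------------------------------------------

amsgradInit <- function(arrays) {
  list(m = lapply(arrays, function(a) a * 0),
       v = lapply(arrays, function(a) a * 0),
       vhat = lapply(arrays, function(a) a * 0),
       t = 0L)
}

# One AMSGrad step (Keras semantics): m,v are exponential moving
# averages; vhat is the running elementwise max of v; the update uses
# the bias-corrected step size lr * sqrt(1-beta2^t) / (1-beta1^t).
amsgradStep <- function(state, arrays, grads, lr, beta1, beta2,
                        eps = 1e-7) {
  state$t <- state$t + 1L
  lrt <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (nm in names(arrays)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
    arrays[[nm]] <- arrays[[nm]] -
      lrt * state$m[[nm]] / (sqrt(state$vhat[[nm]]) + eps)
  }
  list(state = state, arrays = arrays)
}

# ---- training loop ----------------------------------------------------

#' Train the network by AMSGrad on mean batch cross-entropy
#'
#' Initializes weights with \code{\link{initParams}} (unless
#' \code{params} is supplied), then runs minibatch AMSGrad on the mean
#' cross-entropy of shuffled batches for the configured number of
#' epochs. The mask row of the embedding matrix is held at zero after
#' every update. Fully deterministic given the seed in
#' \code{traincfg}.
#'
#' @param dataset list of \linkS4class{LabeledPair} (see
#'   \code{\link{buildDataset}}).
#' @param netcfg a \linkS4class{NetworkConfig}.
#' @param traincfg a \linkS4class{TrainConfig}.
#' @param params optional starting \linkS4class{NetworkParams}.
#' @param verbose log per-epoch mean loss to stderr.
#' @return list with \code{params} (trained
#'   \linkS4class{NetworkParams}) and \code{history} (numeric vector of
#'   per-epoch mean losses).
#' @export
trainNetwork <- function(dataset, netcfg, traincfg = trainConfig(),
                         params = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stopf("empty training set")
  seeds <- deriveSeeds(traincfg@seed, 2L)
  if (is.null(params)) params <- initParams(netcfg, seed = seeds[1L])
  arrays <- paramArrays(params)
  state <- amsgradInit(arrays)
  history <- numeric(traincfg@epochs)
  nEx <- length(dataset)
  withSeed(seeds[2L], {
    for (epoch in seq_len(traincfg@epochs)) {
      ord <- sample.int(nEx)
      starts <- seq.int(1L, nEx, by = traincfg@batchSize)
      epochLoss <- 0
      for (b in seq_along(starts)) {
        take <- ord[starts[b]:min(starts[b] + traincfg@batchSize - 1L, nEx)]
        gsum <- NULL
        bloss <- 0
        for (i in take) {
          ex <- dataset[[i]]
          fw <- pairForward(ex@encA, ex@encB, params, training = TRUE)
          bloss <- bloss + crossEntropy(fw$p, ex@y)
          g <- backwardPair(fw, ex@y, params)
          gsum <- if (is.null(gsum)) g
                  else mapply(`+`, gsum, g, SIMPLIFY = FALSE)
        }
        Z <- length(take)
        if (!is.finite(bloss))
          stopf("non-finite loss at epoch %d, batch %d", epoch, b)
        gmean <- lapply(gsum, `/`, Z)
        step <- amsgradStep(state, arrays, gmean, traincfg@lr,
                            traincfg@beta1, traincfg@beta2)
        state <- step$state
        arrays <- step$arrays
        arrays$We[23L, ] <- 0            # keep mask embedding at zero
        params <- paramsFromArrays(arrays, netcfg)
        epochLoss <- epochLoss + bloss
      }
      history[epoch] <- epochLoss / nEx
      if (verbose)
        message(sprintf("epoch %d/%d: mean loss %.5f", epoch,
                        traincfg@epochs, history[epoch]))
    }
  })
  list(params = params, history = history)
}

#' Stratified k-fold split
#'
#' Partitions the pair list into k folds whose sizes differ by at most
#' one, stratified by class label (each class is split as evenly as the
#' arithmetic allows). Seeded and deterministic.
#'
#' @param pairs a labelled \linkS4class{PairList}.
#' @param k number of folds (>= 2, <= number of pairs).
#' @param seed integer seed.
#' @return list of k integer index vectors into \code{pairs}.
#' @export
kfoldSplit <- function(pairs, k = 5L, seed = 1L) {
  k <- as.integer(k)
  n <- length(pairs)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k = %d exceeds the number of pairs (%d)", k, n)
  labels <- pairLabels(pairs)
  labels[is.na(labels)] <- "unlabelled"
  folds <- vector("list", k)
  withSeed(seed, {
    # round-robin within each class over a random order; rotate the
    # starting fold per class so fold sizes stay balanced overall
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[assign == f])
      offset <- (offset + length(idx)) %% k
    }
  })
  lapply(folds, sort)
}
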