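#' @import methods
NULL

#' EncodedProtein: one-hot sequence matrix with mask channel
#'
#' A protein sequence encoded as a binary matrix \code{X} of shape
#' \code{Lmax x 23}: one column per letter of the 22-letter amino-acid
#' alphabet (see \code{\link{trioAlphabet}}) plus a 23rd mask column.
#' Every row is one-hot; row i carries a 1 in the mask column exactly when
#' the mask bit \code{B[i]} is TRUE.  Padding beyond the sequence, whole
#' sequences (single-protein cases) and single occluded residues are all
#' expressed through the same mask channel.
#'
#' @slot X numeric matrix, \code{Lmax x 23}, one-hot rows.
#' @slot B logical vector of length \code{Lmax}; TRUE = masked.
#' @slot trueLength integer; length of the represented sequence (the
#'   non-padding region). Zero for the empty / fully-masked encoding.
#' @slot alphabet character vector of the 22 residue letters, in column
#'   order; column 23 is always the mask channel.
#' @seealso \code{\link{encodeProtein}}, \code{\link{maskPositions}}
#' @export
setClass("EncodedProtein",
  representation(X = "matrix", B = "logical", trueLength = "integer",
                 alphabet = "character"))

setValidity("EncodedProtein", function(object) {
  msg <- character()
  if (length(object@alphabet) != 22L)
    msg <- c(msg, "alphabet must have exactly 22 letters")
  if (ncol(object@X) != 23L)
    msg <- c(msg, "X must have 23 columns (22 residues + mask)")
  if (length(object@B) != nrow(object@X))
    msg <- c(msg, "length(B) must equal nrow(X)")
  rs <- rowSums(object@X)
  if (nrow(object@X) > 0L && any(abs(rs - 1) > 0))
    msg <- c(msg, "every row of X must sum to exactly 1")
  if (any(object@X[, 23L] != as.numeric(object@B)))
    msg <- c(msg, "mask column of X must agree with B")
  if (object@trueLength < 0L || object@trueLength > nrow(object@X))
    msg <- c(msg, "trueLength out of range")
  if (object@trueLength < nrow(object@X) &&
      !all(object@B[seq.int(object@trueLength + 1L, nrow(object@X))]))
    msg <- c(msg, "padding rows beyond trueLength must be masked")
  if (length(msg)) msg else TRUE
})

#' PairList: labelled (or unlabelled) protein pairs
#'
#' Holds an ordered table of protein-identifier pairs with an optional
#' ternary class label, one of \code{"interacting"}, \code{"negative"},
#' \code{"single_protein"} (or \code{NA} for prediction input).
#'
#' @slot entries data.frame with columns \code{idA}, \code{idB},
#'   \code{label}.
#' @export
setClass("PairList", representation(entries = "data.frame"))

setValidity("PairList", function(object) {
  e <- object@entries
  if (!all(c("idA", "idB", "label") %in% names(e)))
    return("entries must have columns idA, idB, label")
  bad <- !is.na(e$label) & !e$label %in% tripartiteClasses()
  if (any(bad))
    return(sprintf("illegal label(s): %s",
                   paste(unique(e$label[bad]), collapse = ", ")))
  TRUE
})

#' NetworkConfig: architecture hyperparameters
#'
#' @slot d integer; embedding dimension.
#' @slot filters data.frame with one row per parallel convolution filter and
#'   columns \code{l} (window length), \code{s} (stride), \code{M} (number of
#'   kernels).
#' @slot f1 integer; width of the first dense layer.
#' @slot dropoutRate numeric in [0, 1); dropout after the first dense
#'   activation (training only).
#' @slot lmax integer; fixed encoded sequence length.
#' @slot finalRelu logical; apply ReLU to the second dense output
#'   before softmax. FALSE (default) feeds the linear logits to
#'   softmax; TRUE rectifies them first, which is usable for inference
#'   but makes training stall once all logits saturate at zero.
#' @export
setClass("NetworkConfig",
  representation(d = "integer", filters = "data.frame", f1 = "integer",
                 dropoutRate = "numeric", lmax = "integer",
                 finalRelu = "logical"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  f <- object@filters
  if (!all(c("l", "s", "M") %in% names(f)) || nrow(f) < 1L)
    msg <- c(msg, "filters needs >=1 row with columns l, s, M")
  else {
    if (any(f$l < 1L) || any(f$s < 1L) || any(f$M < 1L))
      msg <- c(msg, "all of l, s, M must be >= 1")
    if (any(f$l > object@lmax))
      msg <- c(msg, "window length l exceeds lmax")
  }
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (object@f1 < 1L) msg <- c(msg, "f1 must be >= 1")
  if (object@lmax < 1L) msg <- c(msg, "lmax must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' NetworkParams: all trainable weights
#'
#' Weight container for one network: the 23 x d embedding matrix \code{We}
#' (whose mask row, row 23, is pinned at zero and never updated), one
#' kernel matrix per parallel filter (kernels stored column-wise, each
#' column the l x d kernel flattened column-major), and the two dense
#' matrices.
#'
#' @slot We numeric matrix 23 x d.
#' @slot kernels list of numeric matrices; element n has shape
#'   \code{(l_n * d) x M_n}.
#' @slot Wf1 numeric matrix \code{sum(M) x f1}.
#' @slot Wf2 numeric matrix \code{f1 x 3}.
#' @slot config the owning \code{NetworkConfig}.
#' @export
setClass("NetworkParams",
  representation(We = "matrix", kernels = "list", Wf1 = "matrix",
                 Wf2 = "matrix", config = "NetworkConfig"))

setValidity("NetworkParams", function(object) {
  cfg <- object@config
  msg <- character()
  if (!identical(dim(object@We), c(23L, cfg@d)))
    msg <- c(msg, sprintf("We must be 23 x %d", cfg@d))
  else if (any(object@We[23L, ] != 0))
    msg <- c(msg, "mask row of We (row 23) must be identically zero")
  f <- cfg@filters
  if (length(object@kernels) != nrow(f))
    msg <- c(msg, "one kernel matrix per filter required")
  else for (n in seq_len(nrow(f))) {
    want <- c(f$l[n] * cfg@d, f$M[n])
    if (!identical(dim(object@kernels[[n]]), as.integer(want)))
      msg <- c(msg, sprintf("kernel matrix %d must be %d x %d", n,
                            want[1], want[2]))
  }
  P <- sum(f$M)
  if (!identical(dim(object@Wf1), as.integer(c(P, cfg@f1))))
    msg <- c(msg, sprintf("Wf1 must be %d x %d", P, cfg@f1))
  if (!identical(dim(object@Wf2), as.integer(c(cfg@f1, 3L))))
    msg <- c(msg, sprintf("Wf2 must be %d x 3", cfg@f1))
  if (length(msg)) msg else TRUE
})

#' PredictionResult: ternary class probabilities for one pair
#'
#' @slot probs named numeric vector of length 3 (classes
#'   \code{interacting}, \code{negative}, \code{single_protein}); lies on
#'   the probability simplex.
#' @export
setClass("PredictionResult", representation(probs = "numeric"))

setValidity("PredictionResult", function(object) {
  p <- object@probs
  if (length(p) != 3L) return("probs must have length 3")
  if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0,1]")
  if (abs(sum(p) - 1) > 1e-6) return("probabilities must sum to 1 (1e-6)")
  TRUE
})

#' LabeledPair: one training example
#'
#' Two encoded proteins and a one-hot ternary label. For the
#' single-protein class exactly one of the two encodings is fully masked.
#'
#' @slot encA,encB \code{EncodedProtein}.
#' @slot y numeric one-hot vector of length 3 in class order
#'   (interacting, negative, single_protein).
#' @export
setClass("LabeledPair",
  representation(encA = "EncodedProtein", encB = "EncodedProtein",
                 y = "numeric"))

setValidity("LabeledPair", function(object) {
  y <- object@y
  ok <- length(y) == 3L && all(y %in% c(0, 1)) && sum(y) == 1
  if (!ok) return("y must be a one-hot vector of length 3")
  if (y[3L] == 1) {
    fmA <- isFullyMasked(object@encA)
    fmB <- isFullyMasked(object@encB)
    if (sum(fmA, fmB) != 1L)
      return("single_protein examples need exactly one fully-masked member")
  }
  TRUE
})

#' TrainConfig: optimization settings
#'
#' @slot lr numeric learning rate (AMSGrad alpha).
#' @slot beta1,beta2 numeric exponential decay rates of the first and
#'   second moment estimates.
#' @slot batchSize integer examples per minibatch.
#' @slot epochs integer passes over the data.
#' @slot seed integer; seeds initialization, shuffling and dropout.
#' @slot folds integer; default number of cross-validation folds.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer",
                 folds = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
  if (object@beta1 < 0 || object@beta1 >= 1) msg <- c(msg, "beta1 in [0,1)")
  if (object@beta2 < 0 || object@beta2 >= 1) msg <- c(msg, "beta2 in [0,1)")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' SynthSpec: synthetic motif-planted benchmark specification
#'
#' Describes a ground-truthed synthetic dataset in which interaction is
#' determined by a pair of planted motifs: a pair interacts iff member A
#' carries \code{motifA} and member B carries \code{motifB}.
#'
#' @slot nPairs integer; pairs generated per class.
#' @slot lenRange integer(2); min/max sequence length.
#' @slot motifA,motifB character; planted residue motifs.
#' @slot background numeric(20) residue sampling weights over the 20
#'   standard amino acids (uniform by default).
#' @slot labelNoise numeric in [0, 0.5); fraction of labels flipped.
#' @slot seed integer random seed.
#' @export
setClass("SynthSpec",
  representation(nPairs = "integer", lenRange = "integer",
                 motifA = "character", motifB = "character",
                 background = "numeric", labelNoise = "numeric",
                 seed = "integer"))

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (object@nPairs < 1L) msg <- c(msg, "nPairs must be >= 1")
  if (length(object@lenRange) != 2L || object@lenRange[1] > object@lenRange[2]
      || object@lenRange[1] < 1L)
    msg <- c(msg, "lenRange must be increasing positive integer(2)")
  if (max(nchar(object@motifA), nchar(object@motifB)) >= object@lenRange[1])
    msg <- c(msg, "motifs must be shorter than the minimum length")
  if (object@labelNoise < 0 || object@labelNoise >= 0.5)
    msg <- c(msg, "labelNoise must lie in [0, 0.5)")
  if (length(object@background) != 20L || any(object@background < 0) ||
      sum(object@background) <= 0)
    msg <- c(msg, "background must be 20 nonnegative weights")
  if (length(msg)) msg else TRUE
})

#' ImportanceProfile: per-residue occlusion scores
#'
#' Occlusion importance of each residue of one protein with respect to a
#' fixed partner: score[i] = P_neg with residue i masked minus the
#' baseline P_neg. Positive scores mean the residue's presence supports
#' the interaction call. Positions are reported 1-based.
#'
#' @slot proteinId,partnerId character identifiers.
#' @slot residues character; the scored protein's sequence.
#' @slot scores numeric vector, one score per residue, each in [-1, 1].
#' @export
setClass("ImportanceProfile",
  representation(proteinId = "character", partnerId = "character",
                 residues = "character", scores = "numeric"))

setValidity("ImportanceProfile", function(object) {
  if (length(object@scores) != nchar(object@residues))
    return("one score per residue required")
  if (any(object@scores < -1 | object@scores > 1))
    return("scores must lie in [-1, 1]")
  TRUE
})
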