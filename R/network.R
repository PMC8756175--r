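#' Construct a NetworkConfig
#'
#' Architecture hyperparameters of the Siamese multi-parallel
#' convolutional network. Defaults are this package's documented
#' choices: embedding dimension 12; three parallel filters with windows
#' 2, 6 and 12 (stride 1, 64 kernels each); first dense width 128;
#' dropout 0.2.
#'
#' @param d embedding dimension.
#' @param filters list of \code{c(l, s, M)} triples (window length,
#'   stride, kernel count), one per parallel filter.
#' @param f1 first dense-layer width.
#' @param dropoutRate dropout after the first dense activation, applied
#'   during training only.
#' @param lmax fixed encoded sequence length.
#' @param finalRelu apply ReLU to the final logits before softmax.
#'   Default FALSE (linear logits): rectifying the logits makes the
#'   uniform prediction an inescapable stationary point — once every
#'   logit is clamped at zero for every example the gradient vanishes
#'   identically and training stalls at loss log(3) (see the methods
#'   vignette). The rectified head remains available for forward-pass
#'   use.
#' @return a \linkS4class{NetworkConfig}.
#' @examples
#' networkConfig(d = 4, filters = list(c(2, 1, 8)), f1 = 16, lmax = 50)
#' @export
networkConfig <- function(d = 12L,
                          filters = list(c(2L, 1L, 64L), c(6L, 1L, 64L),
                                         c(12L, 1L, 64L)),
                          f1 = 128L, dropoutRate = 0.2, lmax = 1500L,
                          finalRelu = FALSE) {
  fdf <- as.data.frame(do.call(rbind, lapply(filters, function(x) {
    stopifnot(length(x) == 3L)
    as.integer(x)
  })))
  names(fdf) <- c("l", "s", "M")
  new("NetworkConfig", d = as.integer(d), filters = fdf,
      f1 = as.integer(f1), dropoutRate = as.numeric(dropoutRate),
      lmax = as.integer(lmax), finalRelu = isTRUE(finalRelu))
}

setMethod("show", "NetworkConfig", function(object) {
  f <- object@filters
  cat(sprintf(
    "NetworkConfig: d=%d, lmax=%d, f1=%d, dropout=%.2f, finalRelu=%s\n",
    object@d, object@lmax, object@f1, object@dropoutRate,
    object@finalRelu))
  cat(sprintf("  %d parallel filters: %s\n", nrow(f),
              paste(sprintf("(l=%d,s=%d,M=%d)", f$l, f$s, f$M),
                    collapse = " ")))
})

#' @rdname NetworkParams-class
#' @export
setMethod("netConfig", "NetworkParams", function(x) x@config)

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams:\n")
  show(object@config)
  cat(sprintf("  %d trainable weights\n",
              sum(vapply(paramArrays(object), length, 1L)) -
                object@config@d))  # mask row of We is pinned
})

# named list view of all weight arrays (mask row of We included as-is)
paramArrays <- function(params) {
  c(list(We = params@We),
    structure(params@kernels,
              names = sprintf("kernel%d", seq_along(params@kernels))),
    list(Wf1 = params@Wf1, Wf2 = params@Wf2))
}

# rebuild a NetworkParams from the list view
paramsFromArrays <- function(arrays, config) {
  nf <- nrow(config@filters)
  new("NetworkParams", We = arrays$We,
      kernels = unname(arrays[sprintf("kernel%d", seq_len(nf))]),
      Wf1 = arrays$Wf1, Wf2 = arrays$Wf2, config = config)
}

# cached window indices for one (lmax, l, s, d) combination:
#   rows: K x l matrix of sequence positions per window
#   lin:  K x (l*d) linear indices into the column-major Lmax x d E
.winCache <- new.env(parent = emptyenv())

windowIndex <- function(lmax, l, s, d) {
  key <- paste(lmax, l, s, d, sep = "_")
  hit <- .winCache[[key]]
  if (!is.null(hit)) return(hit)
  K <- (lmax - l) %/% s + 1L
  rows <- matrix(rep((seq_len(K) - 1L) * s, l) +
                 rep(seq_len(l), each = K), K, l)
  lin <- do.call(cbind, lapply(seq_len(d) - 1L, function(j) rows + j * lmax))
  res <- list(K = K, rows = rows, lin = lin)
  .winCache[[key]] <- res
  res
}

#' Embed an encoded protein
#'
#' Computes the dense representation \code{E = X We}. Because the mask
#' row of \code{We} is pinned at zero, every masked position (padding,
#' occlusion, fully-masked partner) embeds to the zero vector and hence
#' contributes exactly nothing downstream.
#'
#' @param enc an \linkS4class{EncodedProtein}.
#' @param params a \linkS4class{NetworkParams}.
#' @return numeric matrix \code{lmax x d}.
#' @export
embedProtein <- function(enc, params) {
  if (nrow(enc@X) != params@config@lmax)
    stopf("encoding length %d does not match config lmax %d",
          nrow(enc@X), params@config@lmax)
  enc@X %*% params@We
}

#' One parallel convolution filter (no bias)
#'
#' Strided valid convolution of the embedded matrix with a bank of
#' kernels: \code{T[k, m] = sum_{i,j} kernel_m[i, j] * E[(k-1)s + i, j]}.
#' No bias is added and no zero-padding is used, so windows over
#' masked-only regions give exactly zero.
#'
#' @param E numeric matrix \code{L x d}.
#' @param kernelMat numeric matrix \code{(l*d) x M}; column m is the
#'   \code{l x d} kernel flattened column-major.
#' @param l window length; \code{s} stride.
#' @param s stride.
#' @return numeric matrix \code{K x M} with \code{K = floor((L-l)/s)+1}.
#' @export
convFilter <- function(E, kernelMat, l, s) {
  L <- nrow(E)
  d <- ncol(E)
  if (l > L) stopf("window length %d exceeds sequence length %d", l, L)
  if (nrow(kernelMat) != l * d)
    stopf("kernel matrix must have l*d = %d rows", l * d)
  idx <- windowIndex(L, as.integer(l), as.integer(s), d)
  WinE <- E[idx$lin]
  dim(WinE) <- c(idx$K, l * d)
  WinE %*% kernelMat
}

#' ReLU + global max pooling
#'
#' \code{h[m] = max_k max(0, T[k, m])}: the strongest nonnegative
#' activation of each kernel over all windows. Always >= 0.
#'
#' @param T numeric matrix \code{K x M} of raw convolution outputs.
#' @return numeric vector of length M.
#' @export
reluMaxPool <- function(T) {
  if (!is.matrix(T) || nrow(T) < 1L || ncol(T) < 1L)
    stopf("T must be a nonempty K x M matrix")
  pmax(colMaxFirst(T)$max, 0)
}

# column maxima with first-occurrence argmax (tie-break: lowest window)
colMaxFirst <- function(T) {
  arg <- max.col(t(T), ties.method = "first")
  list(max = T[cbind(arg, seq_len(ncol(T)))], arg = arg)
}

# forward through one Siamese branch; cache = TRUE retains what the
# backward pass needs (embeddings, argmax windows, their indices)
forwardBranch <- function(enc, params, cache = FALSE) {
  cfg <- params@config
  f <- cfg@filters
  P <- sum(f$M)
  if (isFullyMasked(enc)) {
    H <- numeric(P)
    return(if (cache) list(H = H, masked = TRUE) else H)
  }
  E <- embedProtein(enc, params)
  Eflat <- as.vector(E)
  Hs <- vector("list", nrow(f))
  info <- if (cache) vector("list", nrow(f))
  for (n in seq_len(nrow(f))) {
    idx <- windowIndex(cfg@lmax, f$l[n], f$s[n], cfg@d)
    WinE <- Eflat[idx$lin]
    dim(WinE) <- dim(idx$lin)
    T <- WinE %*% params@kernels[[n]]
    cm <- colMaxFirst(T)
    Hs[[n]] <- pmax(cm$max, 0)
    if (cache) {
      act <- cm$max > 0
      info[[n]] <- list(
        active = act,
        win = WinE[cm$arg, , drop = FALSE],      # M x (l*d)
        lin = idx$lin[cm$arg, , drop = FALSE])   # M x (l*d)
    }
  }
  H <- unlist(Hs, use.names = FALSE)
  if (cache) list(H = H, masked = FALSE, enc = enc, info = info) else H
}

#' Pooled representation of one protein
#'
#' Runs one Siamese branch: embedding, all parallel convolution filters,
#' ReLU, global max pooling and concatenation in filter order. A fully
#' masked protein yields exactly the zero vector (zero embeddings,
#' bias-free convolution, ReLU floor), which is what makes the additive
#' merge reduce to the partner alone in single-protein cases.
#'
#' @param enc an \linkS4class{EncodedProtein}.
#' @param params a \linkS4class{NetworkParams}.
#' @return numeric vector \code{Hconc} of length \code{sum(M_n)};
#'   componentwise >= 0.
#' @export
forwardSingle <- function(enc, params) {
  forwardBranch(enc, params, cache = FALSE)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# dense head: merged vector -> class probabilities (+ cache)
forwardHead <- function(Hm, params, training = FALSE) {
  cfg <- params@config
  z1 <- drop(Hm %*% params@Wf1)
  a1 <- pmax(z1, 0)
  dropMask <- NULL
  a1d <- a1
  if (training && cfg@dropoutRate > 0) {
    dropMask <- (stats::runif(length(a1)) >= cfg@dropoutRate) /
      (1 - cfg@dropoutRate)
    a1d <- a1 * dropMask
  }
  z2 <- drop(a1d %*% params@Wf2)
  Fv <- if (cfg@finalRelu) pmax(z2, 0) else z2
  list(p = softmax(Fv), z1 = z1, a1d = a1d, z2 = z2,
       dropMask = dropMask, Hm = Hm)
}

#' Predict the ternary class of a protein pair
#'
#' Full Siamese forward pass: both branches share all weights, their
#' pooled representations are merged by element-wise addition (so a
#' fully-masked partner contributes nothing rather than annihilating the
#' merge), passed through two dense layers and a 3-class softmax. In
#' inference mode (default) dropout is disabled and the computation is
#' fully deterministic; by symmetry of the merge,
#' \code{predictPair(A, B)} and \code{predictPair(B, A)} are
#' bit-identical.
#'
#' @param encA,encB \linkS4class{EncodedProtein}s of matching lmax.
#' @param params a \linkS4class{NetworkParams}.
#' @param inference disable dropout (default TRUE).
#' @return a \linkS4class{PredictionResult}.
#' @export
predictPair <- function(encA, encB, params, inference = TRUE) {
  HA <- forwardBranch(encA, params)
  HB <- forwardBranch(encB, params)
  head <- forwardHead(HA + HB, params, training = !inference)
  newPrediction(head$p)
}

newPrediction <- function(p) {
  names(p) <- tripartiteClasses()
  new("PredictionResult", probs = p)
}

#' @rdname PredictionResult-class
#' @export
setMethod("probs", "PredictionResult", function(x) x@probs)

#' @rdname PredictionResult-class
#' @export
setMethod("pInteract", "PredictionResult", function(x) x@probs[["interacting"]])

#' @rdname PredictionResult-class
#' @export
setMethod("pNegative", "PredictionResult", function(x) x@probs[["negative"]])

#' @rdname PredictionResult-class
#' @export
setMethod("pSingle", "PredictionResult",
          function(x) x@probs[["single_protein"]])

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf(
    "PredictionResult: P(interacting)=%.4f P(negative)=%.4f P(single)=%.4f\n",
    object@probs[1], object@probs[2], object@probs[3]))
})

# full pair forward with caches for backprop
pairForward <- function(encA, encB, params, training = FALSE) {
  cA <- forwardBranch(encA, params, cache = TRUE)
  cB <- forwardBranch(encB, params, cache = TRUE)
  head <- forwardHead(cA$H + cB$H, params, training = training)
  list(branchA = cA, branchB = cB, head = head, p = head$p)
}

# loss of one pair at given params (dropout off); used by training and
# by finite-difference gradient checks
pairLoss <- function(encA, encB, y, params) {
  fw <- pairForward(encA, encB, params, training = FALSE)
  crossEntropy(fw$p, y)
}

# gradient of one branch given dH (gradient w.r.t. the pooled vector);
# returns dE-independent contributions: dWe and per-filter dKernels
backwardBranch <- function(br, dH, params) {
  cfg <- params@config
  f <- cfg@filters
  dKernels <- vector("list", nrow(f))
  if (br$masked) {
    for (n in seq_len(nrow(f)))
      dKernels[[n]] <- matrix(0, f$l[n] * cfg@d, f$M[n])
    return(list(dWe = matrix(0, 23L, cfg@d), dKernels = dKernels))
  }
  dEflat <- numeric(cfg@lmax * cfg@d)
  off <- 0L
  for (n in seq_len(nrow(f))) {
    M <- f$M[n]
    dHn <- dH[off + seq_len(M)]
    off <- off + M
    inf <- br$info[[n]]
    dK <- matrix(0, f$l[n] * cfg@d, M)
    act <- inf$active & dHn != 0
    if (any(act)) {
      dK[, act] <- t(inf$win[act, , drop = FALSE] * dHn[act])
      km <- params@kernels[[n]]
      for (m in which(act)) {
        lin <- inf$lin[m, ]
        dEflat[lin] <- dEflat[lin] + km[, m] * dHn[m]
      }
    }
    dKernels[[n]] <- dK
  }
  dE <- matrix(dEflat, cfg@lmax, cfg@d)
  dWe <- crossprod(br$enc@X, dE)
  dWe[23L, ] <- 0                       # mask embedding row is pinned
  list(dWe = dWe, dKernels = dKernels)
}

# full backward pass for one example; returns gradients as a named
# array list matching paramArrays()
backwardPair <- function(fw, y, params) {
  cfg <- params@config
  hd <- fw$head
  dF <- hd$p - y
  dz2 <- if (cfg@finalRelu) dF * (hd$z2 > 0) else dF
  dWf2 <- outer(hd$a1d, dz2)
  da1d <- drop(params@Wf2 %*% dz2)
  da1 <- if (!is.null(hd$dropMask)) da1d * hd$dropMask else da1d
  dz1 <- da1 * (hd$z1 > 0)
  dWf1 <- outer(hd$Hm, dz1)
  dHm <- drop(params@Wf1 %*% dz1)
  gA <- backwardBranch(fw$branchA, dHm, params)
  gB <- backwardBranch(fw$branchB, dHm, params)
  grads <- list(We = gA$dWe + gB$dWe)
  for (n in seq_along(params@kernels))
    grads[[sprintf("kernel%d", n)]] <- gA$dKernels[[n]] + gB$dKernels[[n]]
  grads$Wf1 <- dWf1
  grads$Wf2 <- dWf2
  grads
}
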