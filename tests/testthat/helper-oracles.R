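# Independent brute-force oracles used to pin expected values.

# sorted multiset of k-lets of the suffix (positions 2..n)
suffixKlets <- function(x, k = 2L) {
  ch <- strsplit(substr(x, 2L, nchar(x)), "")[[1]]
  m <- length(ch)
  if (m < k) return(character(0))
  sort(vapply(seq_len(m - k + 1L), function(i)
    paste(ch[i:(i + k - 1L)], collapse = ""), ""))
}

# exhaustive enumeration of all valid shuffles: permutations of the
# suffix whose k-let multiset matches, first residue kept in place
enumValidShuffles <- function(x, k = 2L) {
  suf <- strsplit(substr(x, 2L, nchar(x)), "")[[1]]
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      out <- c(out, lapply(perms(rest), function(p) c(u, p)))
    }
    out
  }
  want <- suffixKlets(x, k)
  cand <- unique(vapply(perms(suf), paste, "", collapse = ""))
  full <- paste0(substr(x, 1L, 1L), cand)
  sort(full[vapply(full, function(s)
    identical(suffixKlets(s, k), want), TRUE)])
}

# naive triple-loop matrix product
naiveMatmul <- function(A, B) {
  C <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (l in seq_len(ncol(A)))
        C[i, j] <- C[i, j] + A[i, l] * B[l, j]
  C
}

# naive strided valid convolution with l x d kernels (list of matrices)
naiveConv <- function(E, kernelList, l, s) {
  K <- (nrow(E) - l) %/% s + 1L
  T <- matrix(0, K, length(kernelList))
  for (m in seq_along(kernelList)) {
    v <- kernelList[[m]]
    for (k in seq_len(K))
      for (i in seq_len(l))
        for (j in seq_len(ncol(E)))
          T[k, m] <- T[k, m] + v[i, j] * E[(k - 1L) * s + i, j]
  }
  T
}

# kernel matrix column -> l x d kernel
kernelAsMatrix <- function(kernelMat, m, l, d) {
  matrix(kernelMat[, m], l, d)
}

# independent metric formulas straight from the definitions
refMetrics <- function(TP, FP, TN, FN) {
  list(accuracy = (TP + TN) / (TP + FP + TN + FN),
       precision = TP / (TP + FP),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       f1 = 2 * TP / (2 * TP + FP + FN),
       mcc = (TP * TN - FP * FN) /
         sqrt((TP + FP)) / sqrt((TP + FN)) / sqrt((TN + FP)) /
         sqrt((TN + FN)))
}

# brute-force AP: precision at every positive rank, averaged
refAveragePrecision <- function(scores, isPos) {
  ord <- order(scores, decreasing = TRUE)
  hits <- isPos[ord]
  mean((cumsum(hits) / seq_along(hits))[hits])
}

# brute-force AUC over all positive/negative score pairs
refAUC <- function(scores, isPos) {
  pos <- scores[isPos]
  neg <- scores[!isPos]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

randomAASeq <- function(len) {
  paste(sample(trioAlphabet()[1:20], len, replace = TRUE), collapse = "")
}

tinyConfig <- function(lmax = 12L, d = 3L, finalRelu = FALSE,
                       dropoutRate = 0) {
  networkConfig(d = d, filters = list(c(2L, 1L, 4L), c(3L, 2L, 3L)),
                f1 = 5L, dropoutRate = dropoutRate, lmax = lmax,
                finalRelu = finalRelu)
}
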