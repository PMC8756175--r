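test_that("configuration invariants are enforced", {
  expect_error(networkConfig(filters = list(c(30, 1, 4)), lmax = 20),
               "exceeds lmax")
  expect_error(networkConfig(dropoutRate = 1), "dropoutRate")
  expect_error(networkConfig(d = 0), "d must be")
})

test_that("embedding selects We rows and zeroes masked positions", {
  cfg <- tinyConfig()
  p <- initParams(cfg, seed = 2)
  blank <- encodeProtein("", lmax = 12)
  expect_equal(embedProtein(blank, p), matrix(0, 12, 3))
  enc <- encodeProtein("KR", lmax = 12)
  E <- embedProtein(enc, p)
  expect_equal(E[1, ], p@We[match("K", trioAlphabet()), ])
  expect_equal(E[2, ], p@We[match("R", trioAlphabet()), ])
  expect_equal(E[3:12, ], matrix(0, 10, 3))
  # random one-hot X against the naive triple-loop product
  set.seed(3)
  X <- matrix(0, 12, 23)
  X[cbind(1:12, sample(1:23, 12, TRUE))] <- 1
  We <- matrix(rnorm(23 * 3), 23, 3)
  expect_lt(max(abs(X %*% We - naiveMatmul(X, We))), 1e-12)
})

test_that("convolution matches hand-computed and naive-loop oracles", {
  E <- rbind(c(1, 0), c(0, 1), c(1, 1))
  ones <- matrix(1, 4, 1)     # one 2x2 all-ones kernel
  expect_equal(convFilter(E, ones, l = 2, s = 1),
               matrix(c(2, 3), 2, 1))
  # zero input, no bias: zero output
  expect_equal(convFilter(matrix(0, 5, 2), ones, l = 2, s = 1),
               matrix(0, 4, 1))
  # frame-count arithmetic: stride 2 on L=5, l=2 -> 2 frames
  expect_equal(nrow(convFilter(matrix(0, 5, 2), ones, l = 2, s = 2)), 2L)
  expect_error(convFilter(matrix(0, 3, 2), ones, l = 4, s = 1),
               "exceeds")
  # random instances vs the naive loop, and monotone frame counts
  set.seed(8)
  lastK <- Inf
  for (s in 1:3) {
    L <- 11; d <- 4; l <- 3; M <- 5
    E <- matrix(rnorm(L * d), L, d)
    kern <- lapply(1:M, function(m) matrix(rnorm(l * d), l, d))
    kmat <- vapply(kern, as.vector, numeric(l * d))
    T <- convFilter(E, kmat, l, s)
    expect_lt(max(abs(T - naiveConv(E, kern, l, s))), 1e-10)
    expect_lte(nrow(T), lastK)
    lastK <- nrow(T)
  }
})

test_that("ReLU-max pooling takes the rectified maximum per kernel", {
  expect_equal(reluMaxPool(matrix(c(-5, -1), 2, 1)), 0)
  expect_equal(reluMaxPool(matrix(c(0.2, 3.1, 1.0), 3, 1)), 3.1)
  set.seed(9)
  T <- matrix(rnorm(40), 8, 5)
  brute <- vapply(1:5, function(m) max(c(0, T[, m])), 0)
  expect_identical(reluMaxPool(T), brute)
  expect_error(reluMaxPool(matrix(numeric(0), 0, 2)), "nonempty")
})

test_that("a fully-masked protein pools to exactly zero", {
  cfg <- tinyConfig()
  p <- initParams(cfg, seed = 5)
  H <- forwardSingle(encodeProtein("", lmax = 12), p)
  expect_identical(H, rep(0, 7))
  expect_equal(length(forwardSingle(encodeProtein("MKVED", lmax = 12), p)),
               sum(cfg@filters$M))
})

withSeedHelper <- function(seed) {
  set.seed(seed + 1000)
  randomAASeq(sample(5:12, 1))
}

test_that("pooled representations are nonnegative and reproducible", {
  cfg <- tinyConfig()
  for (seed in 1:20) {
    p <- initParams(cfg, seed = seed)
    enc <- encodeProtein(withSeedHelper(seed), p@config@lmax)
    H <- forwardSingle(enc, p)
    expect_true(all(H >= 0))
    expect_identical(H, forwardSingle(enc, p))
  }
})

test_that("forward pass agrees with an independent naive pipeline", {
  # embed -> conv -> relu/maxpool -> concat, all via naive loops
  set.seed(10)
  for (rep in 1:5) {
    cfg <- networkConfig(d = 4, filters = list(c(2, 1, 3), c(5, 2, 2)),
                         f1 = 6, lmax = 30, dropoutRate = 0)
    p <- initParams(cfg, seed = rep * 7)
    x <- randomAASeq(sample(6:30, 1))
    enc <- encodeProtein(x, lmax = 30)
    Eref <- naiveMatmul(onehot(enc), p@We)
    Href <- unlist(lapply(1:2, function(n) {
      l <- cfg@filters$l[n]; s <- cfg@filters$s[n]; M <- cfg@filters$M[n]
      kern <- lapply(seq_len(M), function(m)
        kernelAsMatrix(p@kernels[[n]], m, l, 4))
      T <- naiveConv(Eref, kern, l, s)
      vapply(seq_len(M), function(m) max(c(0, T[, m])), 0)
    }))
    expect_lt(max(abs(forwardSingle(enc, p) - Href)), 1e-10)
  }
})

test_that("prediction is Siamese-symmetric, normalized and deterministic", {
  cfg <- tinyConfig()
  set.seed(11)
  for (rep in 1:25) {
    p <- initParams(cfg, seed = rep)
    a <- encodeProtein(randomAASeq(sample(4:12, 1)), 12)
    b <- encodeProtein(randomAASeq(sample(4:12, 1)), 12)
    r1 <- probs(predictPair(a, b, p))
    r2 <- probs(predictPair(b, a, p))
    expect_identical(r1, r2)
    expect_equal(sum(r1), 1, tolerance = 1e-6)
    expect_true(all(r1 >= 0 & r1 <= 1))
  }
})

test_that("zero logits give the uniform distribution", {
  for (finalRelu in c(TRUE, FALSE)) {
    cfg <- tinyConfig(finalRelu = finalRelu)
    p <- initParams(cfg, seed = 1)
    p@Wf2[] <- 0          # forces F = (0,0,0)
    pred <- predictPair(encodeProtein("MKV", 12),
                        encodeProtein("DED", 12), p)
    expect_equal(unname(probs(pred)), rep(1 / 3, 3))
  }
})

test_that("a fully-masked partner reduces the merge to one branch", {
  cfg <- tinyConfig()
  p <- initParams(cfg, seed = 13)
  a <- encodeProtein("MKVEDKRLA", 12)
  blank <- encodeProtein("", 12)
  viaPair <- probs(predictPair(a, blank, p))
  # single-input reduction: the head applied to Hconc(A) alone
  viaSingle <- TrioPPI:::forwardHead(forwardSingle(a, p), p)$p
  names(viaSingle) <- names(viaPair)
  expect_identical(viaPair, viaSingle)
})

test_that("masking changes only convolution windows that overlap it", {
  cfg <- networkConfig(d = 3, filters = list(c(3, 1, 4)), f1 = 5,
                       lmax = 15, dropoutRate = 0)
  p <- initParams(cfg, seed = 17)
  enc <- encodeProtein(randomAASeq(15), 15)
  pos <- 8L
  T0 <- convFilter(embedProtein(enc, p), p@kernels[[1]], 3, 1)
  T1 <- convFilter(embedProtein(maskPositions(enc, pos), p),
                   p@kernels[[1]], 3, 1)
  overlap <- vapply(seq_len(nrow(T0)), function(k)
    pos %in% (k:(k + 2)), TRUE)
  expect_identical(T0[!overlap, ], T1[!overlap, ])
  expect_false(isTRUE(all.equal(T0[overlap, ], T1[overlap, ])))
})

test_that("checkpoints round-trip bit-exactly and validate", {
  cfg <- tinyConfig()
  p <- initParams(cfg, seed = 21)
  f <- tempfile(fileext = ".ckpt.json")
  saveCheckpoint(p, f)
  q <- loadCheckpoint(f)
  expect_identical(TrioPPI:::paramArrays(p), TrioPPI:::paramArrays(q))
  expect_equal(q@config, cfg)
  # a corrupted shape is rejected on load
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  doc$weights$Wf2$dim <- c(2, 3)
  doc$weights$Wf2$data <- doc$weights$Wf2$data[1:6]
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(loadCheckpoint(f), "Wf2|invalid")
})
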