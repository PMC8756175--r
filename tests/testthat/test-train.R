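test_that("cross-entropy matches its closed forms", {
  expect_equal(crossEntropy(rep(1 / 3, 3), c(1, 0, 0)), log(3),
               tolerance = 1e-12)
  expect_lt(crossEntropy(c(1, 0, 0), c(1, 0, 0)), 1e-11)
  expect_error(crossEntropy(c(0.5, 0.5), c(1, 0, 0)), "matching")
  # batch mean equals the per-example loop
  set.seed(4)
  C <- t(vapply(1:10, function(i) {
    z <- runif(3); z / sum(z)
  }, numeric(3)))
  Y <- diag(3)[sample(1:3, 10, TRUE), ]
  loop <- mean(vapply(1:10, function(i)
    -sum(Y[i, ] * log(pmax(C[i, ], 1e-12))), 0))
  expect_equal(crossEntropy(C, Y), loop, tolerance = 1e-12)
})

test_that("Glorot initialization respects its support and variance", {
  # large arrays so the moment check is well powered
  cfg <- networkConfig(d = 12, filters = list(c(2, 1, 200)), f1 = 500,
                       lmax = 20)
  p <- initParams(cfg, seed = 31)
  bound <- function(fanIn, fanOut) sqrt(6 / (fanIn + fanOut))
  aWf1 <- bound(200, 500)
  expect_true(all(abs(p@Wf1) <= aWf1))
  expect_true(all(abs(p@We[1:22, ]) <= bound(23, 12)))
  expect_true(all(abs(p@kernels[[1]]) <= bound(24, 200)))
  expect_true(all(p@We[23, ] == 0))
  # empirical variance of 1e5 draws within 5% of a^2/3
  expect_lt(abs(stats::var(as.vector(p@Wf1)) / (aWf1^2 / 3) - 1), 0.05)
  expect_identical(TrioPPI:::paramArrays(p),
                   TrioPPI:::paramArrays(initParams(cfg, seed = 31)))
})

test_that("single-protein cases cover unique sequences with a blank partner", {
  seqs <- c(a = "MKV", b = "ACDEF", c = "MKV", d = "DEDKR", e = "ACDEF")
  cases <- makeSingleProteinCases(seqs, lmax = 10, seed = 3)
  expect_length(cases, 3L)     # 5 records, 3 unique strings
  slots <- vapply(cases, function(cs) {
    expect_equal(cs@y, c(0, 0, 1))
    fmA <- all(maskBits(cs@encA))
    fmB <- all(maskBits(cs@encB))
    expect_equal(fmA + fmB, 1L)
    fmA
  }, TRUE)
  expect_true(any(slots) && any(!slots))   # both slots see blanks
  expect_length(makeSingleProteinCases(character(0), lmax = 10), 0L)
})

test_that("AMSGrad reproduces hand-computed steps on a 1-parameter quadratic", {
  # minimize f(x) = x^2 / 2 from x0 = 1; g = x
  lr <- 0.1; b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  x <- list(w = matrix(1, 1, 1))
  st <- TrioPPI:::amsgradInit(x)
  # -- step 1, by hand:
  # m1 = 0.1*1 = 0.1 ; v1 = 0.001*1 = 0.001 ; vhat = 0.001
  # lr1 = 0.1*sqrt(1-0.999)/(1-0.9)
  # x1 = 1 - lr1 * 0.1/(sqrt(0.001)+eps)
  lr1 <- lr * sqrt(1 - b2) / (1 - b1)
  x1 <- 1 - lr1 * 0.1 / (sqrt(0.001) + eps)
  s1 <- TrioPPI:::amsgradStep(st, x, list(w = matrix(1, 1, 1)),
                              lr, b1, b2, eps)
  expect_equal(s1$arrays$w[1, 1], x1, tolerance = 1e-14)
  # -- step 2 with gradient g2 = x1:
  m2 <- b1 * 0.1 + (1 - b1) * x1
  v2 <- b2 * 0.001 + (1 - b2) * x1^2
  vhat2 <- max(0.001, v2)
  lr2 <- lr * sqrt(1 - b2^2) / (1 - b1^2)
  x2 <- x1 - lr2 * m2 / (sqrt(vhat2) + eps)
  s2 <- TrioPPI:::amsgradStep(s1$state, s1$arrays,
                              list(w = matrix(x1, 1, 1)), lr, b1, b2, eps)
  expect_equal(s2$arrays$w[1, 1], x2, tolerance = 1e-14)
  # second-moment maximum is non-decreasing
  expect_gte(s2$state$vhat$w[1, 1], s1$state$vhat$w[1, 1])
})

test_that("analytic gradients agree with central finite differences", {
  eA <- encodeProtein("MKVEDKRLA", lmax = 12)
  eB <- encodeProtein("DEDEADK", lmax = 12)
  for (case in list(list(seed = 4, finalRelu = TRUE),
                    list(seed = 4, finalRelu = FALSE),
                    list(seed = 9, finalRelu = TRUE))) {
    cfg <- tinyConfig(finalRelu = case$finalRelu)
    p <- initParams(cfg, seed = case$seed)
    y <- c(0, 1, 0)
    fw <- TrioPPI:::pairForward(eA, eB, p, training = FALSE)
    g <- TrioPPI:::backwardPair(fw, y, p)
    arrays <- TrioPPI:::paramArrays(p)
    h <- 1e-6
    nonzero <- 0L
    for (nm in names(arrays)) {
      a <- arrays[[nm]]
      for (i in seq_along(a)) {
        if (nm == "We" && ((i - 1) %% 23 + 1) == 23) next  # pinned row
        ap <- arrays; ap[[nm]][i] <- a[i] + h
        am <- arrays; am[[nm]][i] <- a[i] - h
        num <- (TrioPPI:::pairLoss(eA, eB, y,
                  TrioPPI:::paramsFromArrays(ap, cfg)) -
                TrioPPI:::pairLoss(eA, eB, y,
                  TrioPPI:::paramsFromArrays(am, cfg))) / (2 * h)
        ana <- g[[nm]][i]
        if (abs(num) > 1e-8 || abs(ana) > 1e-8) {
          nonzero <- nonzero + 1L
          expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4)
        }
      }
    }
    expect_gt(nonzero, 20L)   # the check exercised real gradients
  }
})

test_that("training reduces the loss on a motif dataset and is deterministic", {
  gen <- generateSynthetic(synthSpec(nPairs = 30, lenRange = c(30, 50),
                                     seed = 12))
  ds <- buildDataset(gen$pairs, gen$sequences, lmax = 50, seed = 2)
  nc <- networkConfig(d = 6, filters = list(c(2, 1, 16), c(6, 1, 16)),
                      f1 = 32, lmax = 50, dropoutRate = 0.1)
  tc <- trainConfig(epochs = 6, batchSize = 16, seed = 21)
  fit <- trainNetwork(ds, nc, tc)
  expect_length(fit$history, 6L)
  expect_lt(fit$history[6], fit$history[1])
  # identical seeds give identical loss histories
  fit2 <- trainNetwork(ds, nc, tc)
  expect_identical(fit$history, fit2$history)
  # mask row of the embedding stays pinned at zero after updates
  expect_true(all(fit$params@We[23, ] == 0))
})

test_that("zero epochs return the starting parameters unchanged", {
  cfg <- tinyConfig()
  p0 <- initParams(cfg, seed = 6)
  ds <- list(new("LabeledPair", encA = encodeProtein("MKVE", 12),
                 encB = encodeProtein("DEDA", 12), y = c(1, 0, 0)))
  fit <- trainNetwork(ds, cfg, trainConfig(epochs = 0, seed = 1),
                      params = p0)
  expect_identical(TrioPPI:::paramArrays(fit$params),
                   TrioPPI:::paramArrays(p0))
  expect_length(fit$history, 0L)
})

test_that("k-fold splits partition, balance and stratify", {
  pl <- PairList(sprintf("a%d", 1:10), sprintf("b%d", 1:10),
                 rep(c("interacting", "negative"), 5))
  folds <- kfoldSplit(pl, k = 5, seed = 3)
  expect_length(folds, 5L)
  expect_true(all(lengths(folds) == 2L))
  expect_setequal(unlist(folds), 1:10)
  for (f in folds) {
    tab <- table(pairLabels(pl)[f])
    expect_true(max(tab) - min(tab) <= 1)
  }
  # larger, odd-sized case: sizes differ by at most one, classes within 1
  pl2 <- PairList(sprintf("a%d", 1:23), sprintf("b%d", 1:23),
                  c(rep("interacting", 11), rep("negative", 12)))
  folds2 <- kfoldSplit(pl2, k = 5, seed = 8)
  expect_setequal(unlist(folds2), 1:23)
  expect_lte(diff(range(lengths(folds2))), 1L)
  nInt <- vapply(folds2, function(f)
    sum(pairLabels(pl2)[f] == "interacting"), 0L)
  expect_lte(diff(range(nInt)), 1L)
  expect_error(kfoldSplit(pl, k = 11), "exceeds")
})
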