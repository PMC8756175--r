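test_that("binary reduction calls the pair-class argmax with a conservative tie", {
  pm <- rbind(c(0.7, 0.2, 0.1), c(0.2, 0.7, 0.1), c(0.45, 0.45, 0.10))
  expect_equal(binarizeCalls(pm),
               c("interacting", "negative", "negative"))
  expect_equal(binarizeCalls(pm, policy = "threshold", threshold = 0.4),
               c("interacting", "negative", "interacting"))
})

test_that("metrics reproduce the worked confusion table", {
  rep <- metricsReport(list(TP = 40, FP = 10, TN = 45, FN = 5))
  expect_equal(rep$accuracy, 0.85)
  expect_equal(rep$precision, 0.8)
  expect_equal(rep$sensitivity, 40 / 45)
  expect_equal(rep$specificity, 45 / 55)
  expect_equal(rep$mcc, (40 * 45 - 10 * 5) / sqrt(50 * 45 * 55 * 50))
  expect_equal(round(rep$mcc, 4), 0.7035)
})

test_that("a perfect classifier scores 1 everywhere", {
  labels <- rep(c("interacting", "negative"), each = 10)
  scores <- rep(c(0.9, 0.1), each = 10)
  rep <- metricsReport(list(TP = 10, FP = 0, TN = 10, FN = 0),
                       scores, labels)
  for (m in c("accuracy", "precision", "sensitivity", "specificity",
              "f1", "mcc", "ap_interacting", "ap_negative", "auc"))
    expect_equal(rep[[m]], 1, info = m)
})

test_that("undefined denominators report NA with a warning, never 0", {
  expect_warning(rep <- metricsReport(list(TP = 0, FP = 0, TN = 9,
                                           FN = 1)), "precision undefined")
  expect_true(is.na(rep$precision))
  expect_equal(rep$f1, 0)   # count form 2TP/(2TP+FP+FN) is defined here
  expect_error(metricsReport(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "no evaluated")
})

test_that("metric formulas agree with an independent reference on random tables", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    calls <- sample(c("interacting", "negative"), n, TRUE)
    labels <- sample(c("interacting", "negative"), n, TRUE)
    cc <- confusionCounts(calls, labels)
    # recount brute-force
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
    expect_equal(cc$TP, sum(calls == "interacting" &
                            labels == "interacting"))
    if (min(cc$TP + cc$FP, cc$TP + cc$FN, cc$TN + cc$FP,
            cc$TN + cc$FN) == 0) next
    got <- metricsReport(cc)
    want <- refMetrics(cc$TP, cc$FP, cc$TN, cc$FN)
    for (m in names(want))
      expect_equal(got[[m]], want[[m]], tolerance = 1e-12, info = m)
    expect_gte(got$mcc, -1); expect_lte(got$mcc, 1)
    expect_gte(got$f1, 0);  expect_lte(got$f1, 1)
  }
})

test_that("AP and AUC match brute force and pROC", {
  set.seed(15)
  for (rep in 1:25) {
    n <- sample(20:50, 1)
    labels <- sample(c("interacting", "negative"), n, TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)      # ties included
    got <- metricsReport(list(TP = 1, FP = 1, TN = 1, FN = 1),
                         scores, labels)
    isPos <- labels == "interacting"
    expect_equal(got$ap_interacting, refAveragePrecision(scores, isPos),
                 tolerance = 1e-12)
    expect_equal(got$ap_negative, refAveragePrecision(-scores, !isPos),
                 tolerance = 1e-12)
    expect_equal(got$auc, refAUC(scores, isPos), tolerance = 1e-12)
    expect_gte(got$ap_interacting, 0); expect_lte(got$ap_interacting, 1)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(got$auc,
                   as.numeric(pROC::auc(pROC::roc(as.numeric(isPos), scores,
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-validation reports per-fold rows, a consistent summary and no leakage", {
  gen <- generateSynthetic(synthSpec(nPairs = 10, lenRange = c(30, 45),
                                     seed = 23))
  nc <- networkConfig(d = 4, filters = list(c(2, 1, 8), c(6, 1, 8)),
                      f1 = 16, lmax = 45, dropoutRate = 0)
  tc <- trainConfig(epochs = 2, batchSize = 8, seed = 17, folds = 5)
  cv <- crossValidate(gen$pairs, gen$sequences, nc, tc)
  expect_equal(nrow(cv$perFold), 5L)
  expect_equal(cv$summary$statistic, c("mean", "sd"))
  expect_equal(cv$summary$accuracy[1], mean(cv$perFold$accuracy),
               tolerance = 1e-12)
  expect_equal(cv$summary$accuracy[2], stats::sd(cv$perFold$accuracy),
               tolerance = 1e-12)
  # folds partition the pairs
  expect_setequal(unlist(cv$folds), seq_len(length(gen$pairs)))
  # single-protein augmentation never sees held-out sequences: the
  # training set for each fold only references training-fold pair ids
  seqChar <- as.character(gen$sequences)
  for (f in seq_along(cv$folds)) {
    trainPairs <- pairFrame(gen$pairs[-cv$folds[[f]]])
    testOnlyIds <- setdiff(
      unlist(pairFrame(gen$pairs[cv$folds[[f]]])[c("idA", "idB")]),
      unlist(trainPairs[c("idA", "idB")]))
    ds <- buildDataset(gen$pairs[-cv$folds[[f]]], gen$sequences,
                       lmax = 45, singles = TRUE, seed = 1)
    singles <- Filter(function(ex) ex@y[3] == 1, ds)
    testOnlySeqs <- seqChar[testOnlyIds]
    for (ex in singles) {
      enc <- if (all(maskBits(ex@encA))) ex@encB else ex@encA
      len <- trueLength(enc)
      # reconstruct the residue string from the one-hot rows
      letters <- trioAlphabet()[apply(
        onehot(enc)[seq_len(len), , drop = FALSE], 1, which.max)]
      expect_false(paste(letters, collapse = "") %in% testOnlySeqs)
    }
  }
})
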