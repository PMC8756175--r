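# One trained model at the study conditions, shared by the tests that
# need it (trained lazily, once per test run).
#   training corpus: 100 interacting + 100 negative pairs (seed 101)
#   + single-protein cases; held-out corpus: 50 + 50 pairs (seed 202);
#   default architecture at lmax = 300; 30 epochs of AMSGrad (seed 5).
.modelCache <- new.env(parent = emptyenv())

synthStudyModel <- function() {
  if (!is.null(.modelCache$fit)) return(as.list(.modelCache))
  trainGen <- generateSynthetic(synthSpec(nPairs = 100L, seed = 101L))
  testGen <- generateSynthetic(synthSpec(nPairs = 50L, seed = 202L))
  netcfg <- networkConfig(lmax = 300L)
  ds <- buildDataset(trainGen$pairs, trainGen$sequences, lmax = 300L,
                     seed = 1L)
  fit <- trainNetwork(ds, netcfg, trainConfig(epochs = 30L, seed = 5L))
  .modelCache$trainGen <- trainGen
  .modelCache$testGen <- testGen
  .modelCache$netcfg <- netcfg
  .modelCache$fit <- fit
  as.list(.modelCache)
}
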