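#' Construct a SynthSpec
#'
#' Specification of a synthetic, ground-truthed benchmark in which
#' interaction is decided by a pair of planted motifs: a pair is
#' interacting iff member A carries \code{motifA} and member B carries
#' \code{motifB}. Defaults: 50 pairs per class, lengths 150--300 (the
#' corpus length floor and a desk-scale cap), motifs
#' \code{"KRKRKRKR"} / \code{"DEDEDEDE"} (length 8, charge-contrasted
#' so they are distinguishable), uniform background over the 20
#' standard amino acids, no label noise.
#'
#' @param nPairs pairs per class.
#' @param lenRange integer(2) min/max sequence length.
#' @param motifA,motifB planted motifs (shorter than
#'   \code{lenRange[1]}).
#' @param background numeric(20) sampling weights over the 20 standard
#'   residues (order of \code{trioAlphabet()[1:20]}); NULL = uniform.
#' @param labelNoise fraction of labels flipped per class, in [0, 0.5).
#' @param seed integer seed.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nPairs = 50L, lenRange = c(150L, 300L),
                      motifA = "KRKRKRKR", motifB = "DEDEDEDE",
                      background = NULL, labelNoise = 0, seed = 1L) {
  if (is.null(background)) background <- rep(1 / 20, 20L)
  new("SynthSpec", nPairs = as.integer(nPairs),
      lenRange = as.integer(lenRange), motifA = motifA, motifB = motifB,
      background = background, labelNoise = as.numeric(labelNoise),
      seed = as.integer(seed))
}

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(
    "SynthSpec: %d pairs/class, lengths %d-%d, motifs %s/%s, noise %.2f, seed %d\n",
    object@nPairs, object@lenRange[1], object@lenRange[2],
    object@motifA, object@motifB, object@labelNoise, object@seed))
})

# random background sequence free of both motifs
backgroundSeq <- function(len, spec, letters20) {
  repeat {
    s <- paste(sample(letters20, len, replace = TRUE,
                      prob = spec@background), collapse = "")
    if (!grepl(spec@motifA, s, fixed = TRUE) &&
        !grepl(spec@motifB, s, fixed = TRUE)) return(s)
  }
}

# plant `motif` at a uniform random position of a motif-free background
plantMotif <- function(len, motif, spec, letters20) {
  ml <- nchar(motif)
  repeat {
    s <- backgroundSeq(len, spec, letters20)
    start <- sample.int(len - ml + 1L, 1L)
    out <- paste0(substr(s, 1L, start - 1L), motif,
                  substr(s, start + ml, len))
    # planting may create a stray second occurrence across the joins;
    # the recorded start must be (and is) a true occurrence
    if (!grepl(if (identical(motif, spec@motifA)) spec@motifB
               else spec@motifA, out, fixed = TRUE))
      return(list(seq = out, start = start))
  }
}

#' Generate a synthetic motif-determined PPI dataset
#'
#' Emits \code{nPairs} interacting pairs (member A carries motifA,
#' member B carries motifB, each planted at a uniform random position)
#' and \code{nPairs} negative pairs cycling through three sub-modes:
#' motifA only, motifB only, neither. Sequence members are freshly
#' drawn per pair; backgrounds are rejection-sampled to be motif-free,
#' so ground-truth motif positions always index a true occurrence and
#' negatives genuinely lack the missing motif. With
#' \code{labelNoise > 0}, \code{round(labelNoise * nPairs)} labels per
#' class are flipped (seeded, without replacement). Deterministic given
#' the spec's seed.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with \code{sequences} (named \code{AAStringSet}),
#'   \code{pairs} (labelled \linkS4class{PairList}; labels reflect any
#'   noise flips), \code{truth} (data.frame \code{id}, \code{motif},
#'   \code{start} — 1-based — one row per planted motif), and
#'   \code{cleanLabels} (pre-noise labels).
#' @export
generateSynthetic <- function(spec) {
  validObject(spec)
  letters20 <- trioAlphabet()[1:20]
  n <- spec@nPairs
  withSeed(spec@seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    addRecord <- function(prefix, i, planted) {
      id <- sprintf("%s%04d", prefix, i)
      ids <<- c(ids, id)
      seqs <<- c(seqs, planted$seq)
      if (!is.null(planted$motif))
        truth[[length(truth) + 1L]] <<- data.frame(
          id = id, motif = planted$motif, start = planted$start)
      id
    }
    rlen <- function() sample(spec@lenRange[1]:spec@lenRange[2], 1L)
    idA <- idB <- character(2L * n)
    for (i in seq_len(n)) {                       # positives
      pa <- plantMotif(rlen(), spec@motifA, spec, letters20)
      pa$motif <- spec@motifA
      pb <- plantMotif(rlen(), spec@motifB, spec, letters20)
      pb$motif <- spec@motifB
      idA[i] <- addRecord("posA", i, pa)
      idB[i] <- addRecord("posB", i, pb)
    }
    modes <- rep_len(c("Aonly", "Bonly", "neither"), n)
    for (i in seq_len(n)) {                       # negatives
      a <- if (modes[i] == "Aonly") {
        p <- plantMotif(rlen(), spec@motifA, spec, letters20)
        p$motif <- spec@motifA; p
      } else list(seq = backgroundSeq(rlen(), spec, letters20))
      b <- if (modes[i] == "Bonly") {
        p <- plantMotif(rlen(), spec@motifB, spec, letters20)
        p$motif <- spec@motifB; p
      } else list(seq = backgroundSeq(rlen(), spec, letters20))
      idA[n + i] <- addRecord("negA", i, a)
      idB[n + i] <- addRecord("negB", i, b)
    }
    labels <- rep(c("interacting", "negative"), each = n)
    clean <- labels
    nFlip <- round(spec@labelNoise * n)
    if (nFlip > 0L) {
      flipPos <- sample.int(n, nFlip)
      flipNeg <- n + sample.int(n, nFlip)
      labels[flipPos] <- "negative"
      labels[flipNeg] <- "interacting"
    }
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- ids
    list(sequences = sequences,
         pairs = PairList(idA, idB, labels),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(id = character(), motif = character(),
                                 start = integer()),
         cleanLabels = clean)
  })
}
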