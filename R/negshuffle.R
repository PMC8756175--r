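#' k-let-preserving sequence shuffle (first residue fixed)
#'
#' Returns a random permutation of \code{residues} that keeps the first
#' residue in place and exactly preserves the multiset of k-lets
#' (contiguous length-k substrings; k = 2 means dipeptides) of the
#' suffix starting at position 2. Total residue composition is always
#' preserved. Sampling uses the Euler-path construction on the
#' (k-1)-gram transition multigraph of the suffix (Altschul--Erickson
#' style): a uniformly chosen last-out-edge arborescence towards the
#' terminal vertex, rejection-sampled for connectivity, followed by a
#' uniform permutation of the remaining out-edges, which draws uniformly
#' from the set of valid shuffles. Because the suffix's k-lets are
#' conserved exactly, only the k-lets straddling position 1 can change;
#' whole-sequence k-let frequencies are therefore approximately (and the
#' suffix's exactly) conserved.
#'
#' A shuffle can return the input itself (for some sequences it is the
#' only valid arrangement). When \code{attempts > 1} the draw is
#' repeated up to that many times to obtain an output different from
#' the input; if all attempts return the input it is accepted with a
#' warning.
#'
#' @param residues character string, length >= k + 1.
#' @param k k-let order (default 2, dipeptides).
#' @param seed optional integer seed; the caller's RNG state is
#'   untouched. NULL draws from the current RNG stream.
#' @param attempts maximum redraws aiming for an output distinct from
#'   the input (>= 1).
#' @return the shuffled string.
#' @examples
#' kletShuffle("MKVEDELKRRAEELKAK", seed = 1)
#' @export
kletShuffle <- function(residues, k = 2L, seed = NULL, attempts = 10L) {
  k <- as.integer(k)
  attempts <- as.integer(attempts)
  if (k < 1L) stopf("k must be >= 1")
  if (attempts < 1L) stopf("attempts must be >= 1")
  n <- nchar(residues)
  if (n < k + 1L)
    stopf("sequence of length %d too short for k = %d (need >= %d)",
          n, k, k + 1L)
  withSeed(seed, {
    out <- residues
    for (a in seq_len(attempts)) {
      out <- paste0(substr(residues, 1L, 1L),
                    eulerShuffle(substr(residues, 2L, n), k))
      if (out != residues) break
    }
    if (out == residues && attempts > 1L && !uniqueArrangement(residues, k))
      warnf("shuffle returned the input sequence after %d attempts",
            attempts)
    out
  })
}

# TRUE when the suffix trivially admits a single arrangement (all k-lets
# leave no freedom); used only to silence the fixed-point warning.
uniqueArrangement <- function(residues, k) {
  suf <- strsplit(substr(residues, 2L, nchar(residues)), "")[[1]]
  length(unique(suf)) == 1L || length(suf) <= k
}

# Uniform k-let-preserving shuffle of a whole string via an Euler path
# over its (k-1)-gram transition multigraph. First and last (k-1)-grams
# are conserved by any valid shuffle, hence the first and last k-1
# characters stay fixed.
eulerShuffle <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  m <- length(chars)
  if (m <= k) return(s)                       # single k-let at most: fixed
  if (k == 1L) {                              # plain composition shuffle
    return(paste(sample(chars), collapse = ""))
  }
  # vertex sequence: (k-1)-grams at positions 1..m-k+2
  nv <- m - k + 2L
  grams <- vapply(seq_len(nv), function(i)
    paste(chars[i:(i + k - 2L)], collapse = ""), "")
  vlev <- unique(grams)
  v <- match(grams, vlev)                     # walk v[1] -> v[nv]
  from <- v[-nv]
  to <- v[-1L]
  nE <- length(from)
  start <- v[1L]
  end <- v[nv]
  outEdges <- split(seq_len(nE), from)        # edge ids by source vertex
  # vertices (other than end) whose out-edges need a designated last edge
  needLast <- setdiff(as.integer(names(outEdges)), end)
  edgeOrder <- function() {
    last <- integer(0)
    if (length(needLast)) {
      for (tries in seq_len(2000L)) {
        last <- vapply(needLast, function(u) {
          es <- outEdges[[as.character(u)]]
          if (length(es) == 1L) es else es[sample.int(length(es), 1L)]
        }, integer(1))
        if (lastEdgesReachEnd(needLast, to[last], end)) break
        last <- integer(0)
      }
      if (!length(last)) {
        # deterministic fallback: BFS tree towards `end` (valid, not
        # uniform; unreachable in practice for biological alphabets)
        last <- bfsLastEdges(needLast, outEdges, to, end)
      }
    }
    # per-vertex ordering: random order of non-last edges, last edge last
    ord <- vector("list", length(vlev))
    for (u in as.integer(names(outEdges))) {
      es <- outEdges[[as.character(u)]]
      if (u %in% needLast) {
        le <- last[match(u, needLast)]
        rest <- setdiff(es, le)
        ord[[u]] <- c(if (length(rest)) rest[sample.int(length(rest))], le)
      } else {
        ord[[u]] <- if (length(es) > 1L) es[sample.int(length(es))] else es
      }
    }
    ord
  }
  ord <- edgeOrder()
  ptr <- integer(length(vlev)) + 1L
  walk <- integer(nE)
  cur <- start
  for (i in seq_len(nE)) {
    e <- ord[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    walk[i] <- e
    cur <- to[e]
  }
  # rebuild: first (k-1)-gram then the last character of each traversed edge
  paste0(vlev[start],
         paste(vapply(walk, function(e) {
           g <- vlev[to[e]]
           substr(g, k - 1L, k - 1L)
         }, ""), collapse = ""))
}

# Does following the designated last edges from every vertex in `verts`
# reach `end` without cycling? (arborescence test)
lastEdgesReachEnd <- function(verts, lastTo, end) {
  nextOf <- structure(lastTo, names = as.character(verts))
  for (u in verts) {
    seen <- integer(0)
    cur <- u
    repeat {
      if (cur == end) break
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      nx <- nextOf[as.character(cur)]
      if (is.na(nx)) return(FALSE)
      cur <- as.integer(nx)
    }
  }
  TRUE
}

# Deterministic arborescence towards `end` by reverse BFS.
bfsLastEdges <- function(needLast, outEdges, to, end) {
  last <- integer(length(needLast))
  assigned <- rep(FALSE, length(needLast))
  frontier <- end
  while (any(!assigned)) {
    progress <- FALSE
    for (i in which(!assigned)) {
      u <- needLast[i]
      es <- outEdges[[as.character(u)]]
      hit <- es[to[es] %in% frontier]
      if (length(hit)) {
        last[i] <- hit[1L]
        assigned[i] <- TRUE
        frontier <- c(frontier, u)
        progress <- TRUE
      }
    }
    if (!progress) stopf("transition graph is not Eulerian-connected")
  }
  last
}

#' Generate negative pairs by dipeptide-preserving shuffling
#'
#' For each positive pair, one member is chosen at random, its sequence
#' shuffled with \code{\link{kletShuffle}} (first residue fixed, suffix
#' k-let counts conserved), registered under a derived identifier
#' (\code{"<id>_shuf<i>"}), and paired with the untouched partner under
#' the \code{"negative"} label. This yields a 1:1 class balance with
#' negatives whose composition and dipeptide statistics match their
#' positive templates.
#'
#' @param positives \linkS4class{PairList}; all entries must be labelled
#'   \code{"interacting"}.
#' @param sequences named \code{AAStringSet} (or named character vector)
#'   resolving all pair ids.
#' @param k k-let order (default 2).
#' @param seed integer seed; drives both the member choice and the
#'   shuffles.
#' @param attempts redraw budget per shuffle (see
#'   \code{\link{kletShuffle}}).
#' @return list with \code{pairs} (the negative \code{PairList}) and
#'   \code{sequences} (an \code{AAStringSet} of the new shuffled
#'   records only).
#' @export
buildNegatives <- function(positives, sequences, k = 2L, seed = 1L,
                           attempts = 10L) {
  e <- pairFrame(positives)
  if (nrow(e) > 0L && !all(e$label == "interacting"))
    stopf("all positive pairs must be labelled 'interacting'")
  seqChar <- as.character(sequences)
  names(seqChar) <- names(sequences)
  nShuf <- integer(0)                       # per-original-id counter
  newIds <- character(nrow(e))
  newSeqs <- character(nrow(e))
  idA <- e$idA
  idB <- e$idB
  withSeed(seed, {
    for (i in seq_len(nrow(e))) {
      pickB <- sample(c(TRUE, FALSE), 1L)
      orig <- if (pickB) e$idB[i] else e$idA[i]
      cnt <- if (is.na(nShuf[orig])) 1L else nShuf[orig] + 1L
      nShuf[orig] <- cnt
      nid <- sprintf("%s_shuf%d", orig, cnt)
      newIds[i] <- nid
      newSeqs[i] <- kletShuffle(seqChar[[orig]], k = k, seed = NULL,
                                attempts = attempts)
      if (pickB) idB[i] <- nid else idA[i] <- nid
    }
  })
  shufSet <- Biostrings::AAStringSet(newSeqs)
  names(shufSet) <- newIds
  list(pairs = PairList(idA, idB, rep("negative", nrow(e))),
       sequences = shufSet)
}
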