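#' Occlusion effect of one residue on the interaction call
#'
#' Masks a single residue of protein A and reports the change in the
#' predicted non-interaction probability with partner B:
#' \code{P_neg(A with position masked, B) - P_neg(A, B)}, dropout
#' disabled. A positive value means the residue's presence supports the
#' interaction (masking it pushes the model towards "negative"). Bounded
#' in [-1, 1].
#'
#' @param encA encoding of the scored protein.
#' @param encB encoding of the (unmasked) partner.
#' @param position 1-based residue position,
#'   \code{<= trueLength(encA)}.
#' @param params trained \linkS4class{NetworkParams}.
#' @return numeric scalar.
#' @export
residueEffect <- function(encA, encB, position, params) {
  base <- pNegative(predictPair(encA, encB, params))
  occluded <- pNegative(predictPair(maskPositions(encA, position), encB,
                                    params))
  occluded - base
}

#' Per-residue importance profile by single-position occlusion
#'
#' Computes \code{\link{residueEffect}} for every residue of
#' \code{seqA} with respect to partner \code{seqB}. The baseline
#' prediction and the partner's pooled representation are computed once
#' and reused; the result is bit-identical to position-by-position
#' \code{residueEffect} calls. Swapping the two sequences yields the
#' partner's profile from the same model.
#'
#' @param seqA character; the protein to score.
#' @param seqB character; its partner.
#' @param params trained \linkS4class{NetworkParams}.
#' @param proteinId,partnerId identifiers carried into the profile.
#' @param alphabet residue alphabet.
#' @return an \linkS4class{ImportanceProfile} (positions 1-based).
#' @export
importanceProfile <- function(seqA, seqB, params, proteinId = "A",
                              partnerId = "B",
                              alphabet = trioAlphabet()) {
  cfg <- params@config
  encA <- encodeProtein(seqA, lmax = cfg@lmax, alphabet = alphabet)
  encB <- encodeProtein(seqB, lmax = cfg@lmax, alphabet = alphabet)
  HB <- forwardBranch(encB, params)
  pneg <- function(enc) {
    forwardHead(forwardBranch(enc, params) + HB, params,
                training = FALSE)$p[[2L]]
  }
  base <- pneg(encA)
  eff <- vapply(seq_len(encA@trueLength), function(i)
    pneg(maskPositions(encA, i)) - base, numeric(1))
  new("ImportanceProfile", proteinId = proteinId, partnerId = partnerId,
      residues = as.character(seqA), scores = eff)
}

#' @rdname ImportanceProfile-class
#' @export
setMethod("scores", "ImportanceProfile", function(x) x@scores)

#' @rdname ImportanceProfile-class
#' @param x an \code{ImportanceProfile}.
#' @export
setMethod("length", "ImportanceProfile", function(x) length(x@scores))

setMethod("show", "ImportanceProfile", function(object) {
  cat(sprintf(
    "ImportanceProfile: %s vs %s, %d residues, scores in [%.4f, %.4f]\n",
    object@proteinId, object@partnerId, length(object@scores),
    min(object@scores), max(object@scores)))
})

#' Render an importance map
#'
#' Writes the profile as \code{tsv} (columns \code{position} [1-based],
#' \code{residue}, \code{score}), or as a heat-map grid — \code{png} or
#' \code{html} — of 20 squares per line (so a length-45 protein renders
#' as rows of 20, 20 and 5 squares), colored on a diverging palette
#' symmetric about zero: positive effects in reds, negative in blues,
#' with the residue letter overlaid on each square. The color scale is
#' normalized per protein (symmetric about 0 at the profile's absolute
#' maximum).
#'
#' @param profile an \linkS4class{ImportanceProfile}.
#' @param out output file path.
#' @param format one of \code{"tsv"}, \code{"png"}, \code{"html"}.
#' @return \code{out}, invisibly.
#' @export
renderMap <- function(profile, out, format = c("tsv", "png", "html")) {
  format <- match.arg(format)
  res <- strsplit(profile@residues, "")[[1]]
  sc <- profile@scores
  len <- length(sc)
  switch(format,
    tsv = {
      utils::write.table(
        data.frame(position = seq_len(len), residue = res, score = sc),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    png = {
      nrows <- ceiling(len / 20)
      grDevices::png(out, width = 20 * 28 + 40, height = nrows * 28 + 40)
      on.exit(grDevices::dev.off())
      graphics::par(mar = c(1, 1, 1, 1))
      graphics::plot.new()
      graphics::plot.window(xlim = c(0, 20), ylim = c(nrows, 0),
                            asp = 1)
      cols <- mapColors(sc)
      for (i in seq_len(len)) {
        r <- (i - 1) %/% 20
        c0 <- (i - 1) %% 20
        graphics::rect(c0, r + 1, c0 + 1, r, col = cols[i],
                       border = "grey40")
        graphics::text(c0 + 0.5, r + 0.5, res[i], cex = 0.7)
      }
    },
    html = {
      cols <- mapColors(sc)
      cell <- sprintf(
        paste0("<td title=\"pos %d: %.4f\" style=\"width:22px;",
               "height:22px;text-align:center;background:%s\">%s</td>"),
        seq_len(len), sc, cols, res)
      rows <- split(cell, (seq_len(len) - 1) %/% 20)
      body <- paste0("<tr>", vapply(rows, paste0, "", collapse = ""),
                     "</tr>", collapse = "\n")
      writeLines(c(
        "<!DOCTYPE html><html><body>",
        sprintf("<p>Importance map: %s vs %s</p>", profile@proteinId,
                profile@partnerId),
        "<table style=\"border-collapse:collapse;font-family:monospace\">",
        body, "</table></body></html>"), out)
    })
  invisible(out)
}

# diverging red (positive) / blue (negative) fill, symmetric about 0;
# an all-zero profile renders uniformly neutral (white)
mapColors <- function(sc) {
  m <- max(abs(sc))
  if (m == 0) return(rep("#FFFFFF", length(sc)))
  z <- sc / m                        # in [-1, 1]
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  rgb <- ramp((z + 1) / 2)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}
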