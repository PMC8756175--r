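CHECKPOINT_FORMAT <- 1L

#' Save a model checkpoint
#'
#' Writes the architecture configuration and every weight array to a
#' single JSON document (full double precision, format-versioned).
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param path output file (conventionally \code{.ckpt.json}).
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(params, path) {
  cfg <- params@config
  doc <- list(
    format = CHECKPOINT_FORMAT,
    config = list(d = cfg@d, filters = unname(as.matrix(cfg@filters)),
                  f1 = cfg@f1, dropoutRate = cfg@dropoutRate,
                  lmax = cfg@lmax, finalRelu = cfg@finalRelu),
    # %.17g strings survive the JSON round trip bit-exactly
    weights = lapply(paramArrays(params), function(a)
      list(dim = dim(a), data = sprintf("%.17g", as.vector(a)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Reads a checkpoint written by \code{\link{saveCheckpoint}},
#' validating the format version and all array shapes against the
#' stored configuration.
#'
#' @param path checkpoint file.
#' @return a \linkS4class{NetworkParams}.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != CHECKPOINT_FORMAT)
    stopf("unsupported checkpoint format '%s'", doc$format)
  cf <- doc$config
  filt <- matrix(as.integer(cf$filters), ncol = 3L)
  cfg <- networkConfig(d = cf$d,
                       filters = lapply(seq_len(nrow(filt)),
                                        function(i) filt[i, ]),
                       f1 = cf$f1, dropoutRate = cf$dropoutRate,
                       lmax = cf$lmax, finalRelu = cf$finalRelu)
  arrays <- lapply(doc$weights, function(w) {
    a <- as.numeric(w$data)
    dim(a) <- as.integer(w$dim)
    a
  })
  params <- paramsFromArrays(arrays, cfg)
  validObject(params)
  params
}
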