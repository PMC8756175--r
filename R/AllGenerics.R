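#' @rdname EncodedProtein-class
#' @param x an object.
#' @export
setGeneric("trueLength", function(x) standardGeneric("trueLength"))

#' @rdname EncodedProtein-class
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))

#' @rdname EncodedProtein-class
#' @export
setGeneric("onehot", function(x) standardGeneric("onehot"))

#' @rdname PredictionResult-class
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname PredictionResult-class
#' @export
setGeneric("pInteract", function(x) standardGeneric("pInteract"))

#' @rdname PredictionResult-class
#' @export
setGeneric("pNegative", function(x) standardGeneric("pNegative"))

#' @rdname PredictionResult-class
#' @export
setGeneric("pSingle", function(x) standardGeneric("pSingle"))

#' @rdname ImportanceProfile-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname NetworkParams-class
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))

#' @rdname PairList-class
#' @export
setGeneric("pairFrame", function(x) standardGeneric("pairFrame"))

#' @rdname PairList-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
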