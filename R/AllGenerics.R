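#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("pixelDwell", function(x) standardGeneric("pixelDwell"))
#' @export
setGeneric("linePeriod", function(x) standardGeneric("linePeriod"))
#' @export
setGeneric("columnLabels", function(x) standardGeneric("columnLabels"))
#' @export
setGeneric("columnLabels<-", function(x, value) standardGeneric("columnLabels<-"))
#' @export
setGeneric("columnPositions", function(x) standardGeneric("columnPositions"))
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))
#' @export
setGeneric("corrValues", function(x) standardGeneric("corrValues"))
#' @export
setGeneric("deltaPixels", function(x) standardGeneric("deltaPixels"))
#' @export
setGeneric("deltaUm", function(x) standardGeneric("deltaUm"))
#' @export
setGeneric("curves", function(x) standardGeneric("curves"))
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))
#' @export
setGeneric("transitTable", function(x) standardGeneric("transitTable"))
#' @export
setGeneric("diffusionCoef", function(x) standardGeneric("diffusionCoef"))
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))
#' @export
setGeneric("carpet", function(x) standardGeneric("carpet"))
#' @export
setGeneric("crossingEvents", function(x) standardGeneric("crossingEvents"))
#' @export
setGeneric("realizedKeq", function(x) standardGeneric("realizedKeq"))
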