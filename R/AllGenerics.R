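#' @rdname RadStudy-class
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))

#' @rdname RadStudy-class
#' @export
setGeneric("transcriptome", function(x) standardGeneric("transcriptome"))

#' @rdname RadStudy-class
#' @export
setGeneric("featureMap", function(x) standardGeneric("featureMap"))

#' @rdname RadStudy-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname RadStudy-class
#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @rdname RadStudy-class
#' @export
setGeneric("truthTables", function(x) standardGeneric("truthTables"))

#' @rdname RadStudy-class
#' @export
setGeneric("runConfig", function(x) standardGeneric("runConfig"))
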