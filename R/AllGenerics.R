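#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the container classes: node and entity
#' identifiers, edge tables, interaction pairs and feature values.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return The slot contents (see the individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x, ...) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("pairs", function(x, ...) standardGeneric("pairs"))

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x, ...) standardGeneric("drugIds"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x, ...) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("restartC", function(x, ...) standardGeneric("restartC"))
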