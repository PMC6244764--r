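#' @include AllClasses.R
NULL

#' Compound identifiers of an object
#' @param x an object holding compounds
#' @return character vector of compound identifiers
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Descriptor names of an object
#' @param x an object holding a descriptor matrix
#' @return character vector of descriptor names
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' Descriptor value matrix
#' @param x an object holding a descriptor matrix
#' @return numeric matrix, compounds x descriptors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' Descriptor provenance metadata
#' @param x a [DescriptorTable-class] or [CompoundSet-class]
#' @return data.frame with columns name, source, transform, parent
#' @export
setGeneric("descriptorMeta", function(x) standardGeneric("descriptorMeta"))

#' Response table of a compound set
#' @param x a [CompoundSet-class]
#' @return data.frame of responses
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' Per-compound annotation of a compound set
#' @param x a [CompoundSet-class]
#' @return data.frame of compound annotation
#' @export
setGeneric("compoundInfo", function(x) standardGeneric("compoundInfo"))

#' Variable importance on projection
#' @param object a fitted [PLSModel-class]
#' @return named numeric vector of VIP scores
#' @export
setGeneric("vip", function(object) standardGeneric("vip"))

#' Split-assignment table
#' @param x a [SplitAssignment-class]
#' @return data.frame with compound_id, set, provenance
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
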