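#' @rdname GenotypeMatrix-class
#' @param x a vetkey object.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname AssignmentMatrix-class
#' @param x an \code{AssignmentMatrix}.
#' @export
setGeneric("ancestryQ", function(x) standardGeneric("ancestryQ"))

#' @rdname AssignmentMatrix-class
#' @export
setGeneric("ancestrySE", function(x) standardGeneric("ancestrySE"))

#' @rdname AssignmentMatrix-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname CoancestryMatrix-class
#' @param x a \code{CoancestryMatrix}.
#' @export
setGeneric("coancestry", function(x) standardGeneric("coancestry"))

#' @rdname CoancestryMatrix-class
#' @export
setGeneric("groupMeans", function(x) standardGeneric("groupMeans"))

#' @rdname SiblingGroups-class
#' @param x a \code{SiblingGroups}.
#' @export
setGeneric("siblingGroups", function(x) standardGeneric("siblingGroups"))

#' @rdname SiblingGroups-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname TraitSchema-class
#' @param x a \code{TraitSchema}.
#' @export
setGeneric("traitTable", function(x) standardGeneric("traitTable"))

#' @rdname TraitSchema-class
#' @param trait trait name.
#' @export
setGeneric("traitLevels", function(x, trait) standardGeneric("traitLevels"))

#' @rdname CohortKey-class
#' @param x a \code{CohortKey}.
#' @export
setGeneric("keyIntervals", function(x) standardGeneric("keyIntervals"))
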