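#' Re-exported metadata accessor
#'
#' Re-exported from S4Vectors so that `metadata(result)$prior` works
#' without attaching S4Vectors explicitly.
#'
#' @name metadata
#' @importFrom S4Vectors metadata
#' @export metadata
NULL

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneIds", "GeneModelSet", function(x) mcols(x@genes)$gene_id)

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModelSet-class
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname TagLibrary-class
#' @export
setGeneric("libSize", function(x) standardGeneric("libSize"))

#' @rdname TagLibrary-class
#' @export
setMethod("libSize", "TagLibrary", function(x) x@total)

#' @rdname TagLibrary-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagLibrary-class
#' @export
setMethod("tagCounts", "TagLibrary",
    function(x) stats::setNames(x@counts, x@tags))

#' @rdname TagLibrary-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname TagLibrary-class
#' @export
setMethod("condition", "TagLibrary", function(x) x@condition)

#' @rdname AssignmentReport-class
#' @export
setMethod("condition", "AssignmentReport", function(x) x@condition)

#' @rdname AssignmentReport-class
#' @param x An `AssignmentReport`.
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname AssignmentReport-class
#' @export
setMethod("geneCounts", "AssignmentReport", function(x) x@geneCounts)

#' @rdname AssignmentReport-class
#' @export
setGeneric("categoryReads", function(x) standardGeneric("categoryReads"))

#' @rdname AssignmentReport-class
#' @export
setMethod("categoryReads", "AssignmentReport", function(x) x@categoryReads)

#' @rdname AssignmentReport-class
#' @export
setGeneric("categoryTags", function(x) standardGeneric("categoryTags"))

#' @rdname AssignmentReport-class
#' @export
setMethod("categoryTags", "AssignmentReport", function(x) x@categoryTags)

#' @rdname AssignmentReport-class
#' @export
setGeneric("tagTable", function(x) standardGeneric("tagTable"))

#' @rdname AssignmentReport-class
#' @export
setMethod("tagTable", "AssignmentReport", function(x) x@tagTable)

#' @rdname ProteinCounts-class
#' @param x A `ProteinCounts`.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ProteinCounts-class
#' @export
setMethod("proteinIds", "ProteinCounts", function(x) x@proteinId)

#' @rdname ProteinCounts-class
#' @export
setGeneric("spectralCounts", function(x, normalized = FALSE)
    standardGeneric("spectralCounts"))

#' @rdname ProteinCounts-class
#' @param normalized Return the normalized matrix instead of raw counts.
#' @export
setMethod("spectralCounts", "ProteinCounts", function(x, normalized = FALSE) {
    if (normalized) {
        if (!nrow(x@normalized))
            stop("counts are not normalized yet; run normalizeSpectralCounts()")
        m <- x@normalized
    } else m <- x@counts
    rownames(m) <- x@proteinId
    m
})

#' @rdname ProteinCounts-class
#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))

#' @rdname ProteinCounts-class
#' @export
setMethod("peptideCounts", "ProteinCounts",
    function(x) stats::setNames(x@peptides, x@proteinId))
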