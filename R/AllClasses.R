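#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList strand start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics "start<-" "end<-"
NULL

#' Gene models with exon structure
#'
#' A strand-aware set of gene models on a genome: one genomic span per gene
#' plus an ordered exon list (default: a single exon covering the span).
#' Coordinates are 1-based inclusive throughout (the native R/Bioconductor
#' convention, matching GFF3 on disk).
#'
#' @slot genes A [GenomicRanges::GRanges] with one range per gene, strand
#'   `+` or `-`, and a `gene_id` metadata column (unique).
#' @slot exons A [GenomicRanges::GRangesList] parallel to `genes`, named by
#'   `gene_id`; exons are sorted, non-overlapping and contained in the gene
#'   span.
#'
#' @seealso [readGeneModels()], [extendThreePrime()], [transcriptSequences()]
#' @export
setClass("GeneModelSet",
    slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    g <- object@genes
    ex <- object@exons
    msg <- character()
    if (is.null(mcols(g)$gene_id))
        return("genes must carry a 'gene_id' metadata column")
    ids <- mcols(g)$gene_id
    if (anyDuplicated(ids))
        msg <- c(msg, "gene_id values must be unique")
    if (!all(as.character(strand(g)) %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-' for every gene")
    if (length(ex) != length(g))
        msg <- c(msg, "exons must be parallel to genes")
    if (length(ex) == length(g) && length(g) > 0) {
        if (!identical(names(ex), as.character(ids)))
            msg <- c(msg, "exons must be named by gene_id, in gene order")
        st <- start(ex); en <- end(ex)
        gs <- start(g); ge <- end(g)
        for (i in seq_along(g)) {
            s <- st[[i]]; e <- en[[i]]
            if (length(s) == 0L) { msg <- c(msg, "every gene needs >=1 exon"); break }
            if (is.unsorted(s, strictly = TRUE) ||
                any(s[-1] <= e[-length(e)] )) {
                msg <- c(msg, sprintf("exons of gene '%s' must be sorted and non-overlapping", ids[i]))
                break
            }
            if (min(s) < gs[i] || max(e) > ge[i]) {
                msg <- c(msg, sprintf("exons of gene '%s' fall outside the gene span", ids[i]))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class Number of genes.
#' @param x,object A `GeneModelSet`.
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet with", length(object), "genes on",
        length(unique(as.character(seqnames(object@genes)))), "sequence(s)\n")
    if (length(object)) {
        n_ex <- lengths(object@exons)
        cat("  exons per gene:", min(n_ex), "-", max(n_ex), "\n")
    }
})

#' A tag-count library for one condition
#'
#' A multiset of 21-nt CATG-anchored sequence tags with observed counts and
#' the total number of tags sequenced (the library size used for
#' tags-per-million normalization).
#'
#' @slot condition Single string labelling the condition.
#' @slot tags Character vector of distinct 21-nt tags (prefix `CATG`).
#' @slot counts Integer (or numeric) vector of counts `>= 1`, parallel to
#'   `tags`.
#' @slot total Total tags sequenced; equals `sum(counts)`.
#'
#' @seealso [tagLibrary()], [readTagLibrary()], [mapTags()]
#' @export
setClass("TagLibrary",
    slots = c(condition = "character", tags = "character",
              counts = "numeric", total = "numeric"))

setValidity("TagLibrary", function(object) {
    msg <- character()
    if (length(object@condition) != 1L)
        msg <- c(msg, "condition must be a single string")
    if (length(object@tags) != length(object@counts))
        msg <- c(msg, "tags and counts must be parallel")
    if (anyDuplicated(object@tags))
        msg <- c(msg, "tags must be distinct")
    if (length(object@counts) && any(object@counts < 1))
        msg <- c(msg, "counts must be >= 1")
    if (!isTRUE(all.equal(sum(object@counts), object@total)))
        msg <- c(msg, "total must equal sum(counts)")
    bad <- object@tags[nchar(object@tags) != 21L |
                       substr(object@tags, 1L, 4L) != "CATG"]
    if (length(bad))
        msg <- c(msg, sprintf("invalid tag (must be 21 nt starting CATG): '%s'",
                              bad[1]))
    if (length(msg)) msg else TRUE
})

setMethod("show", "TagLibrary", function(object) {
    cat("TagLibrary '", object@condition, "': ",
        length(object@tags), " unique tags, ",
        format(object@total, big.mark = ","), " total\n", sep = "")
})

#' Tag-to-gene assignment report for one library
#'
#' Per-tag mapping categories and tallies produced by [assignToGenes()].
#' Categories are `gene_sense`, `gene_antisense`, `intergenic`,
#' `multi_mapped`, `unmapped`, and the (normally empty) `ambiguous` class
#' for exact ties between overlapping same-strand models. Read tallies over
#' all categories partition the library total exactly.
#'
#' @slot condition Condition label of the library.
#' @slot tagTable A [S4Vectors::DataFrame] with one row per unique tag:
#'   `tag`, `count`, `category`, `gene_id` (NA unless `gene_sense`),
#'   `chrom`, `pos`, `strand` (NA unless uniquely mapped),
#'   `dist3p` (distance to the nearest model 3' end, intergenic tags only).
#' @slot categoryReads,categoryTags Named numeric tallies per category
#'   (reads, unique tags).
#' @slot geneCounts Named numeric vector of pooled sense read counts per
#'   gene (all genes in the model set, zeros included).
#' @slot total Library total N.
#' @slot utrExtension The 3'-extension (bp) the models carried.
#'
#' @export
setClass("AssignmentReport",
    slots = c(condition = "character", tagTable = "DataFrame",
              categoryReads = "numeric", categoryTags = "numeric",
              geneCounts = "numeric", total = "numeric",
              utrExtension = "numeric"))

setValidity("AssignmentReport", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(sum(object@categoryReads), object@total)))
        msg <- c(msg, "category read tallies must sum to the library total")
    if (!isTRUE(all.equal(sum(object@tagTable$count), object@total)))
        msg <- c(msg, "tag table counts must sum to the library total")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AssignmentReport", function(object) {
    cat("AssignmentReport '", object@condition, "' (3' extension ",
        object@utrExtension, " bp)\n", sep = "")
    tab <- rbind(reads = object@categoryReads,
                 unique_tags = object@categoryTags)
    print(tab)
})

#' Empirical-Bayes prior for the two-library fold-change model
#'
#' A two-component prior over the per-gene log2 fold change delta
#' (condition 2 : condition 1): a point mass at 0 with weight `pi0`
#' (non-differential genes) and a Normal(0, tau^2) slab, discretized on a
#' symmetric grid, with weight `1 - pi0`. Fitted by [fitPrior()] via EM.
#'
#' @slot pi0 Null-component weight in `[0, 1]`.
#' @slot tau Standard deviation (log2 units) of the non-null component.
#' @slot grid Numeric grid of delta values, symmetric about 0, containing 0.
#' @slot spacing Grid spacing h.
#' @slot converged Logical; FALSE when EM hit the iteration cap.
#' @slot logLik Final marginal log-likelihood.
#' @slot nIter Iterations used.
#'
#' @export
setClass("PriorModel",
    slots = c(pi0 = "numeric", tau = "numeric", grid = "numeric",
              spacing = "numeric", converged = "logical",
              logLik = "numeric", nIter = "integer"))

setValidity("PriorModel", function(object) {
    msg <- character()
    if (object@pi0 < 0 || object@pi0 > 1) msg <- c(msg, "pi0 must lie in [0,1]")
    if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
    g <- object@grid
    if (!any(g == 0)) msg <- c(msg, "grid must contain 0")
    if (max(abs(sort(g) + rev(sort(g)))) > 1e-9)
        msg <- c(msg, "grid must be symmetric about 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PriorModel", function(object) {
    cat(sprintf("PriorModel: pi0 = %.4f, tau = %.4f (grid +/-%g, h = %g)%s\n",
                object@pi0, object@tau, max(object@grid), object@spacing,
                if (object@converged) "" else "  [EM not converged]"))
})

#' Spectral-count table for a two-condition proteome comparison
#'
#' Per-protein distinct-peptide support and raw spectral counts for the two
#' conditions, with optional normalized counts (equal-total scaling to the
#' mean library total; see [normalizeSpectralCounts()]).
#'
#' @slot proteinId Character vector of unique protein identifiers.
#' @slot peptides Integer vector: distinct peptide identifications per
#'   protein.
#' @slot counts Numeric matrix (proteins x 2) of raw spectral counts,
#'   columns named by condition (condition 1 = reference/replete,
#'   condition 2 = treatment/deficient).
#' @slot normalized Numeric matrix of normalized counts, or a 0-row matrix
#'   before normalization.
#'
#' @seealso [proteinCounts()], [filterByPeptides()], [fisherDifferential()]
#' @export
setClass("ProteinCounts",
    slots = c(proteinId = "character", peptides = "integer",
              counts = "matrix", normalized = "matrix"))

setValidity("ProteinCounts", function(object) {
    msg <- character()
    n <- length(object@proteinId)
    if (anyDuplicated(object@proteinId))
        msg <- c(msg, "protein ids must be unique")
    if (length(object@peptides) != n || nrow(object@counts) != n)
        msg <- c(msg, "peptides and counts must be parallel to proteinId")
    if (ncol(object@counts) != 2L)
        msg <- c(msg, "counts must have exactly two condition columns")
    if (n && any(object@counts < 0))
        msg <- c(msg, "spectral counts must be >= 0")
    if (n && any(object@peptides < 0))
        msg <- c(msg, "peptide counts must be >= 0")
    if (nrow(object@normalized) && nrow(object@normalized) != n)
        msg <- c(msg, "normalized matrix must be parallel to proteinId")
    if (length(msg)) msg else TRUE
})

setMethod("length", "ProteinCounts", function(x) length(x@proteinId))

setMethod("show", "ProteinCounts", function(object) {
    cat("ProteinCounts:", length(object), "proteins; raw totals",
        paste(colSums(object@counts), collapse = " / "),
        if (nrow(object@normalized)) "(normalized)" else "(raw only)", "\n")
})

#' Simulation configuration
#'
#' Parameters of the synthetic two-condition tag-seq + proteome experiment.
#' Defaults reproduce the study design the package targets: two pooled,
#' replicate-free libraries, incomplete NlaIII digestion, a minority of
#' antisense tags, and an attenuated, noisy protein response.
#'
#' @slot nGenes Number of protein-coding gene models.
#' @slot geneLengthRange Transcript length range (bp), uniform.
#' @slot intronRate Probability a gene carries one intron whose junction
#'   interrupts the 3'-most CATG 21-mer (making that transcript tag
#'   unmappable to the genome).
#' @slot nDeGenes Number of differentially expressed genes.
#' @slot log2fc True log2 fold changes (condition 2 : condition 1) assigned
#'   to DE genes, recycled over the DE set.
#' @slot baselineMeanlog,baselineSdlog Log-normal parameters of baseline
#'   transcript abundance.
#' @slot librarySizes Total tags sequenced (N1, N2).
#' @slot cleavageProb Per-site NlaIII cleavage probability c; the site of
#'   rank k from the 3' end emits with probability c(1-c)^(k-1).
#' @slot antisenseRate Probability a sampled tag is the opposite-strand
#'   21-mer at the same site.
#' @slot seqErrorRate Per-base substitution probability.
#' @slot enforceUniqueTags Regenerate genes whose canonical tag occurs
#'   elsewhere in the genome (either strand).
#' @slot seed Base RNG seed; each stage draws from an offset stream so
#'   stages are independently reproducible.
#'
#' @seealso [simConfig()], [generateReference()], [simulateTagLibraries()]
#' @export
setClass("SimConfig",
    slots = c(nGenes = "numeric", geneLengthRange = "numeric",
              intronRate = "numeric", nDeGenes = "numeric",
              log2fc = "numeric", baselineMeanlog = "numeric",
              baselineSdlog = "numeric", librarySizes = "numeric",
              cleavageProb = "numeric", antisenseRate = "numeric",
              seqErrorRate = "numeric", enforceUniqueTags = "logical",
              seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    p <- c(cleavage = object@cleavageProb, antisense = object@antisenseRate,
           error = object@seqErrorRate, intron = object@intronRate)
    if (any(p < 0 | p > 1))
        msg <- c(msg, "all rate parameters must lie in [0, 1]")
    if (object@nDeGenes > object@nGenes)
        msg <- c(msg, "nDeGenes must be <= nGenes")
    if (length(object@librarySizes) != 2L || any(object@librarySizes <= 0))
        msg <- c(msg, "librarySizes must be two positive totals")
    if (length(object@geneLengthRange) != 2L ||
        object@geneLengthRange[1] > object@geneLengthRange[2])
        msg <- c(msg, "geneLengthRange must be an increasing pair")
    if (object@geneLengthRange[1] < 21)
        msg <- c(msg, "genes shorter than 21 bp cannot carry a tag")
    if (object@nDeGenes > 0 && length(object@log2fc) == 0)
        msg <- c(msg, "log2fc must be non-empty when nDeGenes > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d genes (%d DE), libraries %s, ",
                       "c = %.2f, antisense = %.2f, error = %.3g, seed = %d\n"),
                object@nGenes, object@nDeGenes,
                paste(format(object@librarySizes, big.mark = ","),
                      collapse = " / "),
                object@cleavageProb, object@antisenseRate,
                object@seqErrorRate, as.integer(object@seed)))
})
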