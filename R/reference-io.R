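#' Read a reference genome from FASTA
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing the sequences and checking the alphabet (`A`, `C`, `G`, `T`,
#' `N` only). Sequence names are truncated at the first whitespace, as is
#' conventional for chromosome identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by chromosome id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
#' @importFrom Biostrings readDNAStringSet DNAStringSet
readGenome <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (any(nm == ""))
        stop("malformed FASTA header (empty id) in ", path)
    if (anyDuplicated(nm))
        stop("duplicate sequence id in ", path, ": ",
             nm[duplicated(nm)][1])
    if (any(lengths(seqs) == 0L))
        stop("empty sequence for record '", nm[lengths(seqs) == 0L][1], "'")
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- nm
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
    allowed <- c("A", "C", "G", "T", "N")
    other <- rowSums(af[, setdiff(colnames(af), allowed), drop = FALSE])
    if (any(other > 0))
        stop("sequence '", nm[other > 0][1],
             "' contains characters outside {A,C,G,T,N}")
    seqs
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path, format = "fasta", width = 70L)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` features (and their `exon` children, when present) from a
#' GFF3 file into a [GeneModelSet-class]. GFF3 coordinates are 1-based
#' inclusive and are kept as such internally. Genes without exon children
#' receive a single exon spanning the gene. Every gene must have an explicit
#' strand (`+` or `-`): tag assignment is strand-aware, so `.` is rejected.
#'
#' @param path Path to a GFF3 file with `gene` (and optional `exon`)
#'   features; the `ID` attribute of a gene is its `gene_id`, and exons
#'   reference their gene through `Parent`.
#' @return A `GeneModelSet`.
#' @export
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges GRangesList split
readGeneModels <- function(path) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    if (is.null(mcols(gr)$type)) stop("not a GFF3 file: ", path)
    genes <- gr[mcols(gr)$type == "gene"]
    if (length(genes) == 0L) stop("no gene features in ", path)
    ids <- as.character(mcols(genes)$ID)
    if (any(is.na(ids) | ids == ""))
        stop("every gene feature needs an ID attribute")
    if (anyDuplicated(ids))
        stop("duplicate gene ID: ", ids[duplicated(ids)][1])
    if (any(as.character(strand(genes)) == "*"))
        stop("strand required for tag assignment (found '.') for gene ",
             ids[as.character(strand(genes)) == "*"][1])
    exons <- gr[mcols(gr)$type == "exon"]
    geneModelSet(
        chrom = as.character(seqnames(genes)),
        start = start(genes), end = end(genes),
        strand = as.character(strand(genes)), geneId = ids,
        exonStarts = if (length(exons)) exonListFor(ids, exons, start) else NULL,
        exonEnds = if (length(exons)) exonListFor(ids, exons, end) else NULL)
}

exonListFor <- function(ids, exons, fun) {
    par <- as.character(unlist(mcols(exons)$Parent))
    if (length(par) != length(exons))
        stop("every exon must name exactly one Parent gene")
    lapply(ids, function(id) {
        e <- exons[par == id]
        if (length(e) == 0L) return(NULL)
        unname(fun(e)[order(start(e))])
    })
}

#' Construct a GeneModelSet from vectors
#'
#' @param chrom,start,end,strand,geneId Parallel vectors describing one gene
#'   per element (1-based inclusive coordinates).
#' @param exonStarts,exonEnds Optional lists, parallel to the genes, of exon
#'   start/end vectors; `NULL` entries get a single spanning exon.
#' @return A [GeneModelSet-class].
#' @export
geneModelSet <- function(chrom, start, end, strand, geneId,
                         exonStarts = NULL, exonEnds = NULL) {
    if (any(end < start))
        stop("gene end < start for gene ", geneId[which(end < start)[1]])
    g <- GRanges(chrom, IRanges(start, end), strand = strand)
    mcols(g)$gene_id <- as.character(geneId)
    n <- length(g)
    exl <- vector("list", n)
    for (i in seq_len(n)) {
        if (is.null(exonStarts) || is.null(exonStarts[[i]])) {
            exl[[i]] <- GRanges(chrom[i], IRanges(start[i], end[i]),
                                strand = strand[i])
        } else {
            exl[[i]] <- GRanges(chrom[i],
                                IRanges(exonStarts[[i]], exonEnds[[i]]),
                                strand = strand[i])
        }
    }
    exons <- GRangesList(exl)
    names(exons) <- geneId
    new("GeneModelSet", genes = g, exons = exons)
}

#' Write gene models to GFF3
#'
#' Emits `gene` and `exon` features with `ID`/`Parent` attributes; a
#' write-then-read round trip reproduces coordinates exactly.
#'
#' @param models A [GeneModelSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    g <- models@genes
    ids <- mcols(g)$gene_id
    lines <- c("##gff-version 3")
    for (i in seq_along(g)) {
        ch <- as.character(seqnames(g))[i]
        st <- as.character(strand(g))[i]
        lines <- c(lines, paste(ch, "tagProteo", "gene", start(g)[i],
                                end(g)[i], ".", st, ".",
                                paste0("ID=", ids[i]), sep = "\t"))
        ex <- models@exons[[i]]
        for (j in seq_along(ex)) {
            lines <- c(lines, paste(ch, "tagProteo", "exon", start(ex)[j],
                                    end(ex)[j], ".", st, ".",
                                    paste0("ID=", ids[i], ".exon", j,
                                           ";Parent=", ids[i]), sep = "\t"))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Extend gene models into the 3' UTR
#'
#' Returns a copy of the models with each gene's 3' end pushed outward by
#' `lengthBp` bases: `+` strand genes grow at their right edge (clipped at
#' the chromosome end), `-` strand genes at their left edge (clipped at 1).
#' The extension is appended to the 3'-most exon. Extensions are not clipped
#' at neighbouring genes; overlapping extended models are permitted and any
#' resulting assignment ties are resolved downstream (see
#' [assignToGenes()]).
#'
#' @param models A [GeneModelSet-class].
#' @param lengthBp Non-negative extension length in bp.
#' @param genome The genome `DNAStringSet` (for chromosome lengths).
#' @return A new `GeneModelSet`; the input is untouched.
#' @export
extendThreePrime <- function(models, lengthBp, genome) {
    stopifnot(lengthBp >= 0)
    g <- models@genes
    chroms <- as.character(seqnames(g))
    unknown <- setdiff(chroms, names(genome))
    if (length(unknown))
        stop("model references unknown chromosome: ", unknown[1])
    if (lengthBp == 0) return(models)
    chrLen <- stats::setNames(lengths(genome), names(genome))[chroms]
    plus <- as.character(strand(g)) == "+"
    newStart <- ifelse(plus, start(g), pmax(start(g) - lengthBp, 1L))
    newEnd <- ifelse(plus, pmin(end(g) + lengthBp, chrLen), end(g))
    ids <- mcols(g)$gene_id
    exl <- vector("list", length(g))
    for (i in seq_along(g)) {
        ex <- models@exons[[i]]
        if (plus[i]) {
            end(ex)[length(ex)] <- newEnd[i]
        } else {
            start(ex)[1] <- newStart[i]
        }
        exl[[i]] <- ex
    }
    geneModelSet(chroms, newStart, newEnd, as.character(strand(g)), ids,
                 exonStarts = lapply(exl, start),
                 exonEnds = lapply(exl, end))
}

#' Spliced transcript sequences of gene models
#'
#' Concatenates each gene's exon sequences in genomic order and reverse
#' complements the result for `-` strand genes, yielding the mature
#' transcript 5' to 3'.
#'
#' @param models A [GeneModelSet-class].
#' @param genome A named `DNAStringSet`.
#' @return A `DNAStringSet` named by gene id.
#' @export
#' @importFrom Biostrings reverseComplement DNAString
transcriptSequences <- function(models, genome) {
    g <- models@genes
    chroms <- as.character(seqnames(g))
    unknown <- setdiff(chroms, names(genome))
    if (length(unknown))
        stop("model references unknown chromosome: ", unknown[1])
    minus <- as.character(strand(g)) == "-"
    seqs <- character(length(g))
    chrChar <- stats::setNames(as.character(genome), names(genome))
    for (i in seq_along(g)) {
        ex <- models@exons[[i]]
        parts <- substring(chrChar[[chroms[i]]], start(ex), end(ex))
        seqs[i] <- paste(parts, collapse = "")
    }
    out <- Biostrings::DNAStringSet(seqs)
    if (any(minus))
        out[minus] <- Biostrings::reverseComplement(out[minus])
    names(out) <- mcols(g)$gene_id
    out
}
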