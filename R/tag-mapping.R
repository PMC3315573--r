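#' Build an exact 21-mer tag index of a genome
#'
#' Indexes, for every genomic `CATG` on either strand, the 21-mer read
#' 5' to 3' on that strand starting at the anchor. Because `CATG` is its own
#' reverse complement, every site exists on both strands: the forward-strand
#' window at anchor position `p` covers `[p, p+20]`, and the reverse-strand
#' window (whose anchor `C` pairs with the forward base at `p+3`) covers
#' `[p-17, p+3]` read on the reverse strand. Windows truncated by a
#' chromosome end are skipped (not indexed). Positions are 1-based anchor-C
#' coordinates on the forward axis.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A `data.table` keyed by `tag` with columns `tag`, `chrom`,
#'   `pos`, `strand`, one row per indexed site.
#' @seealso [mapTags()]
#' @export
#' @import data.table
buildTagIndex <- function(genome) {
    if (is.null(names(genome)) || anyDuplicated(names(genome)))
        stop("genome must be uniquely named")
    pieces <- vector("list", 2L * length(genome))
    k <- 0L
    for (ch in names(genome)) {
        s <- as.character(genome[[ch]])
        len <- nchar(s)
        anchors <- findNlaIIISites(s)
        # forward-strand windows [p, p+20]
        fwd <- anchors[anchors + TAG_LEN - 1L <= len]
        if (length(fwd)) {
            k <- k + 1L
            pieces[[k]] <- data.table::data.table(
                tag = substring(s, fwd, fwd + TAG_LEN - 1L),
                chrom = ch, pos = fwd, strand = "+")
        }
        # reverse-strand windows [p-17, p+3], anchor C at p+3
        rev <- anchors[anchors - (TAG_LEN - 4L) >= 1L]
        if (length(rev)) {
            win <- substring(s, rev - (TAG_LEN - 4L), rev + 3L)
            k <- k + 1L
            pieces[[k]] <- data.table::data.table(
                tag = as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(win))),
                chrom = ch, pos = rev + 3L, strand = "-")
        }
    }
    idx <- data.table::rbindlist(pieces[seq_len(k)])
    if (nrow(idx) == 0L)
        idx <- data.table::data.table(tag = character(0), chrom = character(0),
                                      pos = integer(0), strand = character(0))
    idx <- unique(idx)
    data.table::setkeyv(idx, "tag")
    idx[]
}

#' Map a tag library to an indexed genome
#'
#' Exact lookup only (100% identity over all 21 nt; no mismatches). Tags
#' hitting two or more genomic locations -- strand-distinct hits count as
#' distinct locations -- are flagged `multi_mapped` and excluded from all
#' downstream gene counts; tags with no hit are `unmapped` but retained for
#' reporting.
#'
#' @param lib A [TagLibrary-class].
#' @param index Index from [buildTagIndex()] on the same genome.
#' @return A `data.table` with one row per unique tag: `tag`, `count`,
#'   `nloc` (number of genomic locations), and for uniquely mapped tags
#'   `chrom`, `pos`, `strand` (NA otherwise).
#' @export
mapTags <- function(lib, index) {
    stopifnot(is(lib, "TagLibrary"))
    validObject(lib)
    tags <- data.table::data.table(tag = lib@tags, count = lib@counts)
    locs <- index[tags$tag, on = "tag", nomatch = NULL]
    nloc <- locs[, list(nloc = .N), by = "tag"]
    uniq <- locs[locs$tag %in% nloc$tag[nloc$nloc == 1L]]
    out <- merge(tags, nloc, by = "tag", all.x = TRUE)
    out$nloc[is.na(out$nloc)] <- 0L
    out <- merge(out, uniq, by = "tag", all.x = TRUE)
    data.table::setkeyv(out, "tag")
    out[]
}

#' Assign mapped tags to gene models
#'
#' Implements the tag-accounting rules of the pipeline: a uniquely mapped
#' tag whose anchor falls inside a model's (optionally 3'-extended) span on
#' the model's strand is `gene_sense` and its reads are pooled into that
#' gene's count; the same position on the opposite strand is
#' `gene_antisense` (tallied, never counted toward the gene); a hit inside
#' no model is `intergenic` (with its distance to the nearest model 3' end
#' recorded); multi-location tags are `multi_mapped` and unplaceable tags
#' `unmapped`. A hit inside two same-strand overlapping models goes to the
#' model whose 3' end is nearest (tag-seq signal is 3'-anchored); an exact
#' tie is excluded and tallied `ambiguous`. Read tallies over all categories
#' partition the library total exactly.
#'
#' @param hits Mapping table from [mapTags()].
#' @param lib The [TagLibrary-class] that produced `hits`.
#' @param models A [GeneModelSet-class], optionally pre-extended.
#' @param utrExtensionBp Extension to apply to `models` before assignment
#'   (0 = use them as given); requires `genome` when non-zero.
#' @param genome Genome `DNAStringSet` (only needed when
#'   `utrExtensionBp > 0`, for chromosome-end clipping).
#' @return An [AssignmentReport-class].
#' @export
#' @importFrom GenomicRanges findOverlaps resize
#' @importFrom S4Vectors queryHits subjectHits
assignToGenes <- function(hits, lib, models, utrExtensionBp = 0,
                          genome = NULL) {
    if (utrExtensionBp > 0) {
        if (is.null(genome))
            stop("genome required to clip a non-zero 3' extension")
        models <- extendThreePrime(models, utrExtensionBp, genome)
    }
    g <- models@genes
    ids <- mcols(g)$gene_id
    ht <- data.table::copy(hits)
    ht$category <- ifelse(ht$nloc == 0L, "unmapped",
                   ifelse(ht$nloc >= 2L, "multi_mapped", NA_character_))
    ht$gene_id <- NA_character_
    ht$dist3p <- NA_real_
    um <- which(ht$nloc == 1L)
    if (length(um)) {
        pts <- GRanges(ht$chrom[um], IRanges(ht$pos[um], width = 1L),
                       strand = ht$strand[um])
        ov <- findOverlaps(pts, g, ignore.strand = TRUE)
        qh <- queryHits(ov); sh <- subjectHits(ov)
        sameStrand <- as.character(strand(pts))[qh] ==
            as.character(strand(g))[sh]
        # 3' end coordinate of each model
        plus <- as.character(strand(g)) == "+"
        end3 <- ifelse(plus, end(g), start(g))
        # sense assignment with nearest-3'-end tie-break (vectorized)
        if (any(sameStrand)) {
            sv <- data.table::data.table(
                q = qh[sameStrand], gene = sh[sameStrand],
                d = abs(end3[sh[sameStrand]] - ht$pos[um[qh[sameStrand]]]))
            pick <- sv[, {
                w <- which(d == min(d))
                list(gene = gene[w[1]], tie = length(w) > 1L)
            }, by = "q"]
            ok <- !pick$tie
            ht$category[um[pick$q[ok]]] <- "gene_sense"
            ht$gene_id[um[pick$q[ok]]] <- ids[pick$gene[ok]]
            ht$category[um[pick$q[!ok]]] <- "ambiguous"
        }
        senseQ <- unique(qh[sameStrand])
        antiQ <- setdiff(unique(qh), senseQ)
        ht$category[um[antiQ]] <- "gene_antisense"
        interQ <- setdiff(seq_along(um), unique(qh))
        if (length(interQ)) {
            ht$category[um[interQ]] <- "intergenic"
            # distance from the tag anchor to the nearest model 3' end
            # (direct base distance, not the gap convention)
            gChrom <- as.character(seqnames(g))
            for (ch in unique(ht$chrom[um[interQ]])) {
                e3 <- sort(end3[gChrom == ch])
                qq <- interQ[ht$chrom[um[interQ]] == ch]
                if (length(e3) == 0L) next
                pos <- ht$pos[um[qq]]
                lo <- findInterval(pos, e3)
                dLo <- ifelse(lo >= 1L, pos - e3[pmax(lo, 1L)], Inf)
                dHi <- ifelse(lo < length(e3),
                              e3[pmin(lo + 1L, length(e3))] - pos, Inf)
                ht$dist3p[um[qq]] <- pmin(dLo, dHi)
            }
        }
    }
    cats <- c("gene_sense", "gene_antisense", "intergenic",
              "multi_mapped", "unmapped", "ambiguous")
    reads <- vapply(cats, function(cc) sum(ht$count[ht$category == cc]),
                    numeric(1))
    ntags <- vapply(cats, function(cc) sum(ht$category == cc), numeric(1))
    gc <- stats::setNames(numeric(length(ids)), ids)
    sel <- ht$category == "gene_sense"
    if (any(sel)) {
        agg <- tapply(ht$count[sel], ht$gene_id[sel], sum)
        gc[names(agg)] <- agg
    }
    new("AssignmentReport", condition = lib@condition,
        tagTable = DataFrame(tag = ht$tag, count = ht$count,
                             category = ht$category, gene_id = ht$gene_id,
                             chrom = ht$chrom, pos = ht$pos,
                             strand = ht$strand, dist3p = ht$dist3p),
        categoryReads = reads, categoryTags = ntags, geneCounts = gc,
        total = lib@total, utrExtension = as.numeric(utrExtensionBp))
}

#' Mapping summary across two 3'-extension settings
#'
#' Compares two [AssignmentReport-class]s of the same library that differ
#' only in the 3'-UTR extension applied to the gene models, and reports the
#' headline tag-accounting fractions: reads mapped, unique tags mapped,
#' mapped reads falling in gene models at each extension, and the gain from
#' extending. Because "the percentage increases by X%" is ambiguous between
#' percentage points and relative change, both are reported.
#'
#' @param reportExt0 Report with no extension.
#' @param reportExt Report with the extension of interest (e.g. 200 bp).
#' @return A named list of fractions (0-1 scale) and the two gain measures.
#' @export
mappingSummary <- function(reportExt0, reportExt) {
    if (!isTRUE(all.equal(reportExt0@total, reportExt@total)))
        stop("reports are not on the same library (totals differ)")
    if (reportExt0@total == 0) stop("empty library")
    mappedCats <- c("gene_sense", "gene_antisense", "intergenic", "ambiguous")
    readFrac <- function(r, cats) sum(r@categoryReads[cats]) / r@total
    tagFrac <- function(r, cats)
        sum(r@categoryTags[cats]) / sum(r@categoryTags)
    inGene0 <- sum(reportExt0@categoryReads[c("gene_sense", "gene_antisense",
                                              "ambiguous")]) /
        sum(reportExt0@categoryReads[mappedCats])
    inGeneX <- sum(reportExt@categoryReads[c("gene_sense", "gene_antisense",
                                             "ambiguous")]) /
        sum(reportExt@categoryReads[mappedCats])
    list(
        reads_mapped = readFrac(reportExt0, mappedCats),
        unique_tags_mapped = tagFrac(reportExt0, mappedCats),
        in_gene_ext0 = inGene0,
        in_gene_ext = inGeneX,
        gain_points = inGeneX - inGene0,
        gain_relative = if (inGene0 > 0) (inGeneX - inGene0) / inGene0
                        else NA_real_,
        utr_extension = reportExt@utrExtension)
}

#' Per-gene count table from two assignment reports
#'
#' Joins the pooled sense counts of the two conditions over the shared gene
#' universe and adds tags-per-million columns.
#'
#' @param reportA,reportB Reports for condition 1 and condition 2 built
#'   against the same gene models.
#' @return A `data.frame` with `gene_id`, `x1`, `x2`, `tpm1`, `tpm2`, and
#'   attributes `N1`, `N2` (library totals).
#' @export
geneCountTable <- function(reportA, reportB) {
    if (!identical(names(reportA@geneCounts), names(reportB@geneCounts)))
        stop("reports were built against different gene model sets")
    df <- data.frame(gene_id = names(reportA@geneCounts),
                     x1 = as.numeric(reportA@geneCounts),
                     x2 = as.numeric(reportB@geneCounts))
    df$tpm1 <- normalizeTpm(df$x1, reportA@total)
    df$tpm2 <- normalizeTpm(df$x2, reportB@total)
    attr(df, "N1") <- reportA@total
    attr(df, "N2") <- reportB@total
    df
}
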