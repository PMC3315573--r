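#' Create a simulation configuration
#'
#' Defaults describe the study design the pipeline targets: ~11,000 gene
#' models on a compact genome, two pooled replicate-free libraries of 12
#' million tags each, incomplete NlaIII digestion (per-site cleavage
#' probability 0.8), a 10% antisense tag fraction and a small per-base
#' sequencing error rate. Desk-scale analyses pass smaller `nGenes` /
#' `librarySizes` explicitly.
#'
#' @param nGenes Number of gene models.
#' @param geneLengthRange Uniform transcript length range (bp).
#' @param intronRate Probability a gene carries one intron whose junction
#'   splits the 3'-most CATG 21-mer.
#' @param nDeGenes Number of differentially expressed genes.
#' @param log2fc True log2 fold changes (condition 2 : condition 1)
#'   recycled over the DE genes.
#' @param baselineMeanlog,baselineSdlog Log-normal baseline abundance
#'   parameters.
#' @param librarySizes Total tags per library, `(N1, N2)`.
#' @param cleavageProb Per-site cleavage probability `c`.
#' @param antisenseRate Probability `a` of emitting the opposite-strand
#'   21-mer.
#' @param seqErrorRate Per-base substitution probability `e`.
#' @param enforceUniqueTags Regenerate genes whose canonical tag is not
#'   genome-unique.
#' @param seed Base RNG seed.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 11242, geneLengthRange = c(300, 2000),
                      intronRate = 0.05, nDeGenes = 300,
                      log2fc = rep(c(-3, -2, -1, 1, 2, 3), length.out =
                                       max(nDeGenes, 1)),
                      baselineMeanlog = 0, baselineSdlog = 1,
                      librarySizes = c(12e6, 12e6), cleavageProb = 0.8,
                      antisenseRate = 0.1, seqErrorRate = 0.005,
                      enforceUniqueTags = TRUE, seed = 1) {
    new("SimConfig", nGenes = nGenes, geneLengthRange = geneLengthRange,
        intronRate = intronRate, nDeGenes = nDeGenes,
        log2fc = as.numeric(log2fc), baselineMeanlog = baselineMeanlog,
        baselineSdlog = baselineSdlog, librarySizes = librarySizes,
        cleavageProb = cleavageProb, antisenseRate = antisenseRate,
        seqErrorRate = seqErrorRate,
        enforceUniqueTags = enforceUniqueTags, seed = seed)
}

# Stage-keyed RNG: each simulation stage draws from its own stream derived
# from (seed, stage name), so stages are independently reproducible.
stageSeed <- function(seed, stage) {
    offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChar <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A transcript is admissible when it has >=1 CATG and its 3'-most anchor
# leaves the full 17 nt downstream (canonical tag needs no poly-A padding).
drawTranscript <- function(lenRange) {
    len <- sample(seq(lenRange[1], lenRange[2]), 1L)
    for (try in 1:50) {
        s <- randomDna(len)
        sites <- findNlaIIISites(s)
        if (length(sites) &&
            sites[length(sites)] + TAG_LEN - 1L <= len) return(s)
    }
    # force-plant an anchor away from the 3' end and strip later anchors
    at <- max(1L, len - 40L)
    s <- paste0(substr(s, 1L, at - 1L), ANCHOR, substr(s, at + 4L, len))
    tail <- substr(s, at + 4L, len)
    while (grepl("CATG", tail, fixed = TRUE))
        tail <- sub("CATG", "CATC", tail, fixed = TRUE)
    paste0(substr(s, 1L, at + 3L), tail)
}

#' Generate a synthetic reference genome, gene models and ground truth
#'
#' Builds i.i.d.-uniform background chromosomes carrying `nGenes` gene
#' loci separated by random intergenic spacers. Every transcript contains
#' at least one NlaIII site with a full 17 nt downstream of the 3'-most
#' anchor, so a canonical tag always exists. With probability `intronRate`
#' a gene carries one intron whose junction is placed 10 bp into the
#' 3'-most CATG 21-mer, making the canonical transcript tag unmappable to
#' the genome (the splice-junction tag class). With `enforceUniqueTags`,
#' genes whose canonical 21-mer occurs more than once in the genome (either
#' strand) are regenerated in place. Fully reproducible from
#' `config@seed`.
#'
#' @param config A [SimConfig-class].
#' @return A list: `genome` (`DNAStringSet`), `models`
#'   ([GeneModelSet-class]) and `truth`, a `data.frame` with per-gene
#'   `gene_id`, `chrom`, `strand`, `abundance1`, `abundance2`, `delta`
#'   (0 for non-DE genes), `canonical_tag`, `n_sites` and `has_intron`.
#' @export
generateReference <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(stageSeed(config@seed, "reference"))
    n <- as.integer(config@nGenes)
    genesPerChrom <- 100L
    nChrom <- as.integer(ceiling(n / genesPerChrom))
    intronLenRange <- c(60L, 120L)

    makeGene <- function() {
        tx <- drawTranscript(config@geneLengthRange)
        hasIntron <- stats::runif(1) < config@intronRate
        if (!hasIntron)
            return(list(tx = tx, genomic = tx, exonOffsets = NULL,
                        hasIntron = FALSE))
        sites <- findNlaIIISites(tx)
        sites <- sites[sites + TAG_LEN - 1L <= nchar(tx)]
        anchor <- sites[length(sites)]
        cut <- anchor + 9L          # junction splits the canonical 21-mer
        intron <- randomDna(sample(seq(intronLenRange[1], intronLenRange[2]),
                                   1L))
        genomic <- paste0(substr(tx, 1L, cut), intron,
                          substr(tx, cut + 1L, nchar(tx)))
        # exon coordinates within the genomic (sense) sequence
        exonOffsets <- rbind(c(1L, cut),
                             c(cut + nchar(intron) + 1L, nchar(genomic)))
        list(tx = tx, genomic = genomic, exonOffsets = exonOffsets,
             hasIntron = TRUE)
    }

    geneList <- replicate(n, makeGene(), simplify = FALSE)
    strandVec <- sample(c("+", "-"), n, replace = TRUE)
    chromOf <- rep(seq_len(nChrom), each = genesPerChrom)[seq_len(n)]
    gapLen <- function() sample(100:300, 1L)

    assemble <- function() {
        chromSeq <- character(nChrom)
        meta <- vector("list", n)
        for (ci in seq_len(nChrom)) {
            parts <- character(0)
            cursor <- 0L
            for (gi in which(chromOf == ci)) {
                gap <- randomDna(gapLen())
                parts <- c(parts, gap)
                cursor <- cursor + nchar(gap)
                gl <- geneList[[gi]]
                gs <- if (strandVec[gi] == "+") gl$genomic
                      else revcompChar(gl$genomic)
                gStart <- cursor + 1L
                gEnd <- cursor + nchar(gs)
                ex <- gl$exonOffsets
                if (is.null(ex)) {
                    exS <- gStart; exE <- gEnd
                } else if (strandVec[gi] == "+") {
                    exS <- gStart + ex[, 1] - 1L
                    exE <- gStart + ex[, 2] - 1L
                } else {
                    # mirror sense offsets onto the forward axis
                    L <- nchar(gl$genomic)
                    exS <- rev(gStart + (L - ex[, 2]))
                    exE <- rev(gStart + (L - ex[, 1]))
                }
                meta[[gi]] <- list(chrom = paste0("chr", ci),
                                   start = gStart, end = gEnd,
                                   exS = exS, exE = exE)
                parts <- c(parts, gs)
                cursor <- gEnd
            }
            parts <- c(parts, randomDna(gapLen()))
            chromSeq[ci] <- paste(parts, collapse = "")
        }
        list(chromSeq = chromSeq, meta = meta)
    }

    asm <- assemble()
    canonical <- vapply(geneList, function(g) canonicalTag(g$tx),
                        character(1))
    if (config@enforceUniqueTags) {
        for (round in 1:10) {
            genome <- Biostrings::DNAStringSet(asm$chromSeq)
            names(genome) <- paste0("chr", seq_len(nChrom))
            hits <- countTagOccurrences(canonical, genome)
            # > 1 genomic occurrence breaks uniqueness; intron genes'
            # canonical tags span a junction and legitimately have 0
            dup <- which(hits > 1L | duplicated(canonical) |
                             duplicated(canonical, fromLast = TRUE))
            if (length(dup) == 0L) break
            for (gi in dup) {
                geneList[[gi]] <- makeGene()
                canonical[gi] <- canonicalTag(geneList[[gi]]$tx)
            }
            asm <- assemble()
            if (round == 10L)
                stop("could not achieve genome-unique canonical tags; ",
                     "reduce nGenes or lengthen genes")
        }
    }
    genome <- Biostrings::DNAStringSet(asm$chromSeq)
    names(genome) <- paste0("chr", seq_len(nChrom))

    ids <- sprintf("g%05d", seq_len(n))
    models <- geneModelSet(
        chrom = vapply(asm$meta, `[[`, character(1), "chrom"),
        start = vapply(asm$meta, `[[`, numeric(1), "start"),
        end = vapply(asm$meta, `[[`, numeric(1), "end"),
        strand = strandVec, geneId = ids,
        exonStarts = lapply(asm$meta, `[[`, "exS"),
        exonEnds = lapply(asm$meta, `[[`, "exE"))

    ab1 <- stats::rlnorm(n, config@baselineMeanlog, config@baselineSdlog)
    delta <- numeric(n)
    if (config@nDeGenes > 0) {
        de <- sample(n, config@nDeGenes)
        delta[de] <- rep(config@log2fc,
                         length.out = config@nDeGenes)
    }
    truth <- data.frame(
        gene_id = ids,
        chrom = vapply(asm$meta, `[[`, character(1), "chrom"),
        strand = strandVec,
        abundance1 = ab1, abundance2 = ab1 * 2^delta, delta = delta,
        canonical_tag = canonical,
        n_sites = vapply(geneList, function(g)
            length(findNlaIIISites(g$tx)), numeric(1)),
        has_intron = vapply(geneList, `[[`, logical(1), "hasIntron"))
    list(genome = genome, models = models, truth = truth)
}

# occurrences of each 21-mer in the genome, both strands
countTagOccurrences <- function(tags, genome) {
    idx <- buildTagIndex(genome)
    tab <- idx[, list(n = .N), by = "tag"]
    out <- tab$n[match(tags, tab$tag)]
    out[is.na(out)] <- 0L
    out
}

#' Simulate two-condition tag libraries
#'
#' Emulates the tag-seq protocol on the synthetic reference. Each
#' transcript molecule has every NlaIII site cut independently with
#' probability `c`; the emitted tag is the 21-mer at the 3'-most cut site,
#' so the site of rank k from the 3' end emits with probability
#' `c(1-c)^(k-1)` (molecules with no cut are undigested and emit nothing).
#' With probability `a` the emitted tag is the opposite-strand 21-mer
#' anchored at the same site (sites closer than 17 nt to the transcript
#' 5' end always emit sense). Per-gene expected proportions are
#' proportional to true abundance (`abundance2 = abundance1 * 2^delta` for
#' DE genes); tag counts are drawn multinomially conditioned on the exact
#' library totals `N1`, `N2`. Finally each base of each read is substituted
#' with probability `e`.
#'
#' @param reference Output of [generateReference()].
#' @param config The same [SimConfig-class].
#' @return A list: `libA`, `libB` ([TagLibrary-class]s), and `emission`, a
#'   `data.table` of the pre-error emission truth (`gene_id`, `rank`,
#'   `orientation`, `tag`, `count_A`, `count_B`) used for digestion-law and
#'   recovery checks.
#' @export
simulateTagLibraries <- function(reference, config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(stageSeed(config@seed, "tags"))
    truth <- reference$truth
    txs <- transcriptSequences(reference$models, reference$genome)
    cProb <- config@cleavageProb
    aRate <- config@antisenseRate

    cats <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
        tx <- as.character(txs[[truth$gene_id[i]]])
        et <- allExpectedTags(tx)
        if (nrow(et) == 0L) next  # undigested gene: emits nothing
        pSite <- cProb * (1 - cProb)^(et$rank - 1)
        canAnti <- et$site >= (TAG_LEN - 3L)   # needs 17 nt upstream
        anti <- vapply(seq_len(nrow(et)), function(j) {
            if (!canAnti[j]) return(NA_character_)
            revcompChar(substr(tx, et$site[j] - (TAG_LEN - 4L),
                               et$site[j] + 3L))
        }, character(1))
        aEff <- ifelse(canAnti, aRate, 0)
        cats[[i]] <- data.table::data.table(
            gene_id = truth$gene_id[i], rank = et$rank,
            orientation = rep(c("sense", "antisense"), each = nrow(et)),
            tag = c(et$tag, anti),
            w = c(pSite * (1 - aEff), pSite * aEff))
    }
    cat_dt <- data.table::rbindlist(cats)
    cat_dt <- cat_dt[cat_dt$w > 0]
    ab1 <- truth$abundance1[match(cat_dt$gene_id, truth$gene_id)]
    ab2 <- truth$abundance2[match(cat_dt$gene_id, truth$gene_id)]
    p1 <- cat_dt$w * ab1; p1 <- p1 / sum(p1)
    p2 <- cat_dt$w * ab2; p2 <- p2 / sum(p2)
    N <- config@librarySizes
    cat_dt$count_A <- as.numeric(stats::rmultinom(1L, N[1], p1))
    cat_dt$count_B <- as.numeric(stats::rmultinom(1L, N[2], p2))
    emission <- cat_dt[, c("gene_id", "rank", "orientation", "tag",
                           "count_A", "count_B")]

    libFrom <- function(col, label) {
        counts <- applySequencingError(emission$tag, emission[[col]],
                                       config@seqErrorRate)
        tagLibrary(names(counts), as.numeric(counts), label)
    }
    list(libA = libFrom("count_A", "replete"),
         libB = libFrom("count_B", "deficient"),
         emission = emission)
}

# Substitute each of the 17 variable bases of each read independently with
# probability e (the CATG anchor is protocol-defined: reads without it are
# never tabulated as tags, so errors are modelled on the variable bases).
# Reads are not expanded: only the Binomial(n, 1-(1-e)^17) reads carrying
# at least one error are materialized individually.
applySequencingError <- function(tags, counts, e) {
    keep <- counts > 0
    tags <- tags[keep]; counts <- counts[keep]
    nVar <- TAG_LEN - 4L
    agg <- function(tg, ct) {
        dt <- data.table::data.table(tag = tg, n = ct)
        dt <- dt[, list(n = sum(n)), by = "tag"]
        dt <- dt[dt$n > 0]
        data.table::setkeyv(dt, "tag")
        stats::setNames(dt$n, dt$tag)
    }
    if (e <= 0 || length(tags) == 0L) return(agg(tags, counts))
    pErr <- 1 - (1 - e)^nVar
    nErr <- stats::rbinom(length(tags), counts, pErr)
    clean <- counts - nErr
    tot <- sum(nErr)
    if (tot == 0L) return(agg(tags, clean))
    src <- rep(tags, nErr)
    # substitutions per read, conditioned on >= 1
    kProbs <- stats::dbinom(seq_len(nVar), nVar, e)
    k <- sample(nVar, tot, replace = TRUE, prob = kProbs)
    bases <- c("A", "C", "G", "T")
    one <- which(k == 1L)          # vast majority at realistic e
    if (length(one)) {
        pos <- 4L + sample.int(nVar, length(one), replace = TRUE)
        shift <- sample.int(3L, length(one), replace = TRUE)
        old <- substr(src[one], pos, pos)
        newBase <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
        substr(src[one], pos, pos) <- newBase
    }
    multi <- which(k > 1L)
    for (r in multi) {
        pos <- 4L + sample.int(nVar, k[r])
        for (p in pos) {
            old <- substr(src[r], p, p)
            substr(src[r], p, p) <- sample(setdiff(bases, old), 1L)
        }
    }
    agg(c(tags, src), c(clean, rep(1, tot)))
}

#' Simulate a correlated spectral-count table
#'
#' Generates the proteome companion of a transcript simulation: protein
#' log2 fold change = `slope * delta + intercept * 1{delta != 0} +
#' Normal(0, noiseSd)` -- an attenuated, noisy function of the transcript
#' response. Only the top `detectTopFrac` of genes by mean abundance are
#' detected (LC-MS sees the abundant proteins). Spectral counts per
#' condition are Poisson with means proportional to abundance scaled to
#' `depth` total expected counts in condition 1; distinct-peptide support
#' is at least 1, with a configurable fraction of single-peptide proteins
#' to exercise the peptide filter.
#'
#' @param truth Truth table from [generateReference()].
#' @param slope,intercept Protein-vs-transcript fold-change relation
#'   (defaults: the attenuated relation the pipeline is designed to
#'   recover; the intercept applies to DE genes only).
#' @param noiseSd SD of the protein-level log2 noise.
#' @param detectTopFrac Fraction of genes detected as proteins, `(0, 1]`.
#' @param depth Expected total spectral counts in condition 1.
#' @param singletonFrac Fraction of detected proteins with exactly one
#'   peptide.
#' @param seed RNG seed.
#' @return A [ProteinCounts-class] with attribute `protein_truth` (a
#'   `data.frame` of the planted protein fold changes).
#' @export
simulateSpectralCounts <- function(truth, slope = 0.49, intercept = -0.25,
                                   noiseSd = 0.3, detectTopFrac = 0.11,
                                   depth = 25000, singletonFrac = 0.2,
                                   seed = 1) {
    if (detectTopFrac <= 0 || detectTopFrac > 1)
        stop("detectTopFrac must lie in (0, 1]")
    set.seed(stageSeed(seed, "proteins"))
    nDet <- max(1L, floor(nrow(truth) * detectTopFrac))
    meanAb <- (truth$abundance1 + truth$abundance2) / 2
    det <- order(meanAb, decreasing = TRUE)[seq_len(nDet)]
    det <- det[order(det)]
    delta <- truth$delta[det]
    pFold <- slope * delta + intercept * (delta != 0) +
        stats::rnorm(nDet, 0, noiseSd)
    ab <- truth$abundance1[det]
    mu1 <- ab / sum(ab) * depth
    mu2 <- mu1 * 2^pFold
    s1 <- stats::rpois(nDet, mu1)
    s2 <- stats::rpois(nDet, mu2)
    peptides <- ifelse(stats::runif(nDet) < singletonFrac, 1L,
                       2L + stats::rpois(nDet, 3))
    out <- proteinCounts(truth$gene_id[det], peptides, s1, s2)
    attr(out, "protein_truth") <- data.frame(
        protein_id = truth$gene_id[det], delta = delta,
        protein_log2fc = pFold)
    out
}

#' Write the full synthetic data set to disk
#'
#' Emits the artifact set a real experiment would provide: `genome.fa`,
#' `models.gff3`, `tags_A.tsv`, `tags_B.tsv`, `spectral.tsv` and
#' `truth.tsv`.
#'
#' @param reference Output of [generateReference()].
#' @param libs Output of [simulateTagLibraries()].
#' @param proteins A [ProteinCounts-class] from
#'   [simulateSpectralCounts()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
writeSimulatedData <- function(reference, libs, proteins, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               models = file.path(dir, "models.gff3"),
               tags_A = file.path(dir, "tags_A.tsv"),
               tags_B = file.path(dir, "tags_B.tsv"),
               spectral = file.path(dir, "spectral.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeGenome(reference$genome, paths["genome"])
    writeGeneModels(reference$models, paths["models"])
    writeTagLibrary(libs$libA, paths["tags_A"])
    writeTagLibrary(libs$libB, paths["tags_B"])
    writeProteinCounts(proteins, paths["spectral"])
    utils::write.table(reference$truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths
}
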