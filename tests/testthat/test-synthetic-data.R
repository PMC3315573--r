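test_that("reference generation is reproducible and canonical tags map uniquely", {
    cfg <- simConfig(nGenes = 40, nDeGenes = 5, log2fc = c(-2, 2),
                     librarySizes = c(5e4, 5e4), intronRate = 0,
                     seed = 21)
    ref1 <- generateReference(cfg)
    ref2 <- generateReference(cfg)
    expect_identical(as.character(ref1$genome), as.character(ref2$genome))
    expect_identical(ref1$truth, ref2$truth)
    # byte-identical artifacts from the same seed
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeGenome(ref1$genome, file.path(d1, "g.fa"))
    writeGenome(ref2$genome, file.path(d2, "g.fa"))
    writeGeneModels(ref1$models, file.path(d1, "m.gff3"))
    writeGeneModels(ref2$models, file.path(d2, "m.gff3"))
    expect_identical(readLines(file.path(d1, "g.fa")),
                     readLines(file.path(d2, "g.fa")))
    expect_identical(readLines(file.path(d1, "m.gff3")),
                     readLines(file.path(d2, "m.gff3")))
    # enforce_unique_tags: every canonical tag occurs exactly once in the
    # genome (exhaustive both-strand scan) and within its own gene
    for (i in seq_len(nrow(ref1$truth))) {
        locs <- naiveTagLocations(ref1$truth$canonical_tag[i], ref1$genome)
        expect_equal(nrow(locs), 1L)
        gr <- geneRanges(ref1$models)[i]
        expect_equal(locs$chrom, as.character(GenomicRanges::seqnames(gr)))
        expect_gte(locs$pos, GenomicRanges::start(gr))
        expect_lte(locs$pos, GenomicRanges::end(gr))
        expect_equal(locs$strand, ref1$truth$strand[i])
    }
    expect_error(simConfig(geneLengthRange = c(10, 15)), "21")
})

test_that("intron placement makes the canonical transcript tag unmappable", {
    cfg <- simConfig(nGenes = 25, nDeGenes = 0, log2fc = numeric(0),
                     librarySizes = c(1e4, 1e4), intronRate = 1, seed = 33)
    ref <- generateReference(cfg)
    expect_true(all(ref$truth$has_intron))
    expect_true(all(lengths(exonRanges(ref$models)) == 2))
    # transcripts still carry the canonical tag, but it spans the junction
    tx <- transcriptSequences(ref$models, ref$genome)
    idx <- buildTagIndex(ref$genome)
    hits <- idx[ref$truth$canonical_tag, on = "tag", nomatch = NULL]
    expect_equal(nrow(hits), 0L)
    for (i in seq_len(nrow(ref$truth)))
        expect_identical(canonicalTag(as.character(tx[[i]])),
                         ref$truth$canonical_tag[i])
})

test_that("library totals are exact and degenerate parameters give only canonical tags", {
    sim <- deskSim(seed = 5, nGenes = 60, nDe = 0, log2fc = numeric(0),
                   N = 4e4, cleavageProb = 1, antisenseRate = 0,
                   seqErrorRate = 0, intronRate = 0)
    expect_equal(libSize(sim$libs$libA), 4e4)
    expect_equal(libSize(sim$libs$libB), 4e4)
    # c=1, a=0, e=0: every emitted tag is a canonical most-3' tag
    expect_true(all(names(tagCounts(sim$libs$libA)) %in%
                    sim$ref$truth$canonical_tag))
    expect_true(all(sim$libs$emission$rank == 1))
    expect_true(all(sim$libs$emission$orientation == "sense"))
})

test_that("emitted tags occur in the source transcript and counts are recoverable", {
    sim <- deskSim(seed = 6, nGenes = 50, nDe = 5, log2fc = 2, N = 5e4,
                   antisenseRate = 0, seqErrorRate = 0, intronRate = 0)
    tx <- transcriptSequences(sim$ref$models, sim$ref$genome)
    em <- sim$libs$emission
    for (i in sample(nrow(em), 40))
        expect_true(grepl(em$tag[i], as.character(tx[[em$gene_id[i]]]),
                          fixed = TRUE))
    # full pipeline recovery: each gene's sense count equals its emission
    idx <- buildTagIndex(sim$ref$genome)
    for (lib in list(sim$libs$libA, sim$libs$libB)) {
        rep <- assignToGenes(mapTags(lib, idx), lib, sim$ref$models, 0)
        col <- if (identical(condition(lib), "replete")) "count_A"
               else "count_B"
        emitted <- tapply(em[[col]], em$gene_id, sum)
        gc <- geneCounts(rep)
        expect_equal(unname(gc[names(emitted)]), unname(as.numeric(emitted)))
    }
})

test_that("secondary-site emission follows the geometric incomplete-digestion law", {
    # pooled over 10 seeds: rank-2 share of digested molecules ~ c(1-c)
    cc <- 0.8
    obs2 <- tot <- 0
    for (seed in 1:10) {
        sim <- deskSim(seed = seed, nGenes = 80, nDe = 0,
                       log2fc = numeric(0), N = 3e4, cleavageProb = cc,
                       seqErrorRate = 0, intronRate = 0)
        em <- sim$libs$emission
        deep <- sim$ref$truth$gene_id[sim$ref$truth$n_sites >= 5]
        em <- em[em$gene_id %in% deep]
        obs2 <- obs2 + sum(em$count_A[em$rank == 2]) +
            sum(em$count_B[em$rank == 2])
        tot <- tot + sum(em$count_A) + sum(em$count_B)
    }
    phat <- obs2 / tot
    se <- sqrt(phat * (1 - phat) / tot)
    expect_lt(abs(phat - cc * (1 - cc)), 3 * se + 1e-4)
})

test_that("null libraries show no systematic count trend", {
    sim <- deskSim(seed = 12, nGenes = 100, nDe = 0, log2fc = numeric(0),
                   N = 1e5, seqErrorRate = 0, intronRate = 0)
    em <- sim$libs$emission
    a <- tapply(em$count_A, em$gene_id, sum)
    b <- tapply(em$count_B, em$gene_id, sum)
    keep <- a + b > 20
    lr <- log2((b[keep] + 0.5) / (a[keep] + 0.5))
    expect_lt(abs(mean(lr)), 0.05)
})

test_that("spectral-count simulation has the planted structure", {
    set.seed(1)
    truth <- data.frame(gene_id = sprintf("g%04d", 1:500),
                        abundance1 = rlnorm(500), delta = 0)
    truth$delta[1:50] <- rep(c(-2, 2), 25)
    truth$abundance2 <- truth$abundance1 * 2^truth$delta
    # noiseSd=0, slope=1, intercept=0: protein FC equals transcript FC
    pc <- simulateSpectralCounts(truth, slope = 1, intercept = 0,
                                 noiseSd = 0, detectTopFrac = 1,
                                 depth = 1e5, seed = 4)
    pt <- attr(pc, "protein_truth")
    expect_equal(pt$protein_log2fc, pt$delta)
    # detect_top_frac keeps the most abundant floor(frac * n) proteins
    pc2 <- simulateSpectralCounts(truth, detectTopFrac = 0.11, seed = 4)
    expect_equal(length(pc2), floor(500 * 0.11))
    thr <- sort((truth$abundance1 + truth$abundance2) / 2,
                decreasing = TRUE)[55]
    ab <- (truth$abundance1 + truth$abundance2) / 2
    expect_true(all(ab[match(proteinIds(pc2), truth$gene_id)] >= thr))
    # determinism and the error contract
    pc3 <- simulateSpectralCounts(truth, detectTopFrac = 0.11, seed = 4)
    expect_identical(spectralCounts(pc2), spectralCounts(pc3))
    expect_error(simulateSpectralCounts(truth, detectTopFrac = 0), "0, 1")
    # full-scale sanity: 11% detection over 11242 modelled genes lands in
    # the ~1.2k-protein range a deep LC-MS survey reports
    big <- data.frame(gene_id = sprintf("G%05d", 1:11242),
                      abundance1 = rlnorm(11242), delta = 0)
    big$abundance2 <- big$abundance1
    pcBig <- simulateSpectralCounts(big, detectTopFrac = 0.11, seed = 2)
    expect_equal(length(pcBig), 1236L)
})
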