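test_that("tag index matches a naive both-strand scan on random genomes", {
    set.seed(202)
    genome <- Biostrings::DNAStringSet(c(cA = randomDnaStr(8000),
                                         cB = randomDnaStr(4000)))
    idx <- buildTagIndex(genome)
    # every indexed entry is a real occurrence
    some <- sample(nrow(idx), min(100, nrow(idx)))
    for (i in some) {
        locs <- naiveTagLocations(idx$tag[i], genome)
        hit <- paste(idx$chrom[i], idx$pos[i], idx$strand[i])
        expect_true(hit %in% paste(locs$chrom, locs$pos, locs$strand))
    }
    # reverse-strand-only context is indexed on the reverse strand only
    g2 <- Biostrings::DNAStringSet(c(
        z = paste0(strrep("T", 30), "CATG", strrep("T", 30))))
    idx2 <- buildTagIndex(g2)
    # forward window CATG+T17 exists; reverse window revcomp(T17+CATG)=CATG+A17
    expect_setequal(idx2$strand, c("+", "-"))
    expect_identical(sort(idx2$tag),
                     sort(c(paste0("CATG", strrep("T", 17)),
                            paste0("CATG", strrep("A", 17)))))
})

test_that("mapping enforces 100% identity and the uniqueness filter", {
    set.seed(303)
    genome <- Biostrings::DNAStringSet(c(c1 = randomDnaStr(6000)))
    idx <- buildTagIndex(genome)
    uniqTags <- idx$tag[!(duplicated(idx$tag) |
                          duplicated(idx$tag, fromLast = TRUE))]
    t1 <- uniqTags[1]
    # one substitution in a variable base -> unmapped
    mism <- t1
    substr(mism, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(t1, 10, 10))[1]
    while (mism %in% idx$tag)  # guard the rare accidental hit
        substr(mism, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                        substr(mism, 11, 11))[1]
    # an absent tag
    absent <- paste0("CATG", strrep("A", 17))
    while (absent %in% idx$tag) absent <- paste0("CATG", randomDnaStr(17))
    lib <- tagLibrary(c(t1, mism, absent), c(10, 3, 2), "t")
    hits <- mapTags(lib, idx)
    h <- as.data.frame(hits)
    expect_equal(h$nloc[h$tag == t1], 1)
    expect_equal(h$nloc[h$tag == mism], 0)
    expect_equal(h$nloc[h$tag == absent], 0)
    # invalid tag rejected by the library constructor itself
    expect_error(tagLibrary("CATGXX", 1), "21 nt")
})

test_that("multi-location tags (including strand-distinct) are excluded", {
    # the same 21-mer planted twice forward and its revcomp elsewhere
    body <- paste0("CATG", strrep("T", 8), strrep("C", 9))
    genome <- Biostrings::DNAStringSet(c(c1 = paste0(
        strrep("A", 25), body, strrep("A", 25), body, strrep("A", 25),
        revcomp(body), strrep("A", 25))))
    idx <- buildTagIndex(genome)
    lib <- tagLibrary(body, 5, "t")
    hits <- as.data.frame(mapTags(lib, idx))
    expect_gte(hits$nloc, 3)
    rep <- assignToGenes(mapTags(lib, idx), lib,
                         geneModelSet("c1", 1L, 20L, "+", "g"), 0)
    expect_equal(unname(categoryReads(rep)["multi_mapped"]), 5)
})

test_that("gene assignment follows the sense/antisense/extension rules", {
    fx <- plantedOverhangFixture(nGenes = 10)
    idx <- buildTagIndex(fx$genome)
    # sense tag inside gene; same tag cannot be antisense, so plant a
    # library of gene tags (sense), revcomp-context tags (antisense) and
    # downstream tags (intergenic at ext 0, sense at ext 200)
    anti <- vapply(fx$geneTags, function(tg) {
        locs <- naiveTagLocations(tg, fx$genome)
        p <- locs$pos[locs$strand == "+"][1]
        s <- as.character(fx$genome[["chr1"]])
        revcomp(substr(s, p - 17, p + 3))
    }, "")
    lib <- tagLibrary(c(fx$geneTags, anti, fx$utrTags),
                      rep(c(4, 2, 1), each = 10), "mix")
    hits <- mapTags(lib, idx)
    rep0 <- assignToGenes(hits, lib, fx$models, 0)
    cr0 <- categoryReads(rep0)
    expect_equal(unname(cr0["gene_sense"]), 40)
    expect_equal(unname(cr0["gene_antisense"]), 20)
    expect_equal(unname(cr0["intergenic"]), 10)
    # antisense reads never enter gene counts
    expect_equal(sum(geneCounts(rep0)), 40)
    # category partition is exact
    expect_equal(sum(cr0), libSize(lib))
    # with the 200 bp extension the downstream tags become gene_sense
    repX <- assignToGenes(hits, lib, fx$models, 200, fx$genome)
    crX <- categoryReads(repX)
    expect_equal(unname(crX["gene_sense"]), 50)
    expect_equal(unname(crX["intergenic"]), 0)
    expect_equal(sum(crX), libSize(lib))
    # intergenic tags carry their distance to the nearest 3' end
    tt <- tagTable(rep0)
    d <- tt$dist3p[tt$category == "intergenic"]
    expect_true(all(!is.na(d)) && all(d == 30))
})

test_that("mapping equals the naive both-strand scan on small random genomes", {
    set.seed(404)
    genome <- Biostrings::DNAStringSet(c(c1 = randomDnaStr(20000),
                                         c2 = randomDnaStr(10000)))
    idx <- buildTagIndex(genome)
    tags <- unique(c(sample(idx$tag, 60),
                     replicate(15, paste0("CATG", randomDnaStr(17)))))
    lib <- tagLibrary(tags, rep(1, length(tags)), "t")
    hits <- as.data.frame(mapTags(lib, idx))
    for (i in seq_len(nrow(hits))) {
        locs <- naiveTagLocations(hits$tag[i], genome)
        expect_equal(hits$nloc[i], nrow(locs))
        if (nrow(locs) == 1) {
            expect_equal(hits$chrom[i], locs$chrom)
            expect_equal(hits$pos[i], locs$pos)
            expect_equal(hits$strand[i], locs$strand)
        }
    }
})

test_that("mapping summary reports fractions and the extension gain both ways", {
    fx <- plantedOverhangFixture(nGenes = 20)
    idx <- buildTagIndex(fx$genome)
    lib <- tagLibrary(c(fx$geneTags, fx$utrTags), rep(c(8, 2), each = 20),
                      "planted")
    hits <- mapTags(lib, idx)
    rep0 <- assignToGenes(hits, lib, fx$models, 0)
    repX <- assignToGenes(hits, lib, fx$models, 200, fx$genome)
    s <- mappingSummary(rep0, repX)
    expect_equal(s$reads_mapped, 1)
    expect_equal(s$in_gene_ext0, 0.8)     # 160 of 200 mapped reads in genes
    expect_equal(s$in_gene_ext, 1)
    expect_equal(s$gain_points, 0.2)
    expect_equal(s$gain_relative, 0.25)
    expect_error(mappingSummary(rep0, assignToGenes(
        mapTags(tagLibrary(fx$geneTags[1], 3, "x"), idx),
        tagLibrary(fx$geneTags[1], 3, "x"), fx$models, 0)),
        "totals differ")
})
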