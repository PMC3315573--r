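# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (loops, string scans, direct
# enumeration) and shares no code path with the package internals it checks.

revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

randomDnaStr <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force window scan for CATG anchor positions (1-based)
naiveSites <- function(s) {
    out <- integer(0)
    if (nchar(s) >= 4)
        for (i in 1:(nchar(s) - 3))
            if (substr(s, i, i + 3) == "CATG") out <- c(out, i)
    out
}

# all genomic locations of a 21-mer tag on both strands, as the mapping
# index defines them: forward hits at the anchor position of the match;
# reverse hits where revcomp(tag) occurs at q..q+20, recorded at q+20
# (the forward coordinate pairing with the reverse-strand anchor C)
naiveTagLocations <- function(tag, genome) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0))
    for (ch in names(genome)) {
        s <- as.character(genome[[ch]])
        fwd <- gregexpr(tag, s, fixed = TRUE)[[1]]
        if (fwd[1] != -1)
            out <- rbind(out, data.frame(chrom = ch, pos = as.integer(fwd),
                                         strand = "+"))
        rev <- gregexpr(revcomp(tag), s, fixed = TRUE)[[1]]
        if (rev[1] != -1)
            out <- rbind(out, data.frame(chrom = ch,
                                         pos = as.integer(rev) + 20L,
                                         strand = "-"))
    }
    unique(out[order(out$chrom, out$pos, out$strand), , drop = FALSE])
}

# independently coded grid integrator for the spike-and-slab posterior
oraclePosterior <- function(x1, x2, N1, N2, pi0, tau, grid, spacing) {
    K <- length(grid)
    w <- numeric(K)
    for (j in seq_len(K)) w[j] <- exp(-grid[j]^2 / (2 * tau^2))
    w <- w / sum(w)
    lp <- numeric(K + 1L)
    n <- x1 + x2
    for (j in seq_len(K)) {
        th <- N1 / (N1 + N2 * 2^grid[j])
        lp[j] <- log(1 - pi0) + log(w[j]) + dbinom(x1, n, th, log = TRUE)
    }
    lp[K + 1L] <- log(pi0) + dbinom(x1, n, N1 / (N1 + N2), log = TRUE)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    m1 <- 0
    for (j in seq_len(K)) m1 <- m1 + p[j] * grid[j]
    m2 <- 0
    for (j in seq_len(K)) m2 <- m2 + p[j] * grid[j]^2
    list(delta = m1,
         se = max(sqrt(max(m2 - m1^2, 0)), spacing / sqrt(12)),
         lfdr = p[K + 1L])
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p of the
# 2x2 table [s1, T1 - s1; s2, T2 - s2] (minimum-likelihood rule, with the
# customary relative tolerance on ties)
fisherEnumeration <- function(s1, s2, T1, T2) {
    n <- s1 + s2
    support <- max(0L, n - T2):min(n, T1)
    d <- dhyper(support, T1, T2, n)
    dObs <- dhyper(s1, T1, T2, n)
    min(1, sum(d[d <= dObs * (1 + 1e-7)]))
}

# Hand-built genome of nGenes plus-strand genes, each containing exactly one
# CATG 21-mer, with a second unique CATG 21-mer planted 50 bp downstream of
# each gene's 3' end (inside a 200 bp extension window). Spacers and tag
# bodies avoid G so the planted anchors are the only CATGs. Returns genome,
# models and the two planted tag sets.
plantedOverhangFixture <- function(nGenes = 30) {
    body17 <- function() paste(sample(c("A", "C", "T"), 17, replace = TRUE),
                               collapse = "")
    spacer <- function(n) paste(sample(c("A", "C", "T"), n, replace = TRUE),
                                collapse = "")
    geneTags <- character(nGenes); utrTags <- character(nGenes)
    repeat {
        geneTags <- vapply(seq_len(nGenes),
                           function(i) paste0("CATG", body17()), "")
        utrTags <- vapply(seq_len(nGenes),
                          function(i) paste0("CATG", body17()), "")
        if (!anyDuplicated(c(geneTags, utrTags))) break
    }
    parts <- character(0)
    starts <- ends <- integer(nGenes)
    cursor <- 0L
    for (i in seq_len(nGenes)) {
        pre <- spacer(40)                   # inside gene, before the tag
        post <- spacer(20)                  # inside gene, after the tag
        gap1 <- spacer(29)                  # gene 3' end -> planted anchor
        gap2 <- spacer(60)                  # after the planted 21-mer
        gene <- paste0(pre, geneTags[i], post)
        starts[i] <- cursor + 1L
        ends[i] <- cursor + nchar(gene)
        parts <- c(parts, gene, gap1, utrTags[i], gap2)
        cursor <- cursor + nchar(gene) + nchar(gap1) + 21L + nchar(gap2)
    }
    genome <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
    names(genome) <- "chr1"
    models <- geneModelSet(rep("chr1", nGenes), starts, ends,
                           rep("+", nGenes), sprintf("pg%03d", seq_len(nGenes)))
    list(genome = genome, models = models,
         geneTags = geneTags, utrTags = utrTags)
}

# small helper: desk-scale simulated experiment reused by several tests
deskSim <- function(seed = 11, nGenes = 150, nDe = 20,
                    log2fc = c(-2, 2), N = 2e5, ...) {
    cfg <- simConfig(nGenes = nGenes, nDeGenes = nDe, log2fc = log2fc,
                     librarySizes = c(N, N), seed = seed, ...)
    ref <- generateReference(cfg)
    libs <- simulateTagLibraries(ref, cfg)
    list(cfg = cfg, ref = ref, libs = libs)
}
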