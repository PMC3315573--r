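#' Construct a ProteinCounts table
#'
#' @param proteinId Unique protein identifiers.
#' @param peptides Distinct peptide identifications per protein.
#' @param s1,s2 Raw spectral counts in condition 1 (reference / replete)
#'   and condition 2 (treatment / deficient).
#' @param conditions Length-2 character vector of condition labels.
#' @return A [ProteinCounts-class].
#' @export
proteinCounts <- function(proteinId, peptides, s1, s2,
                          conditions = c("replete", "deficient")) {
    m <- cbind(as.numeric(s1), as.numeric(s2))
    colnames(m) <- conditions
    new("ProteinCounts", proteinId = as.character(proteinId),
        peptides = as.integer(peptides), counts = m,
        normalized = matrix(numeric(0), 0, 2))
}

#' Read / write a spectral-count table
#'
#' TSV with header columns `protein_id`, `peptides`, `count_A`, `count_B`.
#'
#' @param path File path.
#' @return `readProteinCounts`: a [ProteinCounts-class].
#' @export
readProteinCounts <- function(path) {
    if (!file.exists(path)) stop("spectral-count table not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", rep("numeric", 3)))
    need <- c("protein_id", "peptides", "count_A", "count_B")
    if (!all(need %in% names(df)))
        stop("spectral-count table must have columns ",
             paste(need, collapse = ", "))
    proteinCounts(df$protein_id, df$peptides, df$count_A, df$count_B)
}

#' @rdname readProteinCounts
#' @param x A [ProteinCounts-class].
#' @export
writeProteinCounts <- function(x, path) {
    utils::write.table(
        data.frame(protein_id = x@proteinId, peptides = x@peptides,
                   count_A = x@counts[, 1], count_B = x@counts[, 2]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Filter proteins by peptide support
#'
#' Removes proteins identified by fewer than `minPeptides` distinct tryptic
#' peptides (default 2: single-peptide identifications are too unreliable
#' to quantify). The number removed is recorded in an attribute and
#' reported via `message()`.
#'
#' @param x A [ProteinCounts-class].
#' @param minPeptides Minimum distinct peptide identifications.
#' @return The filtered [ProteinCounts-class] with attribute `n_removed`.
#' @export
filterByPeptides <- function(x, minPeptides = 2L) {
    stopifnot(is(x, "ProteinCounts"))
    keep <- x@peptides >= minPeptides
    out <- new("ProteinCounts", proteinId = x@proteinId[keep],
               peptides = x@peptides[keep],
               counts = x@counts[keep, , drop = FALSE],
               normalized = if (nrow(x@normalized))
                   x@normalized[keep, , drop = FALSE]
                   else x@normalized)
    message(sum(!keep), " of ", length(x),
            " proteins removed by the >=", minPeptides, "-peptide filter")
    attr(out, "n_removed") <- sum(!keep)
    out
}

#' Normalize spectral counts across samples
#'
#' Equal-total scaling: each sample's counts are multiplied by
#' `mean(T1, T2) / T_i`, so both normalized columns sum to the mean raw
#' total. This is the standard spectral-counting convention for comparing
#' relative protein abundance between runs of unequal depth.
#'
#' @param x A [ProteinCounts-class] with positive totals in both columns.
#' @return The object with its `normalized` slot filled.
#' @export
normalizeSpectralCounts <- function(x) {
    stopifnot(is(x, "ProteinCounts"))
    tot <- colSums(x@counts)
    if (any(tot == 0)) stop("cannot normalize a sample with zero total counts")
    scale <- mean(tot) / tot
    norm <- sweep(x@counts, 2L, scale, "*")
    colnames(norm) <- colnames(x@counts)
    new("ProteinCounts", proteinId = x@proteinId, peptides = x@peptides,
        counts = x@counts, normalized = norm)
}

#' Fisher exact differential protein abundance
#'
#' For each protein, tests the 2x2 table `[s1, T1 - s1; s2, T2 - s2]`
#' (raw integer counts against the rest of their library -- the test
#' requires true sampling counts, so normalization is for display only).
#' The two-sided p sums all hypergeometric tables with probability at most
#' that of the observed one. Display fold changes come from normalized
#' counts with 0.5 pseudocounts, oriented condition 2 : condition 1
#' (deficient : replete). A Benjamini-Hochberg q-value column is included
#' for information, but significance is the uncorrected `p < alpha` rule.
#'
#' @param x A [ProteinCounts-class] (normalized internally if needed).
#' @param alpha Significance level on the uncorrected p.
#' @return A `data.frame`: `protein_id`, `s1`, `s2`, `ns1`, `ns2`, `fold`
#'   (log2), `p`, `q`, `significant`; attributes `n_up` / `n_down` count
#'   the significant proteins by fold direction.
#' @export
fisherDifferential <- function(x, alpha = 0.05) {
    stopifnot(is(x, "ProteinCounts"))
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie inside (0, 1)")
    if (!nrow(x@normalized)) x <- normalizeSpectralCounts(x)
    s1 <- x@counts[, 1]; s2 <- x@counts[, 2]
    if (any(s1 != round(s1) | s2 != round(s2)))
        stop("Fisher test requires raw integer spectral counts")
    T1 <- sum(s1); T2 <- sum(s2)
    p <- vapply(seq_along(s1), function(i) {
        tab <- matrix(c(s1[i], T1 - s1[i], s2[i], T2 - s2[i]), 2L, 2L)
        stats::fisher.test(tab)$p.value
    }, numeric(1))
    p <- pmin(p, 1)
    ns1 <- x@normalized[, 1]; ns2 <- x@normalized[, 2]
    fold <- log2((ns2 + 0.5) / (ns1 + 0.5))
    out <- data.frame(protein_id = x@proteinId, s1 = s1, s2 = s2,
                      ns1 = ns1, ns2 = ns2, fold = fold, p = p,
                      q = stats::p.adjust(p, "BH"),
                      significant = p < alpha)
    attr(out, "n_up") <- sum(out$significant & fold > 0)
    attr(out, "n_down") <- sum(out$significant & fold < 0)
    attr(out, "totals") <- c(T1 = T1, T2 = T2)
    out
}
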