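#' Join transcript and protein differential results
#'
#' Inner join of the transcript table (from [runDGE()] /
#' [posteriorDE()]) and the protein table (from [fisherDifferential()]) on
#' the shared identifier space (`gene_id == protein_id` in simulation).
#' Both fold changes are oriented condition 2 : condition 1
#' (deficient : replete). The transcript fold used on the x-axis is, by
#' default, the display fold from pseudocounted tpm ratios (mirroring how
#' such comparisons are plotted); set `useDelta = TRUE` to use the
#' posterior mean instead.
#'
#' @param transcriptDE Transcript results with columns `gene_id`,
#'   `log2fc_tpm`, `delta`, `significant`.
#' @param proteinDE Protein results with columns `protein_id`, `fold`,
#'   `significant`.
#' @param useDelta Use the posterior mean `delta` as the transcript fold.
#' @return A `data.frame` of integration records: `gene_id`, `t_fold`,
#'   `p_fold`, `t_sig`, `p_sig`, `coordination`; attributes
#'   `n_transcript_only_ids` and `n_protein_only_ids` tally the unmatched
#'   identifiers on each side.
#' @export
joinResults <- function(transcriptDE, proteinDE, useDelta = FALSE) {
    t_ids <- as.character(transcriptDE$gene_id)
    p_ids <- as.character(proteinDE$protein_id)
    if (anyDuplicated(t_ids)) stop("duplicate gene_id in transcript results")
    if (anyDuplicated(p_ids)) stop("duplicate protein_id in protein results")
    shared <- intersect(t_ids, p_ids)
    ti <- match(shared, t_ids); pj <- match(shared, p_ids)
    rec <- data.frame(
        gene_id = shared,
        t_fold = if (useDelta) as.numeric(transcriptDE$delta[ti])
                 else as.numeric(transcriptDE$log2fc_tpm[ti]),
        p_fold = as.numeric(proteinDE$fold[pj]),
        t_sig = as.logical(transcriptDE$significant[ti]),
        p_sig = as.logical(proteinDE$significant[pj]))
    rec$coordination <- classifyRecord(rec$t_fold, rec$p_fold,
                                       rec$t_sig, rec$p_sig)
    attr(rec, "n_transcript_only_ids") <- length(setdiff(t_ids, shared))
    attr(rec, "n_protein_only_ids") <- length(setdiff(p_ids, shared))
    rec
}

coordinationClasses <- c("both_up", "both_down", "protein_only_up",
                         "protein_only_down", "transcript_only",
                         "opposing", "neither")

classifyRecord <- function(t_fold, p_fold, t_sig, p_sig) {
    out <- rep("neither", length(t_fold))
    both <- t_sig & p_sig
    out[both & t_fold > 0 & p_fold > 0] <- "both_up"
    out[both & t_fold < 0 & p_fold < 0] <- "both_down"
    out[both & (sign(t_fold) != sign(p_fold))] <- "opposing"
    pOnly <- p_sig & !t_sig
    out[pOnly & p_fold > 0] <- "protein_only_up"
    out[pOnly & p_fold <= 0] <- "protein_only_down"
    out[t_sig & !p_sig] <- "transcript_only"
    factor(out, levels = coordinationClasses)
}

#' Tally transcript-protein coordination classes
#'
#' Deterministic classification of each joined record by the two
#' significance flags and fold directions; class counts partition the join.
#'
#' @param records Output of [joinResults()].
#' @return Named integer vector over the coordination classes.
#' @export
classifyCoordination <- function(records) {
    tab <- table(records$coordination)
    stats::setNames(as.integer(tab), names(tab))
}

#' Transcript-protein concordance regression
#'
#' Ordinary least squares of the protein log2 fold change on the transcript
#' log2 fold change, over proteins changing at least `minFold`-fold in
#' either direction (the filter is applied on the protein axis). The slope
#' below 1 that such fits typically return quantifies the attenuation of
#' the protein response relative to the transcript response.
#'
#' @param records Output of [joinResults()].
#' @param minFold Linear fold-change filter on `|p_fold|`
#'   (default 2 means `|p_fold| >= 1` in log2 units).
#' @return A list of class `concordanceFit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
concordanceRegression <- function(records, minFold = 2.0) {
    keep <- abs(records$p_fold) >= log2(minFold)
    d <- records[keep, , drop = FALSE]
    if (nrow(d) < 2L)
        stop("fewer than 2 records pass the |fold| >= ", minFold, " filter")
    if (stats::var(d$t_fold) == 0)
        stop("degenerate design: all transcript folds identical")
    fit <- stats::lm(p_fold ~ t_fold, data = d)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_squared = summary(fit)$r.squared,
                n_points = nrow(d))
    class(out) <- "concordanceFit"
    out
}

#' @export
print.concordanceFit <- function(x, ...) {
    cat(sprintf(
        "Concordance fit (n = %d): protein = %.3f * transcript %+.3f, r^2 = %.3f\n",
        x$n_points, x$slope, x$intercept, x$r_squared))
    invisible(x)
}
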