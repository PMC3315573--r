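#' Tags-per-million normalization
#'
#' @param x Tag count(s), `0 <= x <= N`.
#' @param N Library total, `> 0`.
#' @return `x / N * 1e6`.
#' @examples
#' normalizeTpm(50, 1e5)  # 500
#' @export
normalizeTpm <- function(x, N) {
    if (length(N) != 1L || is.na(N) || N <= 0) stop("library total N must be > 0")
    if (any(x < 0 | x > N)) stop("counts must lie in [0, N]")
    x / N * 1e6
}

#' Conditional marginal likelihood of a two-library count pair
#'
#' Under independent Poisson sampling of the two libraries with a shared
#' baseline proportion and log2 fold change `delta` (condition 2 :
#' condition 1), conditioning on the pair total `n = x1 + x2` eliminates
#' the baseline exactly: `x1 | n ~ Binomial(n, theta)` with
#' `theta = N1 / (N1 + N2 * 2^delta)`. This is the per-gene likelihood the
#' empirical-Bayes machinery integrates over.
#'
#' @param x1,x2 Non-negative counts in conditions 1 and 2.
#' @param N1,N2 Library totals (`> 0`).
#' @param delta Log2 fold change(s), condition 2 : condition 1.
#' @param log Return the log likelihood.
#' @return Probability (or log probability) of `x1` given `x1 + x2`, for
#'   each value of `delta`.
#' @export
marginalLikelihood <- function(x1, x2, N1, N2, delta, log = FALSE) {
    stopifnot(x1 >= 0, x2 >= 0, N1 > 0, N2 > 0)
    theta <- N1 / (N1 + N2 * 2^delta)
    stats::dbinom(x1, x1 + x2, theta, log = log)
}

# genes x grid matrix of log conditional likelihoods
logLikMatrix <- function(x1, x2, N1, N2, grid) {
    theta <- N1 / (N1 + N2 * 2^grid)
    n <- x1 + x2
    out <- vapply(theta, function(th) stats::dbinom(x1, n, th, log = TRUE),
                  numeric(length(x1)))
    matrix(out, nrow = length(x1), ncol = length(grid))
}

#' Default fold-change grid
#'
#' Symmetric grid of log2 fold changes, `[-deltaMax, deltaMax]` in steps of
#' `h`; always contains 0.
#'
#' @param deltaMax Half-width in log2 units.
#' @param h Spacing.
#' @return Numeric vector.
#' @export
deltaGrid <- function(deltaMax = 10, h = 0.05) {
    g <- seq(-deltaMax, deltaMax, by = h)
    g[abs(g) < h / 2] <- 0  # guard against fp drift at the origin
    g
}

#' Fit the two-component empirical-Bayes prior
#'
#' Maximizes the marginal likelihood of a spike-and-slab prior over the
#' per-gene log2 fold change: a point mass at 0 with weight `pi0` and a
#' Normal(0, tau^2) slab discretized on `grid` with weight `1 - pi0`. In a
#' replicate-free two-library design, biological variability is not
#' estimable per gene; it enters the model only through `tau`, the spread
#' of real fold changes across genes. Fitting is by EM: the E-step computes
#' per-gene component responsibilities, the M-step updates `pi0` in closed
#' form and `tau` by 1-D maximization of the expected complete-data
#' log-likelihood over the discretized normal weights.
#'
#' @param countTable A `data.frame` with columns `x1`, `x2` and attributes
#'   `N1`, `N2` (as returned by [geneCountTable()]), or a plain data.frame
#'   plus explicit `N1`, `N2` arguments.
#' @param N1,N2 Library totals; taken from `countTable` attributes when
#'   missing.
#' @param grid Fold-change grid; see [deltaGrid()].
#' @param emTol Relative log-likelihood convergence tolerance.
#' @param emMaxiter Iteration cap; non-convergence warns and returns the
#'   best iterate, flagged in the result.
#' @param init Named vector with starting `pi0` and `tau`.
#' @return A [PriorModel-class].
#' @export
fitPrior <- function(countTable, N1 = attr(countTable, "N1"),
                     N2 = attr(countTable, "N2"), grid = deltaGrid(),
                     emTol = 1e-6, emMaxiter = 500L,
                     init = c(pi0 = 0.9, tau = 1)) {
    x1 <- countTable$x1; x2 <- countTable$x2
    if (is.null(N1) || is.null(N2)) stop("library totals N1, N2 required")
    if (length(x1) < 50L)
        warning("fewer than 50 genes: prior estimates will be unstable")
    h <- grid[2] - grid[1]
    logL <- logLikMatrix(x1, x2, N1, N2, grid)
    M <- apply(logL, 1L, max)
    A <- exp(logL - M)               # scaled likelihoods, rows max 1
    zeroCol <- which(grid == 0)
    L0 <- A[, zeroCol]
    pi0 <- init[["pi0"]]; tau <- init[["tau"]]
    slabWeights <- function(tau) {
        w <- stats::dnorm(grid, 0, tau)
        w / sum(w)
    }
    ll <- -Inf; converged <- FALSE; iter <- 0L
    repeat {
        iter <- iter + 1L
        w <- slabWeights(tau)
        slab <- as.numeric(A %*% w)
        denom <- pi0 * L0 + (1 - pi0) * slab
        newLL <- sum(M + log(denom))
        if (is.finite(ll) && abs(newLL - ll) < emTol * (abs(ll) + 1e-12)) {
            ll <- newLL; converged <- TRUE; break
        }
        ll <- newLL
        if (iter > emMaxiter) break
        # E-step
        rNull <- pi0 * L0 / denom
        R <- sweep(A, 1L, (1 - pi0) / denom, "*")   # slab responsibilities
        Rcol <- colSums(R) * w                      # sum_g r_g(delta)
        # M-step
        pi0 <- mean(rNull)
        pi0 <- min(max(pi0, 1e-6), 1 - 1e-6)
        qfun <- function(logTau) {
            # floor the weights so a degenerate tau cannot yield -Inf
            lw <- log(pmax(slabWeights(exp(logTau)), 1e-300))
            sum(Rcol * lw)
        }
        opt <- stats::optimize(qfun, interval = log(c(1e-3, 20)),
                               maximum = TRUE)
        tau <- exp(opt$maximum)
    }
    if (!converged)
        warning("EM did not converge in ", emMaxiter,
                " iterations; returning last iterate")
    new("PriorModel", pi0 = unname(pi0), tau = unname(tau), grid = grid,
        spacing = h, converged = converged, logLik = ll,
        nIter = as.integer(iter))
}

#' Posterior differential-expression summaries
#'
#' For each gene, forms the posterior over the spike-at-0 plus the
#' discretized slab under the fitted prior and the binomial-conditional
#' likelihood, and reports: `delta` -- the posterior mean log2 fold change
#' (condition 2 : condition 1, i.e. treatment : reference); `se` -- the
#' posterior standard deviation (the shrunken standard error), floored at
#' `h/sqrt(12)` (the quantization SD of one grid cell); `z = delta/se`; and
#' `lfdr` -- the posterior probability of the spike (null) component. Genes
#' with `x1 = x2 = 0` carry no information: they return `delta = 0`,
#' `lfdr = pi0` and are flagged `no_data`.
#'
#' @inheritParams fitPrior
#' @param prior A fitted [PriorModel-class].
#' @return A [S4Vectors::DataFrame] with one row per gene: `gene_id` (when
#'   present in `countTable`), `x1`, `x2`, `tpm1`, `tpm2`, `log2fc_tpm`
#'   (display fold change from 0.5-pseudocount tpm ratios -- never used in
#'   inference), `delta`, `se`, `z`, `lfdr`, `no_data`.
#' @export
posteriorDE <- function(countTable, prior, N1 = attr(countTable, "N1"),
                        N2 = attr(countTable, "N2")) {
    stopifnot(is(prior, "PriorModel"))
    validObject(prior)
    x1 <- countTable$x1; x2 <- countTable$x2
    if (is.null(N1) || is.null(N2)) stop("library totals N1, N2 required")
    grid <- prior@grid
    h <- prior@spacing
    logL <- logLikMatrix(x1, x2, N1, N2, grid)
    M <- apply(logL, 1L, max)
    A <- exp(logL - M)
    zeroCol <- which(grid == 0)
    w <- stats::dnorm(grid, 0, prior@tau)
    w <- w / sum(w)
    spike <- prior@pi0 * A[, zeroCol]
    slabM <- sweep(A, 2L, (1 - prior@pi0) * w, "*")
    denom <- spike + rowSums(slabM)
    lfdr <- spike / denom
    pm <- as.numeric(slabM %*% grid) / denom          # spike contributes 0
    second <- as.numeric(slabM %*% grid^2) / denom
    sd <- sqrt(pmax(second - pm^2, 0))
    seFloor <- h / sqrt(12)
    se <- pmax(sd, seFloor)
    noData <- (x1 + x2) == 0
    pm[noData] <- 0
    lfdr[noData] <- prior@pi0
    z <- pm / se
    out <- DataFrame(
        x1 = x1, x2 = x2,
        tpm1 = normalizeTpm(x1, N1), tpm2 = normalizeTpm(x2, N2),
        log2fc_tpm = log2(((x2 + 0.5) / N2) / ((x1 + 0.5) / N1)),
        delta = pm, se = se, z = z, lfdr = lfdr, no_data = noData)
    if (!is.null(countTable$gene_id))
        out <- cbind(DataFrame(gene_id = countTable$gene_id), out)
    metadata(out) <- list(prior = prior, N1 = N1, N2 = N2)
    out
}

#' Call differentially expressed genes
#'
#' @param results Output of [posteriorDE()].
#' @param lfdrThreshold Local false discovery rate threshold in (0, 1);
#'   entries with `lfdr` strictly below it are called.
#' @return The called subset, sorted by decreasing `z`, with attributes
#'   `n_up` and `n_down`.
#' @export
callDifferential <- function(results, lfdrThreshold = 0.05) {
    if (lfdrThreshold <= 0 || lfdrThreshold >= 1)
        stop("lfdrThreshold must lie strictly inside (0, 1)")
    called <- results[results$lfdr < lfdrThreshold, , drop = FALSE]
    called <- called[order(called$z, decreasing = TRUE), , drop = FALSE]
    attr(called, "n_up") <- sum(called$delta > 0)
    attr(called, "n_down") <- sum(called$delta < 0)
    called
}

#' One-call differential expression for a two-library count table
#'
#' Convenience wrapper: fits the prior, computes posterior summaries and
#' flags significance at the lfdr threshold.
#'
#' @inheritParams fitPrior
#' @param lfdrThreshold Significance threshold on the local fdr.
#' @param ... Passed to [fitPrior()].
#' @return The [posteriorDE()] table with an added logical `significant`
#'   column; the fitted prior is in `metadata(result)$prior`.
#' @export
runDGE <- function(countTable, N1 = attr(countTable, "N1"),
                   N2 = attr(countTable, "N2"), lfdrThreshold = 0.05, ...) {
    prior <- fitPrior(countTable, N1 = N1, N2 = N2, ...)
    res <- posteriorDE(countTable, prior, N1 = N1, N2 = N2)
    res$significant <- res$lfdr < lfdrThreshold
    res
}
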