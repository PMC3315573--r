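#' Run configuration for the end-to-end pipeline
#'
#' A flat list of paths and thresholds; the defaults are the analysis
#' thresholds the pipeline is built around (200 bp 3' extension,
#' lfdr < 0.05 for transcripts, Fisher p < 0.05 for proteins, >= 2
#' peptides, 2-fold concordance filter).
#'
#' @param dir Working directory holding the stage artifacts.
#' @param simConfig A [SimConfig-class] (used by the `simulate` stage).
#' @param utrExtensionBp 3'-UTR extension applied at gene assignment.
#' @param lfdrThreshold Transcript significance threshold (local fdr).
#' @param proteinAlpha Protein significance level (Fisher p).
#' @param minPeptides Minimum distinct peptides per protein.
#' @param minFold Concordance-regression fold filter (linear scale).
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(dir, simConfig = tagProteo::simConfig(),
                      utrExtensionBp = 200, lfdrThreshold = 0.05,
                      proteinAlpha = 0.05, minPeptides = 2L,
                      minFold = 2.0) {
    if (lfdrThreshold <= 0 || lfdrThreshold >= 1 ||
        proteinAlpha <= 0 || proteinAlpha >= 1)
        stop("significance thresholds must lie inside (0, 1)")
    if (utrExtensionBp < 0) stop("utrExtensionBp must be >= 0")
    structure(list(dir = dir, simConfig = simConfig,
                   utrExtensionBp = utrExtensionBp,
                   lfdrThreshold = lfdrThreshold,
                   proteinAlpha = proteinAlpha,
                   minPeptides = minPeptides, minFold = minFold),
              class = "runConfig")
}

stagePath <- function(config, name) file.path(config$dir, name)

needArtifact <- function(config, name, producer) {
    p <- stagePath(config, name)
    if (!file.exists(p))
        stop("missing artifact '", name, "': run the '", producer,
             "' stage first")
    p
}

stageLog <- function(stage, t0, notes) {
    message(sprintf("[%s] %5.1fs  %s", stage,
                    as.numeric(Sys.time()) - t0, notes))
}

#' Run the pipeline
#'
#' Orchestrates the stages over a working directory of TSV/JSON artifacts.
#' Stages: `simulate` (synthetic genome, models, tag libraries, spectral
#' counts, truth), `map` (tag mapping and gene assignment at extension 0
#' and at the configured extension), `dge` (empirical-Bayes differential
#' expression on pooled gene counts), `prot` (peptide filter,
#' normalization, Fisher test), `integrate` (join, coordination classes,
#' concordance regression), `report` (summary JSON), or `all`. Identical
#' configuration and seed produce byte-identical artifacts.
#'
#' @param config A [runConfig()] list.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
runPipeline <- function(config, stages = "all") {
    known <- c("simulate", "map", "dge", "prot", "integrate", "report")
    if (identical(stages, "all")) stages <- known
    bad <- setdiff(stages, known)
    if (length(bad)) stop("unknown stage: ", bad[1])
    dir.create(config$dir, showWarnings = FALSE, recursive = TRUE)
    written <- list()
    t0 <- as.numeric(Sys.time())

    if ("simulate" %in% stages) {
        ref <- generateReference(config$simConfig)
        libs <- simulateTagLibraries(ref, config$simConfig)
        prot <- simulateSpectralCounts(ref$truth,
                                       seed = config$simConfig@seed)
        written$simulate <- writeSimulatedData(ref, libs, prot, config$dir)
        stageLog("simulate", t0,
                 sprintf("%d genes, libraries %d / %d tags",
                         nrow(ref$truth), libs$libA@total, libs$libB@total))
    }

    if ("map" %in% stages) {
        genome <- readGenome(needArtifact(config, "genome.fa", "simulate"))
        models <- readGeneModels(needArtifact(config, "models.gff3",
                                              "simulate"))
        libA <- readTagLibrary(needArtifact(config, "tags_A.tsv",
                                            "simulate"), "replete")
        libB <- readTagLibrary(needArtifact(config, "tags_B.tsv",
                                            "simulate"), "deficient")
        idx <- buildTagIndex(genome)
        hitsA <- mapTags(libA, idx); hitsB <- mapTags(libB, idx)
        repA0 <- assignToGenes(hitsA, libA, models, 0)
        repB0 <- assignToGenes(hitsB, libB, models, 0)
        repA <- assignToGenes(hitsA, libA, models, config$utrExtensionBp,
                              genome)
        repB <- assignToGenes(hitsB, libB, models, config$utrExtensionBp,
                              genome)
        ct <- geneCountTable(repA, repB)
        p1 <- stagePath(config, "gene_counts.tsv")
        utils::write.table(cbind(ct, N1 = attr(ct, "N1"),
                                 N2 = attr(ct, "N2")),
                           p1, sep = "\t", quote = FALSE, row.names = FALSE)
        summ <- list(replete = mappingSummary(repA0, repA),
                     deficient = mappingSummary(repB0, repB),
                     category_reads = list(replete = as.list(repA@categoryReads),
                                           deficient = as.list(repB@categoryReads)))
        p2 <- stagePath(config, "mapping_summary.json")
        writeJson(summ, p2)
        written$map <- c(gene_counts = p1, mapping_summary = p2)
        stageLog("map", t0, sprintf(
            "%.1f%% / %.1f%% of reads mapped",
            100 * summ$replete$reads_mapped,
            100 * summ$deficient$reads_mapped))
    }

    if ("dge" %in% stages) {
        p <- needArtifact(config, "gene_counts.tsv", "map")
        ct <- utils::read.table(p, header = TRUE, sep = "\t",
                                colClasses = c("character",
                                               rep("numeric", 6)))
        attr(ct, "N1") <- ct$N1[1]; attr(ct, "N2") <- ct$N2[1]
        res <- runDGE(ct, lfdrThreshold = config$lfdrThreshold)
        out <- as.data.frame(res)
        p1 <- stagePath(config, "dge.tsv")
        utils::write.table(out, p1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written$dge <- c(dge = p1)
        stageLog("dge", t0, sprintf(
            "%d genes called at lfdr < %g (pi0 = %.3f)",
            sum(res$significant), config$lfdrThreshold,
            metadata(res)$prior@pi0))
    }

    if ("prot" %in% stages) {
        p <- needArtifact(config, "spectral.tsv", "simulate")
        pc <- readProteinCounts(p)
        pc <- suppressMessages(filterByPeptides(pc, config$minPeptides))
        pc <- normalizeSpectralCounts(pc)
        pres <- fisherDifferential(pc, config$proteinAlpha)
        p1 <- stagePath(config, "protein_de.tsv")
        utils::write.table(pres, p1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written$prot <- c(protein_de = p1)
        stageLog("prot", t0, sprintf(
            "%d of %d proteins significant (up %d / down %d)",
            sum(pres$significant), nrow(pres),
            attr(pres, "n_up"), attr(pres, "n_down")))
    }

    if ("integrate" %in% stages) {
        pd <- needArtifact(config, "dge.tsv", "dge")
        pp <- needArtifact(config, "protein_de.tsv", "prot")
        tde <- utils::read.table(pd, header = TRUE, sep = "\t",
                                 colClasses = list(character = "gene_id"))
        pde <- utils::read.table(pp, header = TRUE, sep = "\t",
                                 colClasses = list(character = "protein_id"))
        rec <- joinResults(tde, pde)
        p1 <- stagePath(config, "integration.tsv")
        utils::write.table(rec, p1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        fit <- tryCatch(concordanceRegression(rec, config$minFold),
                        error = function(e) NULL)
        p2 <- stagePath(config, "regression.json")
        writeJson(c(unclass(fit),
                    list(coordination = as.list(classifyCoordination(rec)))),
                  p2)
        written$integrate <- c(integration = p1, regression = p2)
        stageLog("integrate", t0, sprintf(
            "%d joined records%s", nrow(rec),
            if (!is.null(fit)) sprintf(", slope %.3f (r2 %.2f)",
                                       fit$slope, fit$r_squared) else ""))
    }

    if ("report" %in% stages) {
        rep <- list()
        for (f in c("mapping_summary.json", "regression.json")) {
            p <- stagePath(config, f)
            if (file.exists(p))
                rep[[sub("\\.json$", "", f)]] <- jsonlite::fromJSON(p)
        }
        pd <- stagePath(config, "dge.tsv")
        if (file.exists(pd)) {
            tde <- utils::read.table(pd, header = TRUE, sep = "\t")
            rep$dge <- list(
                n_genes = nrow(tde),
                n_significant = sum(tde$significant),
                n_up = sum(tde$significant & tde$delta > 0),
                n_down = sum(tde$significant & tde$delta < 0))
        }
        pp <- stagePath(config, "protein_de.tsv")
        if (file.exists(pp)) {
            pde <- utils::read.table(pp, header = TRUE, sep = "\t")
            rep$proteins <- list(
                n_proteins = nrow(pde),
                n_significant = sum(pde$significant),
                n_up = sum(pde$significant & pde$fold > 0),
                n_down = sum(pde$significant & pde$fold < 0))
        }
        p1 <- stagePath(config, "report.json")
        writeJson(rep, p1)
        written$report <- c(report = p1)
        stageLog("report", t0, "summary written")
    }
    invisible(written)
}

writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
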