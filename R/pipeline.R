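#' Default pipeline run configuration
#'
#' All analysis thresholds surfaced in one place: call-rate thresholds
#' (0.65, 0.85), FDR and nominal significance levels (0.05), positivity
#' thresholds (amyloid-PET 20 Centiloids, tau-PET SUVR 1.5, CSF
#' Aβ42/Aβ40 ratio 0.0673), dual-cutoff targets (0.95/0.95), the number
#' of surrogate variables (2), the KM/horizon settings, the stage
#' toggles, and the seed.
#'
#' @param ... overrides of any default element.
#' @return Named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        out_dir = NULL,
        cohort = list(),               # cohortConfig() overrides
        call_rate_thresholds = c(0.65, 0.85),
        fdr_alpha = 0.05,
        nominal_alpha = 0.05,
        centiloid_threshold = 20,
        tau_suvr_threshold = 1.5,
        csf_ratio_threshold = 0.0673,
        sens_target = 0.95,
        spec_target = 0.95,
        n_sv = 2L,
        biomarker = "pTau217",
        horizons = c(5, 10, 15),
        stages = c(simulate = TRUE, qc = TRUE, daa = TRUE, compare = TRUE,
                   cutoff = TRUE, evaluate = TRUE, progress = TRUE))
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    for (nm in c("fdr_alpha", "nominal_alpha"))
        .assertRate(cfg[[nm]], nm)
    structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are \code{runConfig}
#'   fields (\code{cohort:} holds \code{cohortConfig} overrides).
#' @return A validated \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (!is.null(y$stages)) y$stages <- unlist(y$stages)
    if (!is.null(y$call_rate_thresholds))
        y$call_rate_thresholds <- as.numeric(y$call_rate_thresholds)
    do.call(runConfig, y)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages simulate -> qc -> daa -> compare -> cutoff ->
#' evaluate -> progress as toggled in the config, returning every
#' stage's result in memory and (when \code{out_dir} is set) writing
#' the tabular outputs, a structured per-stage log with counts in/out
#' at every filter, and a JSON manifest recording the seed, the config
#' and per-stage output files. Rerunning the same config reproduces
#' the outputs bit for bit.
#'
#' @param config a \code{\link{runConfig}} (or YAML path).
#' @return List of class \code{"PipelineRun"} with elements
#'   \code{cohort}, \code{qc}, \code{normalized}, \code{daa},
#'   \code{compare}, \code{cutoffs}, \code{evaluation},
#'   \code{progression}, \code{manifest}, \code{log}.
#' @export
runPipeline <- function(config = runConfig()) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    log <- character(0)
    note <- function(fmt, ...) {
        msg <- sprintf(fmt, ...)
        log <<- c(log, msg)
        message(msg)
    }
    res <- list(manifest = list(seed = config$seed,
                                config = unclass(config),
                                started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                stages = list()))
    on <- function(stage) isTRUE(config$stages[[stage]])

    ## simulate -------------------------------------------------------
    if (!on("simulate")) stop("the pipeline needs the simulate stage as input source")
    ccfg <- do.call(cohortConfig, c(config$cohort, list(seed = config$seed)))
    cohort <- generateCohort(ccfg)
    res$cohort <- cohort
    note("simulate: %d analytes x %d samples (%s)",
         nrow(cohort$matrix), ncol(cohort$matrix),
         paste(sprintf("%s=%d", names(ccfg$n_per_group), ccfg$n_per_group),
               collapse = ", "))

    ## qc + normalize -------------------------------------------------
    mat <- cohort$matrix
    if (on("qc")) {
        fl <- flagIqrOutliers(mat)
        nMasked <- sum(qcAnalyteStats(fl$report)$n_outliers)
        filt <- twoStepCallRateFilter(fl$matrix, config$call_rate_thresholds)
        mat <- filt$matrix
        res$qc <- list(outliers = fl$report, filter = filt$report)
        note("qc: masked %d outlier cells; removed %d analytes / %d samples; %d analytes and %d samples retained",
             nMasked, nrow(qcRemoved(filt$report, "analytes")),
             nrow(qcRemoved(filt$report, "samples")), nrow(mat), ncol(mat))
    }
    zmat <- normalizeNpq(mat, "zscore")
    res$normalized <- zmat
    ann <- cohort$annotation[colnames(zmat), ]

    ## daa ------------------------------------------------------------
    if (on("daa")) {
        # one sample per participant: latest draw
        ord <- order(ann$participant_id, -ann$age)
        keepIds <- ann$sample_id[ord][!duplicated(ann$participant_id[ord])]
        zd <- zmat[, keepIds]
        ad <- ann[keepIds, ]
        design <- data.frame(group = ad$group, age = ad$age, sex = ad$sex)
        svs <- estimateSurrogateVariables(zd, design, nSv = config$n_sv,
                                          seed = config$seed)
        daa <- list()
        for (d in .DISEASES) {
            keep <- ad$group %in% c("CO", d)
            daa[[d]] <- fitProteinRegressions(
                zd[, keep],
                data.frame(dx = factor(ad$group[keep], c("CO", d)),
                           age = ad$age[keep], sex = ad$sex[keep]),
                predictor = "dx", covariates = c("age", "sex"),
                svs = svs[keep, , drop = FALSE])
            note("daa %s vs CO: n=%d, %d FDR-significant proteins",
                 d, sum(keep), sum(daa[[d]]$p_fdr < config$fdr_alpha,
                                   na.rm = TRUE))
        }
        res$daa <- daa
        res$svs <- svs
    }

    ## compare --------------------------------------------------------
    if (on("compare")) {
        if (is.null(res$daa)) stop("compare stage requires daa outputs")
        est <- effectSizeTable(res$daa)
        pairs <- utils::combn(.DISEASES, 2, simplify = FALSE)
        ztests <- lapply(pairs, function(pr)
            compareContrasts(res$daa[[pr[1]]], res$daa[[pr[2]]]))
        names(ztests) <- vapply(pairs, paste, character(1), collapse = "_vs_")
        cors <- lapply(pairs, function(pr) correlateEffectSizes(est, pr))
        names(cors) <- names(ztests)
        scorecard <- buildScorecard(est)
        sig <- rownames(est$beta)[apply(est$p_fdr < config$fdr_alpha, 1, any,
                                        na.rm = TRUE)]
        trees <- if (length(sig) >= 2)
            clusterEffectMatrix(list(beta = est$beta[sig, , drop = FALSE]))
        else NULL
        res$compare <- list(table = est, ztests = ztests,
                            correlations = cors, scorecard = scorecard,
                            clustering = trees)
        note("compare: %d pairwise z-test tables; top scorecard protein %s (|score| %d)",
             length(ztests), scorecard$analyte[1], scorecard$absolute_total[1])
    }

    ## cutoff ---------------------------------------------------------
    if (on("cutoff")) {
        bm <- config$biomarker
        if (!bm %in% rownames(zmat)) stop("biomarker '", bm, "' not on the panel")
        vals <- npq(zmat)[bm, ]
        amyPos <- ifelse(is.na(ann$amyloid_cl), NA,
                         ann$amyloid_cl > config$centiloid_threshold)
        cuts <- deriveCutoffs(vals, amyPos, x = zmat, analyte = bm,
                              sensTarget = config$sens_target,
                              specTarget = config$spec_target)
        tri <- classifyThreeWay(vals, cuts)
        res$cutoffs <- list(set = cuts, triclass = tri, biomarker = bm,
                            values = vals, amyloid_positive = amyPos)
        note("cutoff: GMM crossing %.3f (linear NPQ %.1f); youden %.3f; dual [%.3f, %.3f]",
             cuts@gmmCutoff,
             if (length(cuts@linearEquivalents)) cuts@linearEquivalents[["gmm"]] else NA,
             cuts@youdenCutoff, cuts@lowerCutoff, cuts@upperCutoff)
    }

    ## evaluate -------------------------------------------------------
    if (on("evaluate")) {
        if (is.null(res$cutoffs)) stop("evaluate stage requires cutoff outputs")
        vals <- res$cutoffs$values
        amyPos <- res$cutoffs$amyloid_positive
        cuts <- res$cutoffs$set
        paired <- !is.na(amyPos)
        conf <- confusionMetrics(vals[paired] > cuts@gmmCutoff, amyPos[paired])
        tri <- res$cutoffs$triclass$labels
        hl <- paired & tri %in% c("low", "high")
        confDual <- confusionMetrics(tri[hl] == "high", amyPos[hl])
        roc <- tryCatch(
            logisticPredictor(amyPos[paired],
                              data.frame(marker = vals[paired],
                                         age = ann$age[paired],
                                         sex = ann$sex[paired]))$roc,
            error = function(e) NULL)
        kd <- kruskalDunn(vals, ann$group,
                          comparisons = lapply(setdiff(.GROUPS, "AD"),
                                               function(g) c("AD", g)))
        apoeCalls <- npq(zmat)["APOE4proteoform", ] >
            gmmCrossingCutoff(fitTwoComponentGmm(npq(zmat)["APOE4proteoform", ]))
        apoe <- apoeConcordance(apoeCalls, ann$apoe)
        res$evaluation <- list(
            pet_concordance = conf, pet_concordance_dual = confDual,
            roc = roc, kruskal_dunn = kd, apoe = apoe)
        note("evaluate: PET concordance %.2f%% (single) / %.2f%% (dual, %d intermediate excluded); APOE concordance %.2f%%",
             conf$concordance, confDual$concordance,
             sum(paired & tri == "intermediate", na.rm = TRUE),
             apoe$overall$concordance)
    }

    ## progress -------------------------------------------------------
    if (on("progress")) {
        elig <- ann$has_followup & !is.na(ann$time_years)
        recs <- data.frame(time = ann$time_years[elig],
                           event = ann$event[elig],
                           age = ann$age[elig], sex = ann$sex[elig])
        markers <- t(npq(zmat)[, elig, drop = FALSE])
        recs <- cbind(recs, markers)
        hazAn <- intersect(names(which(res$cohort$truth$hazard_log_hr != 0)),
                           rownames(zmat))
        anSet <- union(hazAn, config$biomarker)
        cox <- fitCoxPerProtein(recs, anSet)
        grp <- ifelse(recs[[config$biomarker]] > res$cutoffs$set@gmmCutoff,
                      "high", "low")
        km <- kmEstimate(recs, grp)
        hz <- horizonAuc(recs, as.integer(grp == "high"),
                         horizons = config$horizons)
        res$progression <- list(cox = cox, km = km, horizon = hz,
                                n_eligible = sum(elig),
                                n_events = sum(recs$event))
        note("progress: %d eligible, %d events; %s HR %.2f; log-rank p %.3g",
             sum(elig), sum(recs$event), config$biomarker,
             cox$hr[cox$analyte == config$biomarker], km$p)
    }

    res$log <- log
    res$manifest$stages <- names(which(vapply(config$stages, isTRUE, logical(1))))
    res$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

    if (!is.null(config$out_dir)) .writePipelineOutputs(res, config)
    class(res) <- "PipelineRun"
    res
}

# Write the tabular/JSON outputs of a pipeline run; file contents are
# deterministic functions of the config (timestamps only in memory).
.writePipelineOutputs <- function(res, config) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$out_dir, ...)
    writeAnalyteMatrix(res$cohort$matrix, out("matrix.tsv"))
    utils::write.table(res$cohort$annotation, out("annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c("matrix.tsv", "annotation.tsv")
    if (!is.null(res$daa)) {
        for (d in names(res$daa)) {
            f <- sprintf("daa_%s_vs_CO.tsv", d)
            utils::write.table(res$daa[[d]], out(f), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            files <- c(files, f)
        }
    }
    if (!is.null(res$compare)) {
        utils::write.table(res$compare$scorecard, out("scorecard.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "scorecard.tsv")
        for (pr in names(res$compare$ztests)) {
            f <- sprintf("ztest_%s.tsv", pr)
            utils::write.table(res$compare$ztests[[pr]], out(f), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            files <- c(files, f)
        }
        if (!is.null(res$compare$clustering)) {
            writeDendrogramNewick(res$compare$clustering$rows,
                                  out("dendrogram_rows.newick"))
            writeDendrogramNewick(res$compare$clustering$cols,
                                  out("dendrogram_cols.newick"))
            files <- c(files, "dendrogram_rows.newick", "dendrogram_cols.newick")
        }
    }
    if (!is.null(res$cutoffs)) {
        cuts <- res$cutoffs$set
        jsonlite::write_json(list(
            seed = config$seed, biomarker = res$cutoffs$biomarker,
            gmm_cutoff = cuts@gmmCutoff, youden_cutoff = cuts@youdenCutoff,
            lower_cutoff = cuts@lowerCutoff, upper_cutoff = cuts@upperCutoff,
            linear_equivalents = as.list(cuts@linearEquivalents),
            achieved = as.list(cuts@achieved),
            gmm = list(weights = cuts@gmm@weights, means = cuts@gmm@means,
                       sds = cuts@gmm@sds)),
            out("cutoffs.json"), auto_unbox = TRUE, digits = NA, na = "null")
        files <- c(files, "cutoffs.json")
    }
    if (!is.null(res$progression)) {
        utils::write.table(res$progression$cox, out("cox_results.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "cox_results.tsv")
    }
    writeLines(res$log, out("pipeline.log"))
    files <- c(files, "pipeline.log")
    manifest <- res$manifest
    manifest$outputs <- files
    manifest$file_md5 <- as.list(tools::md5sum(file.path(config$out_dir, files)))
    names(manifest$file_md5) <- files
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    invisible(files)
}

#' @export
print.PipelineRun <- function(x, ...) {
    cat("Pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
    cat(paste0("  ", x$log, collapse = "\n"), "\n")
    invisible(x)
}
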