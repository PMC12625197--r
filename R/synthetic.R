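.GROUPS <- c("CO", "AD", "DLB", "FTD", "PD")
.DISEASES <- c("AD", "DLB", "FTD", "PD")

# Canonical panel analytes with planted structure. The remaining
# analytes are named analyte006..analyteNNN and carry no planted
# disease effect by default.
.CANONICAL <- c("pTau217", "GFAP", "NEFL", "Abeta38", "APOE4proteoform")

.defaultEffectMatrix <- function(analytes) {
    em <- matrix(0, nrow = length(analytes), ncol = length(.DISEASES),
                 dimnames = list(analytes, .DISEASES))
    # effect sizes (within-group SD units) shaped after the canonical
    # dementia plasma markers: pTau217 strongly up in AD, modestly up in
    # DLB, slightly down in PD; GFAP up in AD/DLB/FTD; NEFL up in all
    # four with the largest effect in FTD; Abeta38 down in all four.
    if ("pTau217" %in% analytes)
        em["pTau217", ] <- c(AD = 1.0, DLB = 0.3, FTD = 0, PD = -0.2)
    if ("GFAP" %in% analytes)
        em["GFAP", ] <- c(AD = 0.7, DLB = 0.4, FTD = 0.35, PD = 0)
    if ("NEFL" %in% analytes)
        em["NEFL", ] <- c(AD = 0.4, DLB = 0.5, FTD = 0.95, PD = 0.45)
    if ("Abeta38" %in% analytes)
        em["Abeta38", ] <- c(AD = -0.4, DLB = -0.45, FTD = -0.35, PD = -0.3)
    em
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a generated cohort: five
#' diagnosis groups (CO reference plus AD, DLB, FTD, PD), per-analyte
#' Gaussian noise on the log2 NPQ scale with heteroscedastic SDs drawn
#' log-uniform in \code{sd_range}, planted group effects in
#' within-group SD units, age and sex covariate effects, low-rank
#' latent batch structure, MCAR (or optionally intensity-dependent)
#' missingness, displaced IQR-scale outliers, a bimodal biomarker
#' (named \code{pTau217}) coupled to a latent Centiloid-scale amyloid
#' variable, an APOE-e4 proteoform signal conditional on genotype, and
#' exponential proportional-hazards progression times for baseline
#' controls.
#'
#' Demographics default to the structure of large memory-clinic
#' cohorts: group-specific mean ages (AD 77.4, DLB 75.2, PD 71.7, FTD
#' 67.3, CO 72.8 years), female fractions (0.56, 0.33, 0.37, 0.36,
#' 0.60) and an APOE-e4 carrier frequency near 40\%.
#'
#' @param n_per_group samples per diagnosis group; a single integer or
#'   a named integer vector over \code{c("CO","AD","DLB","FTD","PD")}.
#' @param n_analytes number of analytes on the panel (>= 5; the first
#'   five are the named canonical markers).
#' @param effect_matrix analyte x disease matrix of group effects in SD
#'   units (rows may cover a subset of analytes; missing rows = 0).
#' @param age_effect,sex_effect per-analyte slopes in SD units (per
#'   year of age centered at 73; for male sex), recycled if scalar.
#' @param n_latent number of latent batch factors.
#' @param latent_sd SD of the latent factor loadings (SD units).
#' @param missing_rate,outlier_rate cell-level rates in [0, 1].
#' @param missing_mode \code{"mcar"} (default) or \code{"intensity"}
#'   (missingness concentrated in low-abundance cells, for stress
#'   tests).
#' @param mixture_params list with numeric(2) \code{weights} (sum 1),
#'   \code{means}, \code{sds} for the bimodal biomarker on the z
#'   scale.
#' @param biomarker_pos_prob per-group probability that a sample draws
#'   the high mixture component (overrides \code{weights} inside a
#'   cohort so positivity tracks diagnosis).
#' @param amyloid_coupling correlation in [-1, 1] between the
#'   biomarker and the latent amyloid variable.
#' @param centiloid_threshold amyloid positivity threshold (default 20
#'   Centiloids).
#' @param centiloid_mean,centiloid_sd location/scale mapping the latent
#'   amyloid z to the Centiloid scale.
#' @param pet_frac,csf_frac fraction of samples carrying amyloid-PET /
#'   CSF measurements (the rest are NA, as in real cohorts).
#' @param hazard_log_hr named per-analyte log hazard ratios (per SD of
#'   the marker) for progression; analytes not named have log-HR 0.
#' @param baseline_hazard exponential baseline rate per year (> 0).
#' @param censor_rate fraction of at-risk subjects censored.
#' @param followup_frac fraction of baseline controls with follow-up
#'   (only these enter the progression analysis).
#' @param apoe_freqs named genotype frequencies over
#'   \code{e2e2,e2e3,e3e3,e2e4,e3e4,e4e4}; must sum to 1.
#' @param apoe_separation mean shift of the e4-proteoform z per e4
#'   allele (unit SD noise), so genotype concordance is < 100\% by
#'   design.
#' @param sd_range range of per-analyte SDs (log-uniform draw).
#' @param repeat_frac fraction of participants contributing a second
#'   draw (exercises one-sample-per-participant selection).
#' @param seed integer seed; every generator call is deterministic
#'   given the config.
#'
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(n_per_group = 200L,
                         n_analytes = 123L,
                         effect_matrix = NULL,
                         age_effect = 0.01,
                         sex_effect = 0.1,
                         n_latent = 2L,
                         latent_sd = 0.3,
                         missing_rate = 0.02,
                         outlier_rate = 0.005,
                         missing_mode = c("mcar", "intensity"),
                         mixture_params = list(weights = c(0.54, 0.46),
                                               means = c(-0.75, 0.8),
                                               sds = c(0.5, 0.7)),
                         biomarker_pos_prob = c(CO = 0.25, AD = 0.85,
                                                DLB = 0.55, FTD = 0.35,
                                                PD = 0.35),
                         amyloid_coupling = 0.8,
                         centiloid_threshold = 20,
                         centiloid_mean = 18,
                         centiloid_sd = 35,
                         pet_frac = 0.3,
                         csf_frac = 0.25,
                         hazard_log_hr = c(pTau217 = 0.47, NEFL = 0.1),
                         baseline_hazard = 0.02,
                         censor_rate = 0.6,
                         followup_frac = 0.6,
                         apoe_freqs = c(e2e2 = 0.005, e2e3 = 0.07,
                                        e3e3 = 0.525, e2e4 = 0.02,
                                        e3e4 = 0.30, e4e4 = 0.08),
                         apoe_separation = 5,
                         sd_range = c(0.2, 1.0),
                         repeat_frac = 0,
                         seed = 1L) {
    missing_mode <- match.arg(missing_mode)
    if (length(n_per_group) == 1L)
        n_per_group <- stats::setNames(rep(as.integer(n_per_group), 5), .GROUPS)
    if (!all(.GROUPS %in% names(n_per_group)))
        stop("configuration error in 'n_per_group': needs counts for ",
             paste(.GROUPS, collapse = ", "))
    n_per_group <- n_per_group[.GROUPS]
    if (any(n_per_group < 2))
        stop("configuration error in 'n_per_group': each group needs >= 2 samples")
    n_analytes <- as.integer(n_analytes)
    if (n_analytes < length(.CANONICAL))
        stop("configuration error in 'n_analytes': need at least ",
             length(.CANONICAL))
    analytes <- c(.CANONICAL,
                  sprintf("analyte%03d", seq_len(n_analytes - length(.CANONICAL)) +
                              length(.CANONICAL)))
    em <- .defaultEffectMatrix(analytes)
    if (!is.null(effect_matrix)) {
        effect_matrix <- as.matrix(effect_matrix)
        if (is.null(rownames(effect_matrix)) && nrow(effect_matrix) == n_analytes)
            rownames(effect_matrix) <- analytes
        if (!all(colnames(effect_matrix) %in% .DISEASES))
            stop("configuration error in 'effect_matrix': columns must be diseases ",
                 paste(.DISEASES, collapse = ", "))
        em[] <- 0
        em[rownames(effect_matrix), colnames(effect_matrix)] <- effect_matrix
    }
    for (nm in c("missing_rate", "outlier_rate", "censor_rate", "pet_frac",
                 "csf_frac", "followup_frac", "repeat_frac"))
        .assertRate(get(nm), nm)
    .assertScalarNumber(amyloid_coupling, "amyloid_coupling", -1, 1)
    .assertScalarNumber(latent_sd, "latent_sd", 0, Inf)
    if (baseline_hazard <= 0)
        stop("configuration error in 'baseline_hazard': must be > 0")
    mp <- mixture_params
    if (!is.list(mp) || length(mp$weights) != 2L || length(mp$means) != 2L ||
        length(mp$sds) != 2L)
        stop("configuration error in 'mixture_params': exactly 2 components required")
    if (abs(sum(mp$weights) - 1) > 1e-8 || any(mp$weights < 0))
        stop("configuration error in 'mixture_params': weights must be nonnegative and sum to 1")
    if (any(mp$sds <= 0))
        stop("configuration error in 'mixture_params': sds must be > 0")
    if (abs(sum(apoe_freqs) - 1) > 1e-6 || any(apoe_freqs < 0))
        stop("configuration error in 'apoe_freqs': frequencies must sum to 1")
    if (length(sd_range) != 2L || any(sd_range <= 0) || diff(sd_range) < 0)
        stop("configuration error in 'sd_range': need 0 < lo <= hi")
    hl <- rep(0, n_analytes); names(hl) <- analytes
    if (length(hazard_log_hr)) {
        unknown <- setdiff(names(hazard_log_hr), analytes)
        if (length(unknown))
            stop("configuration error in 'hazard_log_hr': unknown analyte(s) ",
                 paste(unknown, collapse = ", "))
        hl[names(hazard_log_hr)] <- hazard_log_hr
    }
    cfg <- list(n_per_group = n_per_group, n_analytes = n_analytes,
                analytes = analytes, effect_matrix = em,
                age_effect = rep_len(age_effect, n_analytes),
                sex_effect = rep_len(sex_effect, n_analytes),
                n_latent = as.integer(n_latent), latent_sd = latent_sd,
                missing_rate = missing_rate, outlier_rate = outlier_rate,
                missing_mode = missing_mode,
                mixture_params = mp, biomarker_pos_prob = biomarker_pos_prob,
                amyloid_coupling = amyloid_coupling,
                centiloid_threshold = centiloid_threshold,
                centiloid_mean = centiloid_mean, centiloid_sd = centiloid_sd,
                pet_frac = pet_frac, csf_frac = csf_frac,
                hazard_log_hr = hl, baseline_hazard = baseline_hazard,
                censor_rate = censor_rate, followup_frac = followup_frac,
                apoe_freqs = apoe_freqs, apoe_separation = apoe_separation,
                sd_range = sd_range, repeat_frac = repeat_frac,
                seed = as.integer(seed),
                age_mean = c(CO = 72.8, AD = 77.4, DLB = 75.2, FTD = 67.3,
                             PD = 71.7),
                age_sd = c(CO = 10.6, AD = 8.5, DLB = 8.1, FTD = 9.2,
                           PD = 8.5),
                female_frac = c(CO = 0.60, AD = 0.56, DLB = 0.33, FTD = 0.36,
                                PD = 0.37))
    class(cfg) <- "CohortConfig"
    cfg
}

#' Draw the bimodal biomarker with a coupled latent amyloid variable
#'
#' Values come from the two-component normal mixture in
#' \code{config$mixture_params}; the latent amyloid z-variable has
#' correlation \code{amyloid_coupling} with the (standardized)
#' biomarker and is mapped to the Centiloid scale; positivity is
#' \code{amyloid > centiloid_threshold}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param n number of draws.
#' @param seed seed (defaults to \code{config$seed}).
#' @param component optional integer vector in \{1, 2\} fixing each
#'   draw's mixture component (used by \code{\link{generateCohort}} to
#'   make component probability group-dependent); \code{NULL} draws
#'   components from the mixture weights.
#' @return List: \code{biomarker} (z scale), \code{component} (1/2),
#'   \code{amyloid} (Centiloid scale), \code{positive} (logical).
#' @export
generateBimodalBiomarker <- function(config, n, seed = NULL, component = NULL) {
    stopifnot(inherits(config, "CohortConfig"))
    mp <- config$mixture_params
    if (length(mp$weights) != 2L)
        stop("unsupported configuration: the bimodal biomarker requires exactly 2 mixture components")
    .withSeed(if (is.null(seed)) config$seed else seed, {
        if (is.null(component))
            component <- 1L + stats::rbinom(n, 1L, mp$weights[2])
        b <- stats::rnorm(n, mp$means[component], mp$sds[component])
        # population moments of the mixture, for standardization
        mMix <- sum(mp$weights * mp$means)
        vMix <- sum(mp$weights * (mp$sds^2 + mp$means^2)) - mMix^2
        zb <- (b - mMix) / sqrt(vMix)
        rho <- config$amyloid_coupling
        az <- rho * zb + sqrt(1 - rho^2) * stats::rnorm(n)
        amyloid <- config$centiloid_mean + config$centiloid_sd * az
        list(biomarker = b, component = component, amyloid = amyloid,
             positive = amyloid > config$centiloid_threshold)
    })
}

#' Draw proportional-hazards progression times
#'
#' Event times are exponential with subject rate
#' \eqn{\lambda \exp(X \beta)} (baseline rate \code{baseline_hazard},
#' log hazard ratios \code{logHr}); censoring is independent
#' exponential with its rate chosen so each subject is censored with
#' probability \code{censor_rate} (two competing exponentials).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param covariates numeric matrix (subjects x markers) entering the
#'   linear predictor.
#' @param logHr log hazard ratios, one per covariate column (defaults
#'   to the config's \code{hazard_log_hr} matched by column name).
#' @param seed seed (defaults to \code{config$seed}).
#' @return List: \code{time} (years, > 0), \code{event} (0/1).
#' @export
generateSurvivalTimes <- function(config, covariates, logHr = NULL,
                                  seed = NULL) {
    stopifnot(inherits(config, "CohortConfig"))
    covariates <- as.matrix(covariates)
    if (is.null(logHr)) {
        if (is.null(colnames(covariates)))
            stop("covariates need column names to match config$hazard_log_hr")
        logHr <- config$hazard_log_hr[colnames(covariates)]
        logHr[is.na(logHr)] <- 0
    }
    if (length(logHr) != ncol(covariates))
        stop("'logHr' length must match the covariate count")
    if (config$baseline_hazard <= 0)
        stop("configuration error in 'baseline_hazard': must be > 0")
    .withSeed(if (is.null(seed)) config$seed else seed, {
        rate <- config$baseline_hazard * exp(drop(covariates %*% logHr))
        tEvent <- stats::rexp(length(rate), rate)
        if (config$censor_rate > 0) {
            cr <- config$censor_rate
            tCens <- stats::rexp(length(rate), rate * cr / (1 - cr))
            list(time = pmin(tEvent, tCens), event = as.integer(tEvent <= tCens))
        } else {
            list(time = tEvent, event = rep(1L, length(rate)))
        }
    })
}

#' Generate a synthetic cohort
#'
#' Builds a full cohort with the statistical structure the downstream
#' stages assume: a log2-NPQ \linkS4class{AnalyteMatrix} with planted
#' group effects, age/sex covariate effects, rank-\code{n_latent}
#' batch structure, MCAR missingness and displaced (3-6) x IQR
#' outliers; sample annotation (group, age, sex, APOE genotype,
#' partial amyloid-PET Centiloids and CSF ratio, CDR, follow-up and
#' progression outcomes); and a \code{truth} record of everything
#' planted. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return List of class \code{"SyntheticCohort"}: \code{matrix}
#'   (\linkS4class{AnalyteMatrix}, scale \code{log2_npq}),
#'   \code{annotation} (\code{data.frame}), \code{truth} (list).
#' @examples
#' cohort <- generateCohort(cohortConfig(n_per_group = 20, n_analytes = 10))
#' dim(npq(cohort$matrix))
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    .withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
    nG <- config$n_per_group
    n <- sum(nG)
    group <- factor(rep(.GROUPS, nG), levels = .GROUPS)
    analytes <- config$analytes
    p <- config$n_analytes

    participant <- sprintf("part%05d", seq_len(n))
    sampleId <- sprintf("samp%05d", seq_len(n))
    age <- stats::rnorm(n, config$age_mean[as.character(group)],
                        config$age_sd[as.character(group)])
    sexMale <- stats::rbinom(n, 1L,
                             1 - config$female_frac[as.character(group)])
    apoe <- sample(names(config$apoe_freqs), n, replace = TRUE,
                   prob = config$apoe_freqs)
    nE4 <- (grepl("e4", substr(apoe, 1, 2))) + (grepl("e4$", apoe))

    baseMean <- stats::runif(p, 6, 14)
    sdRange <- log(config$sd_range)
    analyteSd <- exp(stats::runif(p, sdRange[1], sdRange[2]))

    # systematic structure on the standardized (SD-unit) scale
    zmat <- matrix(0, p, n, dimnames = list(analytes, sampleId))
    em <- config$effect_matrix
    for (d in .DISEASES) {
        idx <- which(group == d)
        if (length(idx)) zmat[, idx] <- zmat[, idx] + em[, d]
    }
    zmat <- zmat + outer(config$age_effect, age - 73) +
        outer(config$sex_effect, sexMale)

    latentScores <- latentLoadings <- NULL
    if (config$n_latent > 0) {
        latentLoadings <- matrix(stats::rnorm(p * config$n_latent, 0,
                                              config$latent_sd),
                                 p, config$n_latent)
        latentScores <- matrix(stats::rnorm(n * config$n_latent), n,
                               config$n_latent)
        zmat <- zmat + latentLoadings %*% t(latentScores)
    }

    # bimodal biomarker overrides the planted-effect row for pTau217,
    # with the high-component probability tied to diagnosis group
    posProb <- config$biomarker_pos_prob[as.character(group)]
    component <- 1L + stats::rbinom(n, 1L, posProb)
    bio <- generateBimodalBiomarker(config, n, seed = config$seed + 1L,
                                    component = component)
    zmat["pTau217", ] <- bio$biomarker

    # APOE e4 proteoform: genotype-conditional normals with overlap
    zmat["APOE4proteoform", ] <- config$apoe_separation * nE4 +
        stats::rnorm(n)

    noise <- matrix(stats::rnorm(p * n), p, n)
    noise["pTau217" == analytes, ] <- 0   # biomarker noise lives in the mixture
    noise["APOE4proteoform" == analytes, ] <- 0
    zmat <- zmat + noise
    values <- baseMean + analyteSd * zmat

    # outliers: displace by +/- (3-6) x IQR so the QC fence catches them
    outlierCells <- NULL
    if (config$outlier_rate > 0) {
        nOut <- round(config$outlier_rate * p * n)
        if (nOut > 0) {
            cells <- sample(p * n, nOut)
            rows <- ((cells - 1L) %% p) + 1L
            cols <- ((cells - 1L) %/% p) + 1L
            iqr <- apply(values, 1, stats::IQR, na.rm = TRUE)
            shift <- stats::runif(nOut, 3, 6) * iqr[rows] *
                sample(c(-1, 1), nOut, replace = TRUE)
            values[cbind(rows, cols)] <- values[cbind(rows, cols)] + shift
            outlierCells <- data.frame(analyte = analytes[rows],
                                       sample = sampleId[cols],
                                       shift = shift)
        }
    }

    # missingness
    missingCells <- NULL
    if (config$missing_rate > 0) {
        if (config$missing_mode == "mcar") {
            mis <- which(stats::runif(p * n) < config$missing_rate)
        } else {
            # intensity-dependent: low cells miss more, preserving the
            # overall rate on average
            rk <- rank(values) / (p * n)
            pr <- config$missing_rate * 2 * (1 - rk)
            mis <- which(stats::runif(p * n) < pr)
        }
        if (length(mis)) {
            rows <- ((mis - 1L) %% p) + 1L
            cols <- ((mis - 1L) %/% p) + 1L
            values[cbind(rows, cols)] <- NA_real_
            missingCells <- data.frame(analyte = analytes[rows],
                                       sample = sampleId[cols])
        }
    }

    # phenotypes
    amyloidCl <- bio$amyloid
    hasPet <- stats::runif(n) < config$pet_frac
    hasCsf <- stats::runif(n) < config$csf_frac
    az <- (amyloidCl - config$centiloid_mean) / config$centiloid_sd
    csfRatio <- 0.0673 - 0.012 * az + stats::rnorm(n, 0, 0.008)
    cdr <- ifelse(group == "CO",
                  sample(c(0, 0.5), n, replace = TRUE, prob = c(0.9, 0.1)),
                  sample(c(0.5, 1, 2), n, replace = TRUE,
                         prob = c(0.45, 0.4, 0.15)))

    # progression: baseline-unimpaired participants with follow-up
    isCo <- group == "CO"
    hasFollowup <- isCo & stats::runif(n) < config$followup_frac
    time <- rep(NA_real_, n); event <- rep(NA_integer_, n)
    hazAn <- names(config$hazard_log_hr)[config$hazard_log_hr != 0]
    if (any(hasFollowup)) {
        idx <- which(hasFollowup)
        covz <- t(zmat[hazAn, idx, drop = FALSE])
        surv <- generateSurvivalTimes(config, covz,
                                      logHr = config$hazard_log_hr[hazAn],
                                      seed = config$seed + 2L)
        time[idx] <- surv$time
        event[idx] <- surv$event
    }

    annotation <- data.frame(
        sample_id = sampleId, participant_id = participant,
        group = group, age = age, sex = ifelse(sexMale == 1, "M", "F"),
        apoe = apoe, apoe4_pos = nE4 > 0,
        amyloid_cl = ifelse(hasPet, amyloidCl, NA_real_),
        csf_ab42_40 = ifelse(hasCsf, csfRatio, NA_real_),
        cdr = cdr, has_followup = hasFollowup,
        time_years = time, event = event,
        stringsAsFactors = FALSE)

    # optional repeated draws per participant (same biology, fresh noise)
    if (config$repeat_frac > 0) {
        nRep <- max(1L, round(config$repeat_frac * n))
        repIdx <- sort(sample(n, nRep))
        repVals <- values[, repIdx, drop = FALSE] +
            analyteSd * matrix(stats::rnorm(p * nRep, 0, 0.3), p, nRep)
        repIds <- sprintf("samp%05d", n + seq_len(nRep))
        repAnn <- annotation[repIdx, ]
        repAnn$sample_id <- repIds
        repAnn$age <- repAnn$age + stats::runif(nRep, 0.5, 3)
        values <- cbind(values, repVals)
        colnames(values) <- c(sampleId, repIds)
        annotation <- rbind(annotation, repAnn)
    }

    rownames(annotation) <- annotation$sample_id
    am <- AnalyteMatrix(values, sampleData = annotation,
                        scaleTag = "log2_npq")
    truth <- list(config = config, effect_matrix = em,
                  analyte_mean = stats::setNames(baseMean, analytes),
                  analyte_sd = stats::setNames(analyteSd, analytes),
                  latent_scores = latentScores,
                  latent_loadings = latentLoadings,
                  biomarker_component = component,
                  amyloid_cl = amyloidCl,
                  amyloid_positive = bio$positive,
                  apoe_n_e4 = nE4,
                  outlier_cells = outlierCells,
                  missing_cells = missingCells,
                  hazard_log_hr = config$hazard_log_hr)
    structure(list(matrix = am, annotation = annotation, truth = truth),
              class = "SyntheticCohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits \code{matrix.tsv} (samples x analytes dialect of
#' \code{\link{writeAnalyteMatrix}}), \code{annotation.tsv} and
#' \code{truth.json} under \code{dir}.
#'
#' @param cohort a \code{"SyntheticCohort"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(inherits(cohort, "SyntheticCohort"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeAnalyteMatrix(cohort$matrix, file.path(dir, "matrix.tsv"))
    utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- cohort$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         matrix = "rowmajor", na = "null")
    invisible(dir)
}
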