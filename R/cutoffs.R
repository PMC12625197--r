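#' Fit a two-component Gaussian mixture by EM
#'
#' Univariate EM with a deterministic median-split initialization
#' (values below/above the median seed the two components), stopping
#' when the observed-data log-likelihood improves by less than
#' \code{tol} or after \code{maxIter} iterations. Components are
#' relabeled so the first mean is the smaller. A variance floor of
#' \code{1e-4} times the total variance averts component collapse and
#' is flagged when active; a fit collapsing below \code{1e-6} SD
#' despite the floor is an error.
#'
#' @param values numeric vector (>= 10 finite values).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @return A \linkS4class{GMMFit}.
#' @examples
#' set.seed(1)
#' fit <- fitTwoComponentGmm(c(rnorm(300, -2), rnorm(300, 2)))
#' fit
#' @export
fitTwoComponentGmm <- function(values, tol = 1e-8, maxIter = 1000L) {
    x <- values[is.finite(values)]
    if (length(x) < 10L)
        stop("need at least 10 finite values to fit a mixture")
    floorVar <- 1e-4 * stats::var(x)
    med <- stats::median(x)
    lo <- x[x <= med]; hi <- x[x > med]
    if (!length(hi)) { lo <- x[x < med]; hi <- x[x >= med] }
    mu <- c(mean(lo), mean(hi))
    s2 <- pmax(c(stats::var(lo), stats::var(hi)), floorVar)
    s2[is.na(s2)] <- floorVar
    w <- c(length(lo), length(hi)) / length(x)
    ll <- numeric(0)
    floorHit <- FALSE
    iter <- 0L
    converged <- FALSE
    repeat {
        iter <- iter + 1L
        d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
        d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
        tot <- d1 + d2
        ll <- c(ll, sum(log(tot)))
        if (iter > 1L && abs(ll[iter] - ll[iter - 1L]) < tol) {
            converged <- TRUE
            break
        }
        if (iter >= maxIter) break
        g <- d1 / tot                   # responsibility of component 1
        n1 <- sum(g); n2 <- length(x) - n1
        w <- c(n1, n2) / length(x)
        mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
        s2 <- c(sum(g * (x - mu[1])^2) / n1,
                sum((1 - g) * (x - mu[2])^2) / n2)
        if (any(s2 < floorVar)) {
            floorHit <- TRUE
            s2 <- pmax(s2, floorVar)
        }
    }
    if (any(sqrt(s2) < 1e-6))
        stop("degenerate fit: component variance collapsed; ",
             "rerun with a variance floor on rescaled data")
    if (mu[1] > mu[2]) {
        mu <- rev(mu); s2 <- rev(s2); w <- rev(w)
    }
    new("GMMFit", weights = w, means = mu, sds = sqrt(s2), logLik = ll,
        converged = converged, nIter = iter,
        varianceFloorActive = floorHit)
}

#' Flag an overlapping / effectively unimodal mixture fit
#'
#' A two-component fit is degenerate when the fitted mixture density
#' has no interior dip between the component means — the components
#' then describe one mode split in two (e.g. EM applied to a single
#' tight cluster) rather than two separated populations, and a
#' crossing-based cutoff is not meaningful.
#'
#' @param fit a \linkS4class{GMMFit}.
#' @return TRUE when the fitted density is effectively unimodal
#'   between the means.
#' @export
gmmIsDegenerate <- function(fit) {
    grid <- seq(fit@means[1], fit@means[2], length.out = 512)
    dens <- fit@weights[1] * stats::dnorm(grid, fit@means[1], fit@sds[1]) +
        fit@weights[2] * stats::dnorm(grid, fit@means[2], fit@sds[2])
    min(dens) >= 0.999 * min(dens[1], dens[length(dens)])
}

#' Equal-likelihood crossing cutoff of a two-component mixture
#'
#' Solves \eqn{\pi_1 N(x; \mu_1, \sigma_1) = \pi_2 N(x; \mu_2,
#' \sigma_2)} for the point where a sample is equally likely to belong
#' to either component. With unequal variances the log-density
#' equality is quadratic and the root inside \eqn{(\mu_1, \mu_2)} is
#' returned; with equal variances it is linear. The posterior
#' probability of each component at the returned cutoff is 0.5.
#'
#' @param fit a converged \linkS4class{GMMFit}.
#' @return The cutoff (numeric scalar, on the scale of the fitted
#'   values).
#' @examples
#' fit <- new("GMMFit", weights = c(0.7, 0.3), means = c(0, 2),
#'            sds = c(1, 1), logLik = 0, converged = TRUE,
#'            nIter = 1L, varianceFloorActive = FALSE)
#' gmmCrossingCutoff(fit)   # 1 + log(7/3)/2
#' @export
gmmCrossingCutoff <- function(fit) {
    stopifnot(is(fit, "GMMFit"))
    if (!fit@converged)
        warning("mixture fit did not converge; cutoff may be unreliable")
    w <- fit@weights; mu <- fit@means; s <- fit@sds
    # log pi1 - log s1 - (x-mu1)^2/(2 s1^2) = log pi2 - log s2 - (x-mu2)^2/(2 s2^2)
    a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
    b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
    cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
        log(w[1] / w[2]) + log(s[2] / s[1])
    if (abs(a) < 1e-12) {
        if (abs(b) < 1e-12)
            stop("no crossing: identical components")
        root <- -cc / b
        if (root < mu[1] || root > mu[2])
            stop(sprintf(
                "no crossing between the means (root %.4f outside [%.4f, %.4f]); extreme weight imbalance",
                root, mu[1], mu[2]))
        return(root)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0)
        stop("no real crossing point; components too imbalanced")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots >= mu[1] & roots <= mu[2]]
    if (!length(inside))
        stop(sprintf(
            "no crossing between the means (roots %s); extreme weight imbalance",
            paste(sprintf("%.4f", roots), collapse = ", ")))
    inside[1]
}

# sensitivity/specificity of the rule "value > threshold -> positive"
.sensSpec <- function(values, labels, thr) {
    pos <- labels == 1
    c(sens = mean(values[pos] > thr), spec = mean(values[!pos] <= thr))
}

.thresholdCandidates <- function(values) {
    u <- sort(unique(values))
    if (length(u) < 2) return(u)
    (u[-length(u)] + u[-1]) / 2
}

#' Youden-index cutoff
#'
#' Maximizes \eqn{J = sensitivity + specificity - 1} of the rule
#' "value > cutoff is positive" over the midpoints between adjacent
#' sorted unique values; ties in J break toward the smallest cutoff.
#'
#' @param values numeric scores (higher = more positive-like).
#' @param labels binary reference (0/1, logical, or 2-level factor
#'   with the positive level second).
#' @return List: \code{cutoff}, \code{J}, \code{sensitivity},
#'   \code{specificity}.
#' @export
youdenCutoff <- function(values, labels) {
    lab <- .binLabels(labels)
    ok <- !is.na(values) & !is.na(lab)
    values <- values[ok]; lab <- lab[ok]
    if (!any(lab == 1) || !any(lab == 0))
        stop("undefined index: both classes must be present")
    cand <- .thresholdCandidates(values)
    if (!length(cand)) cand <- values[1]
    js <- vapply(cand, function(t) sum(.sensSpec(values, lab, t)) - 1,
                 numeric(1))
    best <- which.max(js)               # first max = smallest cutoff
    ss <- .sensSpec(values, lab, cand[best])
    list(cutoff = cand[best], J = js[best],
         sensitivity = unname(ss["sens"]), specificity = unname(ss["spec"]))
}

.binLabels <- function(labels) {
    if (is.factor(labels)) {
        if (nlevels(labels) != 2L) stop("labels must be binary")
        as.integer(labels) - 1L
    } else if (is.logical(labels)) as.integer(labels)
    else {
        u <- unique(labels[!is.na(labels)])
        if (!all(u %in% c(0, 1))) stop("labels must be binary 0/1")
        as.integer(labels)
    }
}

#' Dual cutoffs at target sensitivity and specificity
#'
#' The lower cutoff is the largest threshold whose sensitivity still
#' meets \code{sensTarget}; the upper cutoff is the smallest threshold
#' whose specificity meets \code{specTarget}. Values between them form
#' the intermediate zone of \code{\link{classifyThreeWay}}. On well
#' separated classes the zone can collapse (lower >= upper), which is
#' flagged. Unattainable targets fall back to the boundary threshold
#' with a warning.
#'
#' @inheritParams youdenCutoff
#' @param sensTarget,specTarget targets in (0.5, 1).
#' @return List: \code{lower}, \code{upper}, \code{achieved} (named
#'   numeric: sens at lower, spec at upper), \code{collapsed}.
#' @export
dualCutoffs <- function(values, labels, sensTarget = 0.95,
                        specTarget = 0.95) {
    lab <- .binLabels(labels)
    ok <- !is.na(values) & !is.na(lab)
    values <- values[ok]; lab <- lab[ok]
    if (!any(lab == 1) || !any(lab == 0))
        stop("both classes must be present")
    for (t in c(sensTarget, specTarget))
        if (t <= 0.5 || t >= 1) stop("targets must lie in (0.5, 1)")
    cand <- sort(c(min(values) - 1, .thresholdCandidates(values)))
    sens <- vapply(cand, function(t) .sensSpec(values, lab, t)["sens"],
                   numeric(1))
    spec <- vapply(cand, function(t) .sensSpec(values, lab, t)["spec"],
                   numeric(1))
    okSens <- which(sens >= sensTarget)
    if (length(okSens)) lower <- cand[max(okSens)]
    else {
        warning("sensitivity target unattainable; using boundary threshold")
        lower <- cand[1]
    }
    okSpec <- which(spec >= specTarget)
    if (length(okSpec)) upper <- cand[min(okSpec)]
    else {
        warning("specificity target unattainable; using boundary threshold")
        upper <- cand[length(cand)]
    }
    collapsed <- lower >= upper
    if (collapsed)
        message("dual cutoffs collapsed (classes well separated): no intermediate zone")
    list(lower = lower, upper = upper,
         achieved = c(sens_at_lower = unname(.sensSpec(values, lab, lower)["sens"]),
                      spec_at_upper = unname(.sensSpec(values, lab, upper)["spec"])),
         collapsed = collapsed)
}

#' Tri-class labeling by dual cutoffs
#'
#' \code{value < lower} is low, \code{value > upper} is high,
#' otherwise intermediate; missing values are excluded and counted
#' separately. Percentages are reported to two decimals, rounding
#' half away from zero.
#'
#' @param values numeric biomarker values.
#' @param lower,upper the dual cutoffs (lower <= upper); a
#'   \linkS4class{CutoffSet} may be given as \code{lower}.
#' @return List: \code{labels} (factor low/intermediate/high with NA
#'   for missing), \code{counts}, \code{percentages}, \code{n_missing}.
#' @export
classifyThreeWay <- function(values, lower, upper = NULL) {
    if (is(lower, "CutoffSet")) {
        upper <- lower@upperCutoff
        lower <- lower@lowerCutoff
    }
    if (lower > upper) stop("lower cutoff must not exceed upper cutoff")
    lab <- rep(NA_character_, length(values))
    obs <- !is.na(values)
    lab[obs & values < lower] <- "low"
    lab[obs & values > upper] <- "high"
    lab[obs & is.na(lab)] <- "intermediate"
    lab <- factor(lab, levels = c("low", "intermediate", "high"))
    counts <- table(lab)
    nObs <- sum(obs)
    list(labels = lab,
         counts = counts,
         percentages = stats::setNames(.pctAway(as.numeric(counts), nObs),
                                       names(counts)),
         n_missing = sum(!obs))
}

#' Derive the full cutoff set for a z-scored biomarker
#'
#' Combines the three cutoff strategies on one biomarker: the
#' two-component GMM equal-likelihood crossing (fit on all values,
#' reference-free), the Youden cutoff and the dual
#' sensitivity/specificity cutoffs (both against a binary reference
#' such as amyloid-PET positivity). When \code{x} carries stored
#' normalization constants, linear-NPQ equivalents of every cutoff are
#' reported via \code{\link{zscoreToLinear}}.
#'
#' @param values z-scored biomarker values, or an
#'   \linkS4class{AnalyteMatrix} plus \code{analyte}.
#' @param labels binary reference labels aligned with values (NA
#'   allowed; only non-missing pairs enter the Youden/dual cutoffs).
#'   If all-NA, only the GMM cutoff is derived.
#' @param x optional z-scored \linkS4class{AnalyteMatrix} carrying
#'   normalization metadata (for linear equivalents).
#' @param analyte analyte id within \code{x} (required with \code{x}).
#' @param sensTarget,specTarget dual-cutoff targets.
#' @return A \linkS4class{CutoffSet}.
#' @export
deriveCutoffs <- function(values, labels = NULL, x = NULL, analyte = NULL,
                          sensTarget = 0.95, specTarget = 0.95) {
    fit <- fitTwoComponentGmm(values)
    gmmCut <- gmmCrossingCutoff(fit)
    ycut <- lcut <- ucut <- NA_real_
    achieved <- numeric(0)
    if (!is.null(labels) && any(!is.na(labels))) {
        yc <- youdenCutoff(values, labels)
        dc <- dualCutoffs(values, labels, sensTarget, specTarget)
        ycut <- yc$cutoff; lcut <- dc$lower; ucut <- dc$upper
        achieved <- c(youden_J = yc$J, dc$achieved)
    }
    lin <- numeric(0)
    if (!is.null(x)) {
        if (is.null(analyte)) stop("'analyte' is required with 'x'")
        cuts <- c(gmm = gmmCut, youden = ycut, lower = lcut, upper = ucut)
        obs <- !is.na(cuts)
        lin <- vapply(cuts[obs], zscoreToLinear, numeric(1), x = x,
                      analyte = analyte)
    }
    new("CutoffSet", gmmCutoff = gmmCut, youdenCutoff = ycut,
        lowerCutoff = lcut, upperCutoff = ucut,
        linearEquivalents = lin, achieved = achieved, gmm = fit)
}
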