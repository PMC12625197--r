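#' Per-protein Cox proportional-hazards regression for progression
#'
#' For each analyte, fits a Cox model of time to symptomatic-AD onset
#' on the (z-scored) marker adjusted for age at draw and sex, with
#' Breslow tie handling, via \code{survival::coxph}. Wald p-values are
#' BH-adjusted across analytes. Analytes whose partial likelihood is
#' monotone (infinite HR) are flagged and returned without an
#' estimate.
#'
#' @param records \code{data.frame} with columns \code{time} (> 0,
#'   years), \code{event} (0/1), \code{age}, \code{sex}, plus one
#'   column per analyte in \code{analytes}.
#' @param analytes character vector of marker column names.
#' @param minEvents minimum number of events required (default 10).
#' @return \code{data.frame}: \code{analyte}, \code{log_hr},
#'   \code{hr}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{p_raw}, \code{p_fdr}, \code{n}, \code{n_events},
#'   \code{flagged_reason}.
#' @export
fitCoxPerProtein <- function(records, analytes, minEvents = 10L) {
    records <- as.data.frame(records)
    need <- c("time", "event", "age", "sex")
    miss <- setdiff(need, colnames(records))
    if (length(miss))
        stop("records missing column(s): ", paste(miss, collapse = ", "))
    if (any(records$time <= 0, na.rm = TRUE))
        stop("all times must be > 0")
    nev <- sum(records$event == 1, na.rm = TRUE)
    if (nev == 0) stop("no events: Cox model undefined")
    if (nev < minEvents)
        warning("fewer than ", minEvents, " events; estimates will be unstable")
    out <- data.frame(analyte = analytes, log_hr = NA_real_, hr = NA_real_,
                      se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p_raw = NA_real_, p_fdr = NA_real_, n = NA_integer_,
                      n_events = NA_integer_, flagged_reason = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(analytes)) {
        an <- analytes[i]
        df <- records[, c("time", "event", "age", "sex", an)]
        names(df)[5] <- "marker"
        df <- df[stats::complete.cases(df), ]
        if (!nrow(df) || sum(df$event) == 0) {
            out$flagged_reason[i] <- "no usable events"
            next
        }
        fit <- tryCatch(
            survival::coxph(survival::Surv(time, event) ~ marker + age + sex,
                            data = df, ties = "breslow"),
            error = function(e) e, warning = function(w) w)
        if (inherits(fit, "condition")) {
            refit <- suppressWarnings(tryCatch(
                survival::coxph(
                    survival::Surv(time, event) ~ marker + age + sex,
                    data = df, ties = "breslow"),
                error = function(e) NULL))
            if (is.null(refit) || !is.finite(stats::coef(refit)["marker"]) ||
                abs(stats::coef(refit)["marker"]) > 15) {
                out$flagged_reason[i] <- "monotone likelihood (infinite HR)"
                next
            }
            fit <- refit
        }
        sm <- summary(fit)
        b <- sm$coefficients["marker", "coef"]
        se <- sm$coefficients["marker", "se(coef)"]
        if (!is.finite(b) || abs(b) > 15) {
            out$flagged_reason[i] <- "monotone likelihood (infinite HR)"
            next
        }
        out$log_hr[i] <- b
        out$hr[i] <- exp(b)
        out$se[i] <- se
        out$ci_low[i] <- exp(b - stats::qnorm(0.975) * se)
        out$ci_high[i] <- exp(b + stats::qnorm(0.975) * se)
        out$p_raw[i] <- sm$coefficients["marker", "Pr(>|z|)"]
        out$n[i] <- nrow(df)
        out$n_events[i] <- sum(df$event)
    }
    fitted <- !is.na(out$p_raw)
    out$p_fdr[fitted] <- adjustBH(out$p_raw[fitted])
    attr(out, "ties") <- "breslow"
    out
}

#' Kaplan-Meier curves by biomarker group with log-rank comparison
#'
#' Product-limit survival estimates per group (typically high vs low
#' by the GMM biomarker cutoff) and the log-rank test p-value.
#'
#' @param records \code{data.frame} with \code{time}, \code{event}.
#' @param groups group labels aligned with \code{records} rows.
#' @return List: \code{curves} (named list of \code{data.frame}s with
#'   \code{time}, \code{survival}, \code{n_risk}), \code{p} (log-rank;
#'   NA when undefined, e.g. all censored), \code{fit} (the
#'   \code{survfit} object).
#' @export
kmEstimate <- function(records, groups) {
    records <- as.data.frame(records)
    groups <- factor(groups)
    if (any(table(groups) == 0) || nlevels(groups) < 1)
        stop("every group must contain at least one record")
    df <- data.frame(time = records$time, event = records$event,
                     group = groups)
    df <- df[stats::complete.cases(df), ]
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- if (is.null(fit$strata)) {
        stats::setNames(list(seq_along(fit$time)), levels(groups)[1])
    } else {
        idx <- rep(seq_along(fit$strata), fit$strata)
        split(seq_along(fit$time), names(fit$strata)[idx])
    }
    curves <- lapply(strata, function(ii)
        data.frame(time = fit$time[ii], survival = fit$surv[ii],
                   n_risk = fit$n.risk[ii]))
    names(curves) <- sub("^group=", "", names(curves))
    p <- NA_real_
    if (sum(df$event) > 0 && nlevels(droplevels(df$group)) > 1) {
        sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                                 data = df)
        p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
    }
    list(curves = curves, p = p, fit = fit)
}

#' Fixed-horizon discrimination of a dichotomized marker
#'
#' For each horizon (default 5, 10, 15 years), defines progressors as
#' subjects with an event by the horizon and non-progressors as
#' subjects followed at least to the horizon without an event
#' (censored-early subjects are ambiguous and excluded), fits a
#' logistic model of horizon status on the dichotomized marker plus
#' age and sex, and evaluates the fitted probabilities with
#' \code{\link{rocAucDelong}}.
#'
#' @param records \code{data.frame} with \code{time}, \code{event},
#'   \code{age}, \code{sex}.
#' @param marker binary (dichotomized) marker aligned with rows.
#' @param horizons numeric vector of years.
#' @return \code{data.frame}: \code{horizon}, \code{auc},
#'   \code{ci_low}, \code{ci_high}, \code{n}, \code{n_progressed},
#'   \code{skipped_reason}.
#' @export
horizonAuc <- function(records, marker, horizons = c(5, 10, 15)) {
    records <- as.data.frame(records)
    out <- data.frame(horizon = horizons, auc = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n = NA_integer_,
                      n_progressed = NA_integer_,
                      skipped_reason = NA_character_)
    for (i in seq_along(horizons)) {
        h <- horizons[i]
        progressed <- records$event == 1 & records$time <= h
        nonProg <- records$time >= h & !(records$event == 1 & records$time <= h)
        eligible <- (progressed | nonProg) & !is.na(marker)
        y <- ifelse(progressed[eligible], 1L, 0L)
        if (!any(y == 1) || !any(y == 0)) {
            out$skipped_reason[i] <- "a horizon class is empty"
            next
        }
        fit <- tryCatch(
            logisticPredictor(y, data.frame(marker = marker[eligible],
                                            age = records$age[eligible],
                                            sex = records$sex[eligible])),
            error = function(e) e)
        if (inherits(fit, "error")) {
            if (grepl("separation", conditionMessage(fit))) {
                # the adjusted logistic fit diverges when the marker (or a
                # covariate) splits the classes; discrimination is still
                # well-defined, so rank the marker alone
                roc <- rocAucDelong(marker[eligible], y)
                out$skipped_reason[i] <- "separation: unadjusted marker AUC"
                out$auc[i] <- roc$auc
                out$ci_low[i] <- roc$ci_low
                out$ci_high[i] <- roc$ci_high
                out$n[i] <- sum(eligible)
                out$n_progressed[i] <- sum(y)
            } else out$skipped_reason[i] <- conditionMessage(fit)
            next
        }
        out$auc[i] <- fit$roc$auc
        out$ci_low[i] <- fit$roc$ci_low
        out$ci_high[i] <- fit$roc$ci_high
        out$n[i] <- fit$n
        out$n_progressed[i] <- sum(y)
    }
    out
}
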