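## Outcome association for signature strata: Kaplan-Meier curves, log-rank
## (Mantel-Cox) tests, Cox proportional-hazards regression and chi-square /
## Fisher association between categorical assignments. The heavy lifting is
## delegated to the survival package (survfit / survdiff / coxph with Efron
## tie handling); this module fixes the conventions and output contracts.

#' Assemble a validated survival table
#'
#' One row per (sample, endpoint): positive follow-up time in months,
#' binary event indicator, plus any clinical covariates.
#'
#' @param sample sample identifiers.
#' @param time positive follow-up times (months).
#' @param event 0 = censored, 1 = event.
#' @param endpoint endpoint label: "OS", "DSS" or "DFS".
#' @param covariates optional data.frame of per-sample covariates.
#' @return data.frame with columns sample, endpoint, time, event and the
#'   covariates.
#' @export
survivalTable <- function(sample, time, event, endpoint = "OS",
                          covariates = NULL) {
    endpoint <- match.arg(endpoint, c("OS", "DSS", "DFS"))
    stopifnot(length(sample) == length(time), length(time) == length(event))
    if (any(time <= 0)) stop("follow-up times must be positive")
    if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
    df <- data.frame(sample = as.character(sample), endpoint = endpoint,
                     time = as.numeric(time), event = as.integer(event),
                     stringsAsFactors = FALSE)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    if (anyDuplicated(df[, c("sample", "endpoint")]))
        stop("one row per (sample, endpoint) required")
    df
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival step function over the distinct event times, with S(0) = 1 and
#' right-censoring handled by risk-set decrement.
#'
#' @param time positive follow-up times.
#' @param event 0 = censored, 1 = event.
#' @return data.frame with one row per distinct event time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival}.
#' @export
kmEstimate <- function(time, event) {
    stopifnot(length(time) >= 1)
    if (any(time <= 0)) stop("follow-up times must be positive")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    keep <- fit$n.event > 0
    data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
               n_event = fit$n.event[keep], survival = fit$surv[keep])
}

#' Log-rank (Mantel-Cox) test
#'
#' At every distinct event time a K x 2 table of events by group is
#' formed; the statistic (O - E)' V^-1 (O - E) is referred to chi-square
#' with K - 1 degrees of freedom.
#'
#' @param group group label per subject (>= 2 non-empty groups).
#' @param time positive follow-up times.
#' @param event 0 = censored, 1 = event.
#' @return list of class \code{"LogRankResult"}: \code{chisq}, \code{df},
#'   \code{p}, \code{observed} and \code{expected} event counts per group.
#' @export
logrankTest <- function(group, time, event) {
    group <- as.factor(group)
    if (nlevels(group) < 2) stop("need at least 2 groups")
    if (any(table(group) == 0)) stop("empty group level")
    if (any(time <= 0)) stop("follow-up times must be positive")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
    df <- nlevels(group) - 1L
    out <- list(chisq = unname(sd$chisq), df = df,
                p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                observed = stats::setNames(as.numeric(sd$obs),
                                           levels(group)),
                expected = stats::setNames(as.numeric(sd$exp),
                                           levels(group)))
    class(out) <- "LogRankResult"
    out
}

#' @export
print.LogRankResult <- function(x, ...) {
    cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
                x$chisq, x$df, x$p))
    print(data.frame(observed = x$observed, expected = x$expected))
    invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. Univariate
#' mode fits each covariate alone; multivariate mode fits all jointly.
#'
#' @param data data.frame holding the covariates plus time/event columns.
#' @param covariates character vector of covariate column names.
#' @param timeCol,eventCol column names for follow-up time and event.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @return data.frame with one row per coefficient: \code{covariate},
#'   \code{term}, \code{hr}, \code{lower95}, \code{upper95}, \code{p},
#'   \code{flag} ("" or "separation").
#' @export
coxFit <- function(data, covariates, timeCol = "time", eventCol = "event",
                   mode = c("univariate", "multivariate")) {
    mode <- match.arg(mode)
    stopifnot(all(c(covariates, timeCol, eventCol) %in% names(data)))
    for (cv in covariates) {
        v <- data[[cv]]
        if (length(unique(v[!is.na(v)])) < 2)
            stop("covariate '", cv, "' is constant across samples")
    }
    if (sum(data[[eventCol]]) < length(covariates) + 1)
        stop("fewer events than covariates + 1")
    if (mode == "multivariate" && length(covariates) > 1) {
        for (i in seq_along(covariates)[-1]) for (j in seq_len(i - 1)) {
            if (isTRUE(all.equal(as.numeric(as.factor(data[[covariates[i]]])),
                                 as.numeric(as.factor(data[[covariates[j]]])))))
                stop("collinear covariates: '", covariates[j], "' and '",
                     covariates[i], "' are duplicates")
        }
    }
    fitOne <- function(cvs) {
        fml <- stats::as.formula(paste0(
            "survival::Surv(", timeCol, ", ", eventCol, ") ~ ",
            paste(cvs, collapse = " + ")))
        warn <- character(0)
        fit <- withCallingHandlers(
            survival::coxph(fml, data = data, ties = "efron"),
            warning = function(w) {
                warn <<- c(warn, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        co <- summary(fit)
        if (anyNA(stats::coef(fit)))
            stop("Cox fit produced undefined coefficients (collinearity)")
        sep <- any(abs(stats::coef(fit)) > 15) ||
            any(grepl("infinite|converge", warn))
        data.frame(covariate = cvs[1],
                   term = rownames(co$coefficients),
                   hr = unname(co$coefficients[, "exp(coef)"]),
                   lower95 = unname(co$conf.int[, "lower .95"]),
                   upper95 = unname(co$conf.int[, "upper .95"]),
                   p = unname(co$coefficients[, "Pr(>|z|)"]),
                   flag = if (sep) "separation" else "",
                   row.names = NULL)
    }
    if (mode == "univariate") {
        do.call(rbind, lapply(covariates, fitOne))
    } else {
        out <- fitOne(covariates)
        out$covariate <- sub("[0-9.]+$", "", out$term)
        out
    }
}

#' Chi-square association of a 2x2 table
#'
#' Pearson chi-square without continuity correction; when any expected
#' cell is below 5, Fisher's exact test is run as well and its p-value
#' reported alongside.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list: \code{chisq}, \code{df}, \code{p}, \code{fisher_p} (NA
#'   unless any expected cell < 5), \code{expected}.
#' @export
chisqAssociation <- function(tab, correct = FALSE) {
    tab <- as.matrix(tab)
    stopifnot(all(tab >= 0), all(abs(tab - round(tab)) < 1e-8))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("table has a zero margin")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    fisherP <- NA_real_
    if (any(ct$expected < 5))
        fisherP <- stats::fisher.test(tab)$p.value
    list(chisq = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value), fisher_p = fisherP,
         expected = ct$expected)
}

#' Export Kaplan-Meier curves per group as a TSV-ready table
#'
#' @param group group label per subject.
#' @param time,event follow-up and event indicators.
#' @return data.frame with columns group, time, n_risk, n_event, survival.
#' @export
kmCurvesByGroup <- function(group, time, event) {
    group <- as.factor(group)
    do.call(rbind, lapply(levels(group), function(g) {
        ix <- group == g
        if (!any(ix)) return(NULL)
        km <- kmEstimate(time[ix], event[ix])
        cbind(group = g, km)
    }))
}
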