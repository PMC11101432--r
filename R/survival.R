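#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function, optionally stratified by
#' group. Backed by [survival::survfit()]; returned as a tidy step-function
#' table so curves can be written to TSV for plotting.
#'
#' @param time nonnegative event/censoring times (months).
#' @param event 0/1 event indicators (1 = event).
#' @param group optional grouping vector (e.g. the classified subtype).
#' @return data.frame with columns `group` (if given), `time`, `n_risk`,
#'   `n_event`, `survival`; survival starts at 1, is nonincreasing and
#'   right-continuous within each group.
#' @export
km_curve <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
  } else {
    stopifnot(length(group) == length(time))
    g <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    data.frame(group = sub("^g=", "", strata), time = fit$time,
               n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv, stringsAsFactors = FALSE)
  }
}

#' Log-rank test across groups
#'
#' Standard (unweighted) K-sample log-rank test with df = K - 1, via
#' [survival::survdiff()].
#'
#' @inheritParams km_curve
#' @param group grouping vector with at least two non-empty groups.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  g <- droplevels(factor(group))
  if (nlevels(g) < 2L) stop("log-rank needs >= 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Multivariable Cox regression with Efron tie handling and Wald confidence
#' intervals, via [survival::coxph()]. When a `subtype` term is present it
#' is releveled so LP is the reference group, matching how the LD-vs-LP
#' contrasts are reported.
#'
#' @param data data.frame containing `time`, `event` and the model terms.
#' @param terms character vector of covariate column names (default
#'   `"subtype"`).
#' @param time_col,event_col names of the time and event columns.
#' @param conf confidence level for the hazard-ratio CIs.
#' @return object of class `cox_result`: data.frame with one row per model
#'   term (`term`, `hr`, `lower`, `upper`, `p`), plus attributes `reference`
#'   (named reference levels) and `fit` (the underlying coxph fit).
#' @export
cox_fit <- function(data, terms = "subtype", time_col = "time",
                    event_col = "event", conf = 0.95) {
  stopifnot(is.data.frame(data), all(terms %in% names(data)),
            all(c(time_col, event_col) %in% names(data)))
  check_surv_input(data[[time_col]], data[[event_col]])
  refs <- character(0)
  for (tm in terms) {
    v <- data[[tm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (length(unique(v)) < 2L) {
        stop("term '", tm, "' has zero variance", call. = FALSE)
      }
      if ("LP" %in% levels(v)) v <- stats::relevel(v, ref = "LP")
      data[[tm]] <- v
      refs[tm] <- levels(v)[1L]
    } else if (stats::sd(v, na.rm = TRUE) == 0) {
      stop("term '", tm, "' has zero variance", call. = FALSE)
    }
  }
  n_events <- sum(data[[event_col]])
  if (n_events < length(terms)) {
    warning("fewer events (", n_events, ") than model terms", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(
    term = names(beta),
    hr = exp(beta),
    lower = exp(beta - z * se),
    upper = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "reference") <- refs
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", class(out))
  out
}

check_surv_input <- function(time, event) {
  stopifnot(is.numeric(time), length(time) == length(event))
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(TRUE)
}

#' Survival analysis of a classified cohort for one endpoint
#'
#' Convenience wrapper running the Kaplan-Meier estimate, the log-rank test
#' and a Cox fit (subtype term, LP reference) for one endpoint of a
#' classified case table.
#'
#' @param cases classified case table (needs `classified` plus
#'   `time_<endpoint>` / `event_<endpoint>` columns).
#' @param endpoint one of `"os"`, `"rfs"`, `"dfs"`.
#' @param covariates optional extra covariate columns for the Cox model.
#' @return list with `km` (step table), `logrank`, `cox`.
#' @export
survival_by_subtype <- function(cases, endpoint = c("os", "rfs", "dfs"),
                                covariates = character(0)) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  stopifnot(all(c(tcol, ecol, "classified") %in% names(cases)))
  df <- cases
  df$subtype <- factor(df$classified, SUBTYPE_LEVELS)
  list(
    km = km_curve(df[[tcol]], df[[ecol]], df$subtype),
    logrank = logrank_test(df[[tcol]], df[[ecol]], df$subtype),
    cox = cox_fit(df, terms = c("subtype", covariates),
                  time_col = tcol, event_col = ecol)
  )
}
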