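#' Kaplan-Meier estimate of recurrence-free survival
#'
#' Product-limit estimate with Greenwood variance and log-log 95%
#' confidence bounds (clamped to `[0, 1]` by construction), optionally
#' split by a grouping covariate.
#'
#' @param data data.frame with `time` (> 0) and `event` (0/1) columns.
#' @param group optional name of a grouping column in `data`.
#' @param conf_level confidence level for the pointwise bounds.
#' @return data.frame of curve steps: `group` (or `"all"`), `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`. A group
#'   with zero events yields a flat curve at 1 with a warning.
#' @export
km_estimate <- function(data, group = NULL, conf_level = 0.95) {
  check_survival_frame(data)
  if (!is.null(group)) {
    if (!group %in% names(data)) stop("grouping column '", group, "' not found")
    g <- factor(data[[group]])
    if (any(tapply(data$event, g, sum) == 0)) {
      warning("group with zero events: flat survival curve, degenerate CI")
    }
    fit <- survfit(Surv(data$time, data$event) ~ g,
                   conf.type = "log-log", conf.int = conf_level)
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  } else {
    if (sum(data$event) == 0) {
      warning("zero events: flat survival curve, degenerate CI")
    }
    fit <- survfit(Surv(data$time, data$event) ~ 1,
                   conf.type = "log-log", conf.int = conf_level)
    grp <- rep("all", length(fit$time))
  }
  data.frame(
    group = grp,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    lower = ifelse(is.na(fit$lower), fit$surv, fit$lower),
    upper = ifelse(is.na(fit$upper), fit$surv, fit$upper),
    stringsAsFactors = FALSE
  )
}

#' Log-rank test for a difference between survival curves
#'
#' Standard (unweighted) log-rank chi-square with `groups - 1` degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @param group name of the grouping column (>= 2 groups required).
#' @return list of class `"tilprox_test"`: `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
logrank_test <- function(data, group) {
  check_survival_frame(data)
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2) {
    stop("log-rank test needs at least two groups")
  }
  if (sum(data$event) < 1) stop("log-rank test needs at least one event")
  sd <- survdiff(Surv(data$time, data$event) ~ g)
  df <- length(sd$n) - 1
  test_result(unname(sd$chisq), df,
              pchisq(sd$chisq, df, lower.tail = FALSE), "log-rank")
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization (Newton-Raphson, coefficient tolerance
#' 1e-9, at most 100 iterations) with Efron tie handling by default
#' (Breslow available). Hazard-ratio confidence intervals are Wald
#' intervals on the log-HR scale. Non-convergence and infinite
#' coefficients (monotone likelihood / complete separation) raise
#' explicit errors.
#'
#' Character or factor covariates are modeled through their factor
#' levels; a `<metric>_class` column with levels `high`/`low` therefore
#' yields the hazard ratio of `low` relative to `high`.
#'
#' @inheritParams km_estimate
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `"cox_fit"`: `coefficients` (log-HRs),
#'   `hazard_ratios` (data.frame with `hr`, `lower`, `upper`, `p_value`),
#'   `loglik`, `loglik_null`, `score_test`, `n`, `n_events`, `ties`,
#'   `covariates`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  check_survival_frame(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("covariate column(s) not found: ",
                         paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      stop("covariate '", cv, "' is constant: no contrast to estimate")
    }
  }
  if (sum(data$event) < 1) stop("no events: cannot fit a Cox model")
  fml <- stats::as.formula(paste("Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- coxph(fml, data = data, ties = ties,
               control = coxph.control(eps = 1e-9, iter.max = 100))
  if (!is.null(fit$info) && grepl("infinite", tolower(paste(fit$info)))) {
    stop("Cox fit diverged (monotone likelihood / separation)")
  }
  co <- coef(fit)
  if (any(!is.finite(co)) || any(abs(co) > 15)) {
    stop("Cox fit did not converge to finite coefficients ",
         "(possible complete separation)")
  }
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  hrs <- data.frame(
    term = names(co),
    hr = exp(co),
    lower = exp(co - z * se),
    upper = exp(co + z * se),
    p_value = 2 * pnorm(-abs(co / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = co,
    hazard_ratios = hrs,
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    score_test = unname(fit$score),
    n = fit$n,
    n_events = fit$nevent,
    ties = ties,
    covariates = covariates,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(x$hazard_ratios, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested Cox models
#'
#' Valid when the reduced model's covariates are a subset of the full
#' model's and both were fitted to the same records; both conditions are
#' checked.
#'
#' @param full,reduced two [cox_fit()] objects.
#' @return a test-result list (`statistic`, `df`, `p_value`, `method`).
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (!all(reduced$covariates %in% full$covariates)) {
    stop("models are not nested: reduced covariates must be a subset of full")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    stop("models were fitted to different records")
  }
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- length(full$coefficients) - length(reduced$coefficients)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  test_result(stat, df, p, "likelihood-ratio (nested Cox)")
}

#' Grambsch-Therneau test of proportional hazards
#'
#' Scaled Schoenfeld residuals regressed on Kaplan-Meier-transformed time
#' (the conventional default transform), giving a per-covariate
#' chi-square (df 1) and a global test.
#'
#' @param fit a [cox_fit()].
#' @return data.frame: `term`, `statistic`, `df`, `p_value` (last row is
#'   the global test).
#' @export
ph_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) stop("proportionality test needs at least 3 events")
  z <- cox.zph(fit$fit, transform = "km")
  tab <- as.data.frame(z$table)
  data.frame(
    term = rownames(tab),
    statistic = tab$chisq,
    df = tab$df,
    p_value = tab$p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = as.integer(df),
                 p_value = p_value, method = method),
            class = "tilprox_test")
}

#' @export
print.tilprox_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

check_survival_frame <- function(data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c("time", "event"), names(data))
  if (length(miss)) stop("survival data lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(data$time)) || any(data$time <= 0)) {
    stop("follow-up times must be finite and strictly positive")
  }
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}
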