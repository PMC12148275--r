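#' Kruskal-Wallis rank test across groups
#'
#' H statistic with the midrank ties correction, referred to a chi-square
#' with `groups - 1` degrees of freedom.
#'
#' @param groups named list of numeric vectors (one per group, each
#'   nonempty), or a single numeric vector when `g` is given.
#' @param g grouping factor aligned to `groups` when the latter is a
#'   vector.
#' @return a test-result list (`statistic` = H, `df`, `p_value`,
#'   `method`).
#' @export
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 20, 30)))
kruskal_wallis <- function(groups, g = NULL) {
  if (is.list(groups)) {
    lens <- lengths(groups)
    if (length(groups) < 2) stop("need at least two groups")
    if (any(lens == 0)) stop("every group must be nonempty")
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lens))
  } else {
    stopifnot(!is.null(g), length(groups) == length(g))
    x <- groups
    g <- factor(g)
    if (nlevels(droplevels(g)) < 2) stop("need at least two groups")
    if (any(table(droplevels(g)) == 0)) stop("every group must be nonempty")
  }
  if (length(x) < 3) stop("need at least 3 observations in total")
  kt <- kruskal.test(x, g)
  test_result(unname(kt$statistic), unname(kt$parameter),
              kt$p.value, "Kruskal-Wallis")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of midranks; the p-value uses the t
#' approximation, appropriate for the moderate-to-large samples the
#' biomarkers are compared on.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list: `rho`, plus `statistic`/`df`/`p_value`/`method`. A
#'   constant input vector gives `rho = NA` with a warning (correlation
#'   undefined).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, method = "Spearman"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  n <- length(x)
  list(rho = rho, statistic = unname(ct$statistic), df = n - 2L,
       p_value = ct$p.value, method = "Spearman (t approximation)")
}

#' Odds ratio for a 2x2 contingency table
#'
#' For counts `a` (class 1, biomarker high), `b` (class 1, low), `c`
#' (class 2, high), `d` (class 2, low):
#' \describe{
#'   \item{sample}{`(a*d)/(b*c)` with the Woolf log-normal confidence
#'     interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.}
#'   \item{conditional_mle}{exact conditional maximum-likelihood estimate
#'     under the noncentral hypergeometric distribution, with the exact
#'     conditional confidence interval.}
#' }
#' A zero cell makes the sample OR degenerate; rather than silently
#' applying a continuity correction, the function errors and recommends
#' `method = "conditional_mle"`.
#'
#' @param a,b,c,d nonnegative integer counts; alternatively `a` may be a
#'   2x2 matrix `rbind(c(a, b), c(c, d))`.
#' @param method `"sample"` (default; matches reported one-decimal point
#'   estimates) or `"conditional_mle"`.
#' @param conf_level confidence level.
#' @return list: `or`, `lower`, `upper`, `method`, `counts`.
#' @export
#' @examples
#' odds_ratio_2x2(283, 29, 401, 201)$or  # ~4.9
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           method = c("sample", "conditional_mle"),
                           conf_level = 0.95) {
  method <- match.arg(method)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (method == "sample") {
    if (b == 0 || c == 0) {
      stop("zero cell in the denominator: the sample odds ratio is ",
           "undefined; use method = 'conditional_mle' (no silent 0.5 ",
           "continuity correction is applied)")
    }
    or <- (a * d) / (b * c)
    if (a == 0 || d == 0) {
      # OR = 0 exactly; Woolf CI undefined
      return(list(or = or, lower = NA_real_, upper = NA_real_,
                  method = "sample", counts = counts))
    }
    z <- qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = or, lower = exp(log(or) - z * se),
         upper = exp(log(or) + z * se),
         method = "sample (Woolf CI)", counts = counts)
  } else {
    ft <- fisher.test(matrix(c(a, c, b, d), 2), conf.level = conf_level)
    or <- unname(ft$estimate)
    if (!is.finite(or)) {
      warning("degenerate table: conditional MLE odds ratio is infinite")
    }
    list(or = or, lower = ft$conf.int[1], upper = ft$conf.int[2],
         method = "conditional MLE (exact CI)", counts = counts)
  }
}

#' Load the packaged biomarker-by-class contingency counts
#'
#' High/low counts of the three binarized spatial biomarkers (proximity,
#' consistency, lymphocyte count) against two molecular dichotomies:
#' adaptive-enriched immune class vs the combined innate-enriched/quiet
#' classes, and any-genomic-instability (AGI) vs none (NGI).
#'
#' @return data.frame: `biomarker`, `comparison`, `class`, `referent`
#'   (logical; TRUE marks the referent row of each table), `high`, `low`.
#' @export
load_contingency_fixture <- function() {
  path <- system.file("extdata", "immune_class_contingency.csv",
                      package = "tilprox", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(out$high >= 0), all(out$low >= 0))
  out
}

#' Odds ratios for all packaged biomarker-by-class tables
#'
#' @param method passed to [odds_ratio_2x2()].
#' @return data.frame with one row per biomarker x comparison: the OR,
#'   its CI, and the OR rounded to one decimal as conventionally
#'   reported.
#' @export
contingency_odds_ratios <- function(method = "sample") {
  counts <- load_contingency_fixture()
  combos <- unique(counts[, c("biomarker", "comparison")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- counts[counts$biomarker == combos$biomarker[i] &
                    counts$comparison == combos$comparison[i], ]
    top <- sub[!sub$referent, ]
    ref <- sub[sub$referent, ]
    res <- odds_ratio_2x2(top$high, top$low, ref$high, ref$low,
                          method = method)
    data.frame(biomarker = combos$biomarker[i],
               comparison = combos$comparison[i],
               or = res$or, lower = res$lower, upper = res$upper,
               or_1dp = round(res$or, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
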