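#' Proximity, consistency and lymphocyte count for one participant
#'
#' From the pooled log10 nearest-neighbor distances:
#' \describe{
#'   \item{proximity}{`3 - mean(log10 NND)`. High values mean CD8 T cells
#'     sit close to tumor cells on average. Lies in `[0, 3]` whenever all
#'     distances are in `[1, 1000]` microns.}
#'   \item{consistency}{`1 - var(log10 NND)` (sample variance, n-1
#'     denominator). High values mean uniform tumor-CD8 spacing. Bounded
#'     above by 1; values below 0 are possible for extreme spreads and
#'     are flagged, not clamped.}
#' }
#' The lymphocyte count is the raw CD8 + Treg tally over QC-passed cores
#' (not area-normalized), so it scales with the number of cores a
#' participant contributed; `n_cores_passed` is carried alongside for
#' that reason.
#'
#' @param sample an [pool_participant()] result.
#' @param lymphocyte_count CD8 + Treg count over passed cores.
#' @param n_cores_passed number of cores pooled.
#' @return one-row data.frame: `participant_id`, `proximity`,
#'   `consistency`, `lymphocyte_count`, `n_distances`, `capped_count`,
#'   `n_cores_passed`, `flag` (empty, `"no_distances"`,
#'   `"single_distance"`, or `"negative_consistency"`).
#' @export
#' @examples
#' s <- pool_participant(list(c(10, 100)), "P1")
#' compute_metrics(s, lymphocyte_count = 5, n_cores_passed = 1)
compute_metrics <- function(sample, lymphocyte_count, n_cores_passed) {
  stopifnot(inherits(sample, "nnd_sample"),
            lymphocyte_count >= 0, n_cores_passed >= 0)
  v <- sample$values
  flag <- ""
  if (length(v) == 0) {
    proximity <- NA_real_; consistency <- NA_real_
    flag <- "no_distances"
  } else {
    proximity <- 3 - mean(v)
    if (length(v) < 2) {
      consistency <- NA_real_
      flag <- "single_distance"
    } else {
      consistency <- 1 - var(v)
      if (consistency < 0) flag <- "negative_consistency"
    }
  }
  data.frame(
    participant_id = sample$participant_id,
    proximity = proximity,
    consistency = consistency,
    lymphocyte_count = as.integer(lymphocyte_count),
    n_distances = sample$n_distances,
    capped_count = sample$capped_count,
    n_cores_passed = as.integer(n_cores_passed),
    flag = flag,
    stringsAsFactors = FALSE
  )
}

#' Spatial biomarkers for every participant in a classified cell table
#'
#' Runs the per-core nearest-neighbor computation and per-participant
#' pooling over all QC-passed cores. With
#' `include_double_positive = TRUE` (the sensitivity analysis), Tregs —
#' CD8+FoxP3+ double positives — also count as CD8 targets for the
#' distances, which can only shrink them, so per-participant proximity is
#' monotone nondecreasing under the toggle. The lymphocyte count is
#' CD8 + Treg in either case.
#'
#' @param cells classified cell table ([classify_cells()] output).
#' @param summaries QC-flagged core summaries ([qc_filter_cores()]).
#' @param cap,no_cd8_policy see [nearest_neighbor_distances()].
#' @param include_double_positive count Tregs as CD8 targets for the
#'   distance computation.
#' @return data.frame with one [compute_metrics()] row per participant
#'   that has at least one passed core; participants whose cores all fail
#'   QC (or are all dropped under `"drop-core"`) are returned with
#'   `flag = "no_passed_cores"` and `NA` metrics, never silently removed.
#' @export
compute_cohort_metrics <- function(cells, summaries, cap = 1000,
                                   no_cd8_policy = c("assign-cap",
                                                     "drop-core"),
                                   include_double_positive = FALSE) {
  no_cd8_policy <- match.arg(no_cd8_policy)
  stopifnot("cell_class" %in% names(cells),
            "passed_qc" %in% names(summaries))
  if (anyNA(summaries$passed_qc)) {
    stop("run qc_filter_cores() before computing cohort metrics")
  }
  target_classes <- if (include_double_positive) c("cd8", "treg") else "cd8"
  passed <- summaries$core_id[summaries$passed_qc]

  out <- lapply(unique(cells$participant_id), function(p) {
    sub <- cells[cells$participant_id == p, , drop = FALSE]
    cores <- intersect(unique(sub$core_id), passed)
    if (length(cores) == 0) {
      empty <- compute_metrics(pool_participant(list(), p),
                               lymphocyte_count = 0, n_cores_passed = 0)
      empty$flag <- "no_passed_cores"
      return(empty)
    }
    dists <- lapply(cores, function(cid) {
      core <- sub[sub$core_id == cid, , drop = FALSE]
      nearest_neighbor_distances(
        tumor_xy = as.matrix(core[core$cell_class == "tumor",
                                  c("x_um", "y_um")]),
        cd8_xy = as.matrix(core[core$cell_class %in% target_classes,
                                c("x_um", "y_um")]),
        cap = cap, no_cd8_policy = no_cd8_policy)
    })
    kept <- !vapply(dists, is.null, logical(1))
    lymph <- sum(sub$cell_class %in% c("cd8", "treg") &
                   sub$core_id %in% cores)
    res <- compute_metrics(pool_participant(dists[kept], p),
                           lymphocyte_count = lymph,
                           n_cores_passed = sum(kept))
    if (sum(kept) == 0) res$flag <- "no_passed_cores"
    res
  })
  out <- do.call(rbind, out)
  attr(out, "settings") <- list(cap = cap, no_cd8_policy = no_cd8_policy,
                                include_double_positive = include_double_positive,
                                pooling = "concatenate-then-moments")
  rownames(out) <- NULL
  out
}

#' Binarize a biomarker at a cohort cutpoint
#'
#' Cutpoints are computed on the analysis cohort (after exclusions), with
#' the linear-interpolation quantile convention (R type 7). A value at or
#' above the cutpoint is `"high"`. The analysis defaults, arrived at by
#' quartile-collapse exploration in the source study, are: 1st quartile
#' for proximity, median for consistency, median for lymphocyte count.
#'
#' @param values numeric biomarker values (NAs are returned as NA and
#'   excluded from the cutpoint computation).
#' @param rule `"median"`, `"q1"`, or `"explicit"`.
#' @param explicit_value the cutpoint when `rule = "explicit"`.
#' @return factor with levels `high`, `low`; attribute `cutpoint` records
#'   the value used.
#' @export
#' @examples
#' binarize(c(1, 2, 3, 4), "median")  # low low high high
binarize <- function(values, rule = c("median", "q1", "explicit"),
                     explicit_value = NULL) {
  rule <- match.arg(rule)
  obs <- values[!is.na(values)]
  if (rule == "explicit") {
    if (is.null(explicit_value) || !is.finite(explicit_value)) {
      stop("rule = 'explicit' requires a finite explicit_value")
    }
    cut <- explicit_value
  } else {
    if (length(unique(obs)) < 2) {
      stop("quantile cutpoint is degenerate: fewer than 2 distinct values")
    }
    cut <- unname(quantile(obs, probs = if (rule == "median") 0.5 else 0.25,
                           type = 7))
  }
  out <- factor(ifelse(values >= cut, "high", "low"),
                levels = c("high", "low"))
  attr(out, "cutpoint") <- cut
  attr(out, "rule") <- rule
  out
}

#' Explore biomarker cutpoints by collapsing quartile hazard groups
#'
#' Reproduces the cutpoint-selection procedure: split participants into
#' four groups at the biomarker quartiles, fit a univariate Cox model
#' with group indicators (top quartile as referent), and merge adjacent
#' groups whose log hazard ratios differ by less than `epsilon`
#' (agglomerative: repeatedly merge the adjacent pair of blocks with the
#' smallest event-weighted mean log-HR gap while that gap is below
#' `epsilon`). The boundary between the final two blocks is the suggested
#' cutpoint. If everything collapses to one block the metric carries no
#' hazard signal and no cutpoint is suggested; if more than two blocks
#' survive, the boundary at the largest adjacent gap is reported. The
#' result is advisory — analysis defaults remain the fixed quartile
#' rules in [binarize()].
#'
#' A quartile group with zero events cannot support a hazard ratio and is
#' merged into its neighbor toward the referent before fitting, with a
#' warning.
#'
#' @param values biomarker values, one per participant.
#' @param surv data.frame with `time` and `event` aligned to `values`.
#' @param epsilon log-HR collapse tolerance (default `log(1.5)`: groups
#'   whose hazards differ by less than 1.5-fold merge).
#' @return list: `cutpoint` (value or NA), `quantile` (0.25/0.5/0.75 or
#'   NA), `log_hr` (per quartile group, referent 0), `blocks` (block id
#'   per quartile group), `quartiles` (the three split values).
#' @export
explore_cutpoints <- function(values, surv, epsilon = log(1.5)) {
  stopifnot(length(values) == nrow(surv),
            all(c("time", "event") %in% names(surv)))
  if (epsilon <= 0) stop("epsilon must be positive")
  ok <- !is.na(values)
  values <- values[ok]; surv <- surv[ok, , drop = FALSE]
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7)
  grp <- findInterval(values, q, left.open = FALSE) + 1L  # value >= q enters upper group
  grp <- pmin(pmax(grp, 1L), 4L)

  events_per <- tapply(surv$event, factor(grp, levels = 1:4), sum)
  events_per[is.na(events_per)] <- 0
  fit_groups <- 1:4
  if (any(events_per == 0)) {
    warning("quartile group(s) with zero events merged toward the referent")
    # relabel each zero-event group to its neighbor nearer group 4
    for (g in which(events_per == 0)) {
      grp[grp == g] <- if (g < 4L) g + 1L else 3L
    }
  }

  present <- sort(unique(grp))
  f <- factor(grp, levels = rev(present))  # first level (referent) = top group
  log_hr <- setNames(rep(0, 4), 1:4)
  if (length(present) >= 2) {
    fit <- coxph(Surv(surv$time, surv$event) ~ f)
    co <- coef(fit)
    for (g in present[-length(present)]) {
      log_hr[as.character(g)] <- unname(co[paste0("f", g)])
    }
  }

  # agglomerative merge of adjacent quartile blocks
  blocks <- as.list(1:4)
  n_events <- as.numeric(events_per)
  block_val <- function(b) {
    w <- n_events[b]
    if (sum(w) == 0) mean(log_hr[b]) else sum(w * log_hr[b]) / sum(w)
  }
  repeat {
    if (length(blocks) == 1) break
    vals <- vapply(blocks, block_val, numeric(1))
    gaps <- abs(diff(vals))
    i <- which.min(gaps)
    if (gaps[i] >= epsilon) break
    blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
    blocks[[i + 1]] <- NULL
  }

  if (length(blocks) == 1) {
    boundary <- NA_integer_
  } else if (length(blocks) == 2) {
    boundary <- max(blocks[[1]])
  } else {
    vals <- vapply(blocks, block_val, numeric(1))
    i <- which.max(abs(diff(vals)))
    boundary <- max(blocks[[i]])
  }

  block_id <- integer(4)
  for (b in seq_along(blocks)) block_id[blocks[[b]]] <- b
  list(
    cutpoint = if (is.na(boundary)) NA_real_ else unname(q[boundary]),
    quantile = if (is.na(boundary)) NA_real_ else c(0.25, 0.5, 0.75)[boundary],
    log_hr = log_hr,
    blocks = block_id,
    quartiles = q
  )
}
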