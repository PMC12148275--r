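#' Configure an end-to-end pipeline run
#'
#' Exactly one of `cell_table`/`survival`/`labels` paths or a
#' `simulation` block must be supplied. Thresholds are required for real
#' inputs; for simulated input they default to the thresholds implied by
#' the simulation's intensity parameters ([suggested_thresholds()]).
#'
#' @param cell_table,survival,labels input CSV paths (`labels` optional).
#' @param simulation a [simulation_config()] for a synthetic run.
#' @param thresholds a [threshold_set()].
#' @param qc list with `min_tumor`, `min_total`, `mode` (see
#'   [qc_filter_cores()]).
#' @param cap,no_cd8_policy,include_double_positive see
#'   [compute_cohort_metrics()].
#' @param cutpoints named list of binarization rules per metric; the
#'   defaults are the analysis cutpoints (proximity: 1st quartile;
#'   consistency and count: median).
#' @param seed integer seed; for simulated runs it overrides the
#'   simulation block's seed so one value governs the whole run.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cell_table = NULL, survival = NULL,
                            labels = NULL, simulation = NULL,
                            thresholds = NULL,
                            qc = list(min_tumor = 1000, min_total = 3000,
                                      mode = "and"),
                            cap = 1000,
                            no_cd8_policy = "assign-cap",
                            include_double_positive = FALSE,
                            cutpoints = list(proximity = "q1",
                                             consistency = "median",
                                             count = "median"),
                            seed = NULL) {
  has_paths <- !is.null(cell_table)
  has_sim <- !is.null(simulation)
  if (has_paths == has_sim) {
    stop("exactly one of input paths (cell_table [+ survival, labels]) ",
         "or a simulation block must be given")
  }
  if (has_sim) {
    stopifnot(inherits(simulation, "simulation_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
    if (is.null(thresholds)) {
      thresholds <- suggested_thresholds(simulation$intensity_params)
    }
  } else {
    if (is.null(thresholds)) {
      stop("thresholds are required for real input tables (they are a ",
           "per-batch calibration with no universal default)")
    }
    if (!is.null(survival) && !file.exists(survival)) {
      stop("survival file not found: ", survival)
    }
  }
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("min_tumor", "min_total", "mode") %in% names(qc)))
  cfg <- list(cell_table = cell_table, survival = survival, labels = labels,
              simulation = simulation, thresholds = thresholds, qc = qc,
              cap = cap, no_cd8_policy = no_cd8_policy,
              include_double_positive = include_double_positive,
              cutpoints = cutpoints,
              seed = if (has_sim) simulation$seed else seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: classify -> core QC -> spatial metrics -> binarize
#' -> survival models (Kaplan-Meier, log-rank, univariate and
#' multivariable Cox with a nested likelihood-ratio test against a
#' count-only model) -> label association (2x2 odds ratios). Input files
#' are never modified; identical config + seed gives identical outputs.
#' Participants excluded at any stage are recorded with reasons, never
#' silently dropped.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, all result tables
#'   are written as CSV plus a JSON run manifest (config, hash, seed,
#'   cutpoints used, participant accounting).
#' @return list of class `"pipeline_result"`: `metrics`, `summaries`,
#'   `km_curves`, `tests`, `cox_models`, `odds_ratios`, `exclusions`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation, cap = config$cap)
    cells <- cohort$cells
    surv <- cohort$survival
    labels <- cohort$labels
  } else {
    cells <- read_cell_table(config$cell_table)
    surv <- if (!is.null(config$survival)) {
      read_survival_table(config$survival)
    } else NULL
    labels <- if (!is.null(config$labels)) {
      read_labels_table(config$labels)
    } else NULL
  }
  n_input <- length(unique(cells$participant_id))

  cells <- classify_cells(cells, config$thresholds)
  summaries <- summarize_cores(cells)
  summaries <- qc_filter_cores(summaries, config$qc$min_tumor,
                               config$qc$min_total, config$qc$mode)

  metrics <- compute_cohort_metrics(
    cells, summaries, cap = config$cap,
    no_cd8_policy = config$no_cd8_policy,
    include_double_positive = config$include_double_positive)

  exclusions <- metrics[metrics$flag %in%
                          c("no_passed_cores", "no_distances",
                            "single_distance"),
                        c("participant_id", "flag")]
  names(exclusions) <- c("participant_id", "reason")
  analysis <- metrics[!metrics$participant_id %in% exclusions$participant_id, ]

  cutpoints_used <- list()
  metric_cols <- c(proximity = "proximity", consistency = "consistency",
                   count = "lymphocyte_count")
  degenerate <- character(0)
  for (m in names(config$cutpoints)) {
    col <- metric_cols[[m]]
    cls <- tryCatch(binarize(analysis[[col]], rule = config$cutpoints[[m]]),
                    error = function(e) NULL)
    if (is.null(cls)) {
      # e.g. a cohort with no lymphocytes: every proximity equals the cap
      # value, the quantile cutpoint is undefined, the metric is dropped
      # from the binarized analysis and recorded in the manifest
      degenerate <- c(degenerate, m)
      next
    }
    analysis[[paste0(m, "_class")]] <- as.character(cls)
    cutpoints_used[[m]] <- attr(cls, "cutpoint")
  }
  usable_metrics <- setdiff(names(config$cutpoints), degenerate)

  km_curves <- NULL; tests <- list(); cox_models <- list()
  model_failures <- character(0)
  # a failed model fit (e.g. separation on a tiny cohort) is recorded in
  # the manifest; earlier stage outputs are kept intact
  safely <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      model_failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (!is.null(surv) && length(usable_metrics)) {
    joined <- merge(analysis, surv, by = "participant_id")
    class_cols <- paste0(usable_metrics, "_class")
    for (m in usable_metrics) {
      col <- paste0(m, "_class")
      joined[[col]] <- factor(joined[[col]], levels = c("high", "low"))
      km <- safely(paste0("km_", m), km_estimate(joined, group = col))
      if (!is.null(km)) {
        km$metric <- m
        km_curves <- rbind(km_curves, km)
      }
      tests[[paste0("logrank_", m)]] <-
        safely(paste0("logrank_", m), logrank_test(joined, col))
      cox_models[[paste0("univariate_", m)]] <-
        safely(paste0("cox_", m), cox_fit(joined, col))
    }
    cox_models$multivariable <-
      safely("cox_multivariable", cox_fit(joined, class_cols))
    if (!is.null(cox_models$multivariable) &&
        "count_class" %in% class_cols && length(class_cols) > 1) {
      tests$lrt_spatial_vs_count_only <- safely("lrt", {
        count_only <- cox_fit(joined, "count_class")
        lrt_nested(cox_models$multivariable, count_only)
      })
    }
    tests <- Filter(Negate(is.null), tests)
    cox_models <- Filter(Negate(is.null), cox_models)
  }

  odds_ratios <- NULL
  if (!is.null(labels)) {
    lj <- merge(analysis, labels, by = "participant_id")
    lev <- sort(unique(lj$label))
    if (length(lev) == 2) {
      for (m in usable_metrics) {
        col <- paste0(m, "_class")
        a <- sum(lj$label == lev[1] & lj[[col]] == "high")
        b <- sum(lj$label == lev[1] & lj[[col]] == "low")
        cc <- sum(lj$label == lev[2] & lj[[col]] == "high")
        dd <- sum(lj$label == lev[2] & lj[[col]] == "low")
        res <- tryCatch(odds_ratio_2x2(a, b, cc, dd), error = function(e) {
          model_failures[[paste0("or_", m)]] <<- conditionMessage(e)
          NULL
        })
        if (is.null(res)) next
        odds_ratios <- rbind(odds_ratios, data.frame(
          metric = m, class1 = lev[1], class2 = lev[2],
          a = a, b = b, c = cc, d = dd,
          or = res$or, lower = res$lower, upper = res$upper,
          stringsAsFactors = FALSE))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tilprox")),
    seed = config$seed,
    config_hash = config_hash(config),
    qc = config$qc,
    cap = config$cap,
    no_cd8_policy = config$no_cd8_policy,
    include_double_positive = config$include_double_positive,
    cutpoint_rules = config$cutpoints,
    cutpoints_used = cutpoints_used,
    degenerate_metrics = as.list(degenerate),
    participants = list(
      input = n_input,
      with_passed_cores = n_input - sum(exclusions$reason == "no_passed_cores"),
      analyzed = nrow(analysis)
    ),
    cores = list(total = nrow(summaries),
                 passed_qc = sum(summaries$passed_qc)),
    model_failures = as.list(model_failures)
  )

  result <- structure(list(
    metrics = analysis, summaries = summaries, km_curves = km_curves,
    tests = tests, cox_models = cox_models, odds_ratios = odds_ratios,
    exclusions = exclusions, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_output_csv(analysis, output_dir, "metrics.csv")
    write_output_csv(summaries, output_dir, "core_summaries.csv")
    write_output_csv(exclusions, output_dir, "exclusions.csv")
    if (!is.null(km_curves)) {
      write_output_csv(km_curves, output_dir, "km_curves.csv")
    }
    if (length(cox_models)) {
      hr_rows <- do.call(rbind, lapply(names(cox_models), function(nm) {
        h <- cox_models[[nm]]$hazard_ratios
        h$model <- nm
        h
      }))
      write_output_csv(hr_rows, output_dir, "cox_summary.csv")
    }
    if (length(tests)) {
      test_rows <- do.call(rbind, lapply(names(tests), function(nm) {
        t <- tests[[nm]]
        data.frame(test = nm, method = t$method, statistic = t$statistic,
                   df = t$df, p_value = t$p_value)
      }))
      write_output_csv(test_rows, output_dir, "tests.csv")
    }
    if (!is.null(odds_ratios)) {
      write_output_csv(odds_ratios, output_dir, "odds_ratios.csv")
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("tilprox pipeline result:", x$manifest$participants$analyzed,
      "participants analyzed (", x$manifest$cores$passed_qc, "/",
      x$manifest$cores$total, "cores passed QC)\n")
  invisible(x)
}

# Deterministic fingerprint of the configuration: rolling polynomial hash
# of the canonical JSON serialization (mod 2^31 - 1, exact in doubles).
config_hash <- function(config) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [pipeline_config()]; a `simulation:`
#' mapping is passed to [simulation_config()], and a `thresholds:`
#' mapping (`t_ck`, `t_cd8`, `t_foxp3`) to [threshold_set()].
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(threshold_set, raw$thresholds)
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(pipeline_config, raw)
}
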