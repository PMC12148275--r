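#' Default log-normal marker-intensity parameters
#'
#' One row per (true class, channel) pair giving the `meanlog`/`sdlog` of
#' the log-normal distribution the simulator draws mean channel
#' intensities from. Positive markers sit at a median of 10 arbitrary
#' fluorescence units, negative at 1, with `sdlog = 0.35`; a threshold at
#' the geometric midpoint (`sqrt(10) ~ 3.16`) then misclassifies well
#' under 1% of cells, emulating a clean stain. Hoechst is positive for
#' every nucleated cell; CK marks tumor; CD8 marks CD8 T cells and Tregs;
#' FoxP3 marks Tregs only.
#'
#' @param positive_meanlog,negative_meanlog log-scale locations for
#'   marker-positive and marker-negative cells.
#' @param sdlog common log-scale spread; raise it to make threshold
#'   classification harder.
#' @return data.frame with columns `class`, `channel`, `meanlog`, `sdlog`.
#' @export
default_intensity_params <- function(positive_meanlog = log(10),
                                     negative_meanlog = log(1),
                                     sdlog = 0.35) {
  classes <- c("tumor", "cd8", "treg", "stromal")
  channels <- c("hoechst", "ck", "cd8", "foxp3")
  positive <- list(
    tumor   = c("hoechst", "ck"),
    cd8     = c("hoechst", "cd8"),
    treg    = c("hoechst", "cd8", "foxp3"),
    stromal = "hoechst"
  )
  grid <- expand.grid(class = classes, channel = channels,
                      stringsAsFactors = FALSE)
  grid$meanlog <- ifelse(
    mapply(function(cl, ch) ch %in% positive[[cl]], grid$class, grid$channel),
    positive_meanlog, negative_meanlog)
  grid$sdlog <- sdlog
  grid
}

#' Thresholds implied by a set of intensity parameters
#'
#' Places each channel threshold at the geometric midpoint between the
#' positive-class and negative-class median intensities, the point that
#' (for equal `sdlog`) minimizes per-channel misclassification.
#'
#' @param intensity_params as from [default_intensity_params()].
#' @return A [threshold_set()].
#' @export
suggested_thresholds <- function(intensity_params = default_intensity_params()) {
  mid <- function(channel) {
    m <- intensity_params$meanlog[intensity_params$channel == channel]
    exp((max(m) + min(m)) / 2)
  }
  threshold_set(t_ck = mid("ck"), t_cd8 = mid("cd8"), t_foxp3 = mid("foxp3"))
}

#' Configure a synthetic TMA cohort simulation
#'
#' Defines the study conditions for [simulate_cohort()] and friends:
#' cohort shape (participants, 1 mm cores per participant), spatial point
#' processes for tumor and lymphocyte cells, marker-intensity
#' distributions, the proportional-hazards model generating
#' recurrence-free-survival outcomes, and the logistic model linking
#' binarized biomarkers to a molecular class label.
#'
#' Tumor cells follow a Thomas (parent-offspring Gaussian) cluster
#' process inside the core disc, mimicking clustered epithelium.
#' Lymphocytes follow the chosen `infiltration_mode`: `"diffuse"`
#' (homogeneous Poisson over the disc), `"hotspot"` (Gaussian clusters
#' around `hotspot_count` random centers with spread `hotspot_sd`), or
#' `"peripheral"` (intensity increasing linearly with radial distance).
#' Stromal cells (classified as unclassified downstream) are homogeneous
#' Poisson. Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_m * 1[metric m low]))` and independent
#' exponential censoring.
#'
#' @param n_participants number of participants (positive integer).
#' @param cores_per_participant cores per participant, in 1..8 (the study
#'   design takes up to four cores per tissue sample, up to eight when two
#'   samples were taken).
#' @param core_radius core radius in microns (1 mm core => 500).
#' @param tumor_intensity expected tumor cells per core (> 0).
#' @param lymphocyte_intensity expected CD8 + Treg cells per core (>= 0).
#' @param stromal_intensity expected unclassified stromal cells per core.
#' @param infiltration_mode `"diffuse"`, `"hotspot"` or `"peripheral"`.
#' @param hotspot_count,hotspot_sd number and Gaussian spread (microns) of
#'   lymphocyte hotspots (hotspot mode only).
#' @param tumor_parents,tumor_cluster_sd expected parent count and
#'   offspring spread (microns) of the tumor Thomas process.
#' @param treg_fraction fraction of lymphocytes that are Tregs
#'   (CD8+FoxP3+ double positives), in `[0, 1]`.
#' @param intensity_params per-class per-channel log-normal parameters;
#'   see [default_intensity_params()].
#' @param survival_betas named log-hazard-ratio vector for *low* biomarker
#'   status; names among `"proximity"`, `"consistency"`, `"count"`.
#' @param baseline_hazard events per unit time for the all-high group.
#' @param censor_rate independent exponential censoring rate (>= 0; 0
#'   disables censoring). Default 0.2 with `baseline_hazard` 0.05 yields
#'   roughly a 20% event fraction.
#' @param label_log_odds named log-odds vector for class-label membership
#'   given *high* biomarker status.
#' @param label_intercept logistic intercept; default `-sum(label_log_odds)/2`
#'   balances the label margins.
#' @param seed global integer seed; expanded into per-core and per-stage
#'   substreams via [substream_seed()], so identical config + seed gives a
#'   bit-identical cohort.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants,
                              cores_per_participant = 4,
                              core_radius = 500,
                              tumor_intensity = 1500,
                              lymphocyte_intensity = 150,
                              stromal_intensity = 2000,
                              infiltration_mode = c("diffuse", "hotspot", "peripheral"),
                              hotspot_count = 3,
                              hotspot_sd = 50,
                              tumor_parents = 8,
                              tumor_cluster_sd = 80,
                              treg_fraction = 0.2,
                              intensity_params = default_intensity_params(),
                              survival_betas = c(proximity = log(2)),
                              baseline_hazard = 0.05,
                              censor_rate = 0.2,
                              label_log_odds = c(proximity = log(5)),
                              label_intercept = NULL,
                              seed = 1L) {
  infiltration_mode <- match.arg(infiltration_mode)
  stopifnot(
    length(n_participants) == 1L, n_participants >= 1,
    n_participants == floor(n_participants),
    cores_per_participant %in% 1:8
  )
  if (!is.finite(core_radius) || core_radius <= 0) {
    stop("core_radius must be a positive length in microns")
  }
  if (!is.finite(tumor_intensity) || tumor_intensity <= 0) {
    stop("tumor_intensity must be strictly positive")
  }
  if (lymphocyte_intensity < 0 || stromal_intensity < 0) {
    stop("lymphocyte_intensity and stromal_intensity must be nonnegative")
  }
  if (treg_fraction < 0 || treg_fraction > 1) {
    stop("treg_fraction must lie in [0, 1]")
  }
  if (baseline_hazard <= 0) stop("baseline_hazard must be strictly positive")
  if (censor_rate < 0) stop("censor_rate must be nonnegative")
  if (hotspot_count < 1 || hotspot_sd <= 0 || tumor_parents < 1 ||
      tumor_cluster_sd <= 0) {
    stop("clustering controls must be positive")
  }
  stopifnot(is.data.frame(intensity_params),
            all(c("class", "channel", "meanlog", "sdlog") %in%
                  names(intensity_params)))
  if (length(survival_betas) && is.null(names(survival_betas))) {
    stop("survival_betas must be a named vector")
  }
  if (length(label_log_odds) && is.null(names(label_log_odds))) {
    stop("label_log_odds must be a named vector")
  }
  if (is.null(label_intercept)) label_intercept <- -sum(label_log_odds) / 2
  cfg <- list(
    n_participants = as.integer(n_participants),
    cores_per_participant = as.integer(cores_per_participant),
    core_radius = core_radius,
    tumor_intensity = tumor_intensity,
    lymphocyte_intensity = lymphocyte_intensity,
    stromal_intensity = stromal_intensity,
    infiltration_mode = infiltration_mode,
    hotspot_count = hotspot_count,
    hotspot_sd = hotspot_sd,
    tumor_parents = tumor_parents,
    tumor_cluster_sd = tumor_cluster_sd,
    treg_fraction = treg_fraction,
    intensity_params = intensity_params,
    survival_betas = survival_betas,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    label_log_odds = label_log_odds,
    label_intercept = label_intercept,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# Uniform points on a disc of radius R centered at the origin.
runif_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  theta <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

# Gaussian displacements around assigned centers, redrawn until inside the
# disc (points still outside after max_iter draws are pulled radially in).
gaussian_in_disc <- function(centers, sd, radius, max_iter = 200L) {
  n <- nrow(centers)
  pts <- centers + matrix(rnorm(2 * n, sd = sd), ncol = 2)
  for (i in seq_len(max_iter)) {
    out <- rowSums(pts^2) > radius^2
    if (!any(out)) break
    pts[out, ] <- centers[out, , drop = FALSE] +
      matrix(rnorm(2 * sum(out), sd = sd), ncol = 2)
  }
  out <- rowSums(pts^2) > radius^2
  if (any(out)) {
    nrm <- sqrt(rowSums(pts[out, , drop = FALSE]^2))
    pts[out, ] <- pts[out, , drop = FALSE] * (0.999 * radius / nrm)
  }
  colnames(pts) <- c("x", "y")
  pts
}

draw_intensities <- function(classes, params) {
  n <- length(classes)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("hoechst", "ck", "cd8", "foxp3")))
  for (cl in unique(classes)) {
    idx <- classes == cl
    for (ch in colnames(out)) {
      row <- params$class == cl & params$channel == ch
      if (!any(row)) stop("intensity_params missing class '", cl,
                          "' channel '", ch, "'")
      out[idx, ch] <- exp(rnorm(sum(idx), params$meanlog[row][1],
                                params$sdlog[row][1]))
    }
  }
  out
}

#' Simulate the cells of one TMA core
#'
#' Draws tumor, lymphocyte and stromal cells inside a disc of radius
#' `config$core_radius` and attaches per-channel mean intensities from
#' each cell's true class. The core's random stream is derived from the
#' global seed via [substream_seed()]`(seed, participant_index,
#' core_index)`, so any core is reproducible in isolation; the caller's
#' RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @param participant_index,core_index positive integers identifying the
#'   core; they also name the output rows (`P0001`, `P0001-C1`, ...).
#' @return data.frame with one row per cell: `participant_id`, `core_id`,
#'   `x_um`, `y_um`, `intensity_hoechst`, `intensity_ck`, `intensity_cd8`,
#'   `intensity_foxp3`, `true_class` (one of tumor / cd8 / treg / stromal).
#' @export
simulate_core <- function(config, participant_index, core_index) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- substream_seed(config$seed, participant_index, core_index)
  with_seed(seed, {
    R <- config$core_radius

    n_tumor <- rpois(1, config$tumor_intensity)
    if (n_tumor > 0) {
      n_par <- max(1L, rpois(1, config$tumor_parents))
      parents <- runif_disc(n_par, R)
      assign_idx <- sample.int(n_par, n_tumor, replace = TRUE)
      tumor_xy <- gaussian_in_disc(parents[assign_idx, , drop = FALSE],
                                   config$tumor_cluster_sd, R)
    } else {
      tumor_xy <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    }

    n_lymph <- if (config$lymphocyte_intensity > 0) {
      rpois(1, config$lymphocyte_intensity)
    } else 0L
    if (n_lymph > 0) {
      lymph_xy <- switch(
        config$infiltration_mode,
        diffuse = runif_disc(n_lymph, R),
        hotspot = {
          centers <- runif_disc(config$hotspot_count, R)
          idx <- sample.int(config$hotspot_count, n_lymph, replace = TRUE)
          gaussian_in_disc(centers[idx, , drop = FALSE], config$hotspot_sd, R)
        },
        peripheral = {
          # radial intensity proportional to r => density f(r) ~ r^2
          r <- R * runif(n_lymph)^(1 / 3)
          theta <- runif(n_lymph, 0, 2 * pi)
          cbind(x = r * cos(theta), y = r * sin(theta))
        })
      is_treg <- runif(n_lymph) < config$treg_fraction
    } else {
      lymph_xy <- matrix(numeric(0), 0, 2)
      is_treg <- logical(0)
    }

    n_stromal <- if (config$stromal_intensity > 0) {
      rpois(1, config$stromal_intensity)
    } else 0L
    stromal_xy <- if (n_stromal > 0) runif_disc(n_stromal, R) else
      matrix(numeric(0), 0, 2)

    classes <- c(rep("tumor", n_tumor),
                 ifelse(is_treg, "treg", "cd8"),
                 rep("stromal", n_stromal))
    xy <- rbind(tumor_xy, lymph_xy, stromal_xy)
    inten <- draw_intensities(classes, config$intensity_params)

    data.frame(
      participant_id = sprintf("P%04d", participant_index),
      core_id = sprintf("P%04d-C%d", participant_index, core_index),
      x_um = unname(xy[, 1]),
      y_um = unname(xy[, 2]),
      intensity_hoechst = unname(inten[, "hoechst"]),
      intensity_ck = unname(inten[, "ck"]),
      intensity_cd8 = unname(inten[, "cd8"]),
      intensity_foxp3 = unname(inten[, "foxp3"]),
      true_class = classes,
      stringsAsFactors = FALSE
    )
  })
}

# Stage tags for per-stage substreams (arbitrary fixed primes).
.stage_key <- c(survival = 104729L, labels = 104723L)

#' Simulate recurrence-free-survival outcomes under proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_m * 1[metric m == "low"]))`; censoring
#' is independent exponential with rate `censor_rate`. Observed time is
#' the minimum of the two and the event indicator marks which came first.
#'
#' @param metrics_binary data.frame with `participant_id` and one
#'   `<metric>_class` column (values `"high"`/`"low"`) per metric named in
#'   `config$survival_betas`.
#' @param config a [simulation_config()].
#' @return data.frame `participant_id`, `time` (> 0), `event` (0/1).
#' @export
simulate_survival <- function(metrics_binary, config) {
  stopifnot(inherits(config, "simulation_config"),
            "participant_id" %in% names(metrics_binary))
  betas <- config$survival_betas
  n <- nrow(metrics_binary)
  log_hr <- numeric(n)
  for (m in names(betas)) {
    col <- paste0(m, "_class")
    if (!col %in% names(metrics_binary)) {
      stop("metrics_binary lacks column '", col, "' required by survival_betas")
    }
    cls <- as.character(metrics_binary[[col]])
    if (anyNA(cls)) stop("metrics_binary column '", col, "' has missing values")
    log_hr <- log_hr + betas[[m]] * (cls == "low")
  }
  with_seed(substream_seed(config$seed, .stage_key[["survival"]]), {
    event_time <- rexp(n, rate = config$baseline_hazard * exp(log_hr))
    censor_time <- if (config$censor_rate > 0) {
      rexp(n, rate = config$censor_rate)
    } else rep(Inf, n)
    data.frame(
      participant_id = metrics_binary$participant_id,
      time = pmin(event_time, censor_time),
      event = as.integer(event_time <= censor_time),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a molecular class label from binarized biomarkers
#'
#' Draws a two-level label (`"enriched"` vs `"other"`, emulating an
#' adaptive-enriched immune class) from a logistic model:
#' `logit P(enriched) = intercept + sum(log_odds_m * 1[metric m == "high"])`.
#'
#' @inheritParams simulate_survival
#' @return data.frame `participant_id`, `label`.
#' @export
simulate_labels <- function(metrics_binary, config) {
  stopifnot(inherits(config, "simulation_config"),
            "participant_id" %in% names(metrics_binary))
  lo <- config$label_log_odds
  n <- nrow(metrics_binary)
  eta <- rep(config$label_intercept, n)
  for (m in names(lo)) {
    col <- paste0(m, "_class")
    if (!col %in% names(metrics_binary)) {
      stop("metrics_binary lacks column '", col, "' required by label_log_odds")
    }
    eta <- eta + lo[[m]] * (as.character(metrics_binary[[col]]) == "high")
  }
  with_seed(substream_seed(config$seed, .stage_key[["labels"]]), {
    data.frame(
      participant_id = metrics_binary$participant_id,
      label = ifelse(rbinom(n, 1, plogis(eta)) == 1, "enriched", "other"),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete synthetic TMA cohort
#'
#' Generates every participant's cores with [simulate_core()], computes
#' the *true* spatial biomarkers from the known cell classes (via the same
#' nearest-neighbor machinery the analysis pipeline uses), binarizes them
#' at the analysis cutpoints (1st quartile for proximity, median for
#' consistency and lymphocyte count), and draws survival outcomes and
#' class labels from those true binarized metrics.
#'
#' @param config a [simulation_config()].
#' @param cap nearest-neighbor distance cap in microns for the truth
#'   metrics (default 1000, the core-size bound).
#' @return An object of class `"synthetic_cohort"`: list with `cells`
#'   (all cores, including `true_class`), `survival`, `labels`, and
#'   `truth` (per-participant true metrics with `*_class` binarizations,
#'   the cutpoints used, and the config).
#' @export
simulate_cohort <- function(config, cap = 1000) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- vector("list", config$n_participants * config$cores_per_participant)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    for (cc in seq_len(config$cores_per_participant)) {
      k <- k + 1L
      cells[[k]] <- simulate_core(config, p, cc)
    }
  }
  cells <- do.call(rbind, cells)

  truth <- true_metrics(cells, cap = cap)
  # degenerate metrics (e.g. no lymphocytes at all) simply carry no class
  for (m in c("proximity", "consistency", "count")) {
    vals <- if (m == "count") truth$lymphocyte_count else truth[[m]]
    rule <- if (m == "proximity") "q1" else "median"
    cls <- tryCatch(binarize(vals, rule = rule), error = function(e) NULL)
    if (!is.null(cls)) truth[[paste0(m, "_class")]] <- as.character(cls)
  }

  needed <- unique(c(names(config$survival_betas), names(config$label_log_odds)))
  missing_cols <- if (length(needed)) {
    setdiff(paste0(needed, "_class"), names(truth))
  } else character(0)
  if (length(missing_cols)) {
    stop("cannot binarize metric(s) ", paste(missing_cols, collapse = ", "),
         " (degenerate cohort); adjust the simulation config")
  }
  survival <- simulate_survival(truth, config)
  labels <- simulate_labels(truth, config)

  structure(list(cells = cells, survival = survival, labels = labels,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

# Per-participant metrics computed from the generator's true classes;
# shares nearest_neighbor_distances/pool/compute with the analysis path.
true_metrics <- function(cells, cap = 1000) {
  parts <- unique(cells$participant_id)
  out <- lapply(parts, function(p) {
    sub <- cells[cells$participant_id == p, , drop = FALSE]
    dists <- lapply(split(sub, sub$core_id), function(core) {
      nearest_neighbor_distances(
        tumor_xy = as.matrix(core[core$true_class == "tumor",
                                  c("x_um", "y_um")]),
        cd8_xy = as.matrix(core[core$true_class == "cd8",
                                c("x_um", "y_um")]),
        cap = cap)
    })
    sample <- pool_participant(dists, p)
    compute_metrics(sample,
                    lymphocyte_count = sum(sub$true_class %in% c("cd8", "treg")),
                    n_cores_passed = length(dists))
  })
  do.call(rbind, out)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic TMA cohort:", x$config$n_participants, "participants,",
      x$config$cores_per_participant, "cores each,",
      nrow(x$cells), "cells; infiltration mode:",
      x$config$infiltration_mode, "\n")
  invisible(x)
}
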