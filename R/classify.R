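#' Channel thresholds for the simple threshold classifier
#'
#' The classifier has no numeric defaults: thresholds are a per-staining-
#' batch calibration (conventionally chosen by inspecting the per-cell
#' mean channel intensities) and must be supplied. For synthetic
#' cohorts, [suggested_thresholds()] derives them from the simulation's
#' intensity parameters.
#'
#' @param t_ck,t_cd8,t_foxp3 finite nonnegative intensity thresholds, in
#'   the same arbitrary fluorescence units as the cell table.
#' @return list of class `"threshold_set"`.
#' @export
threshold_set <- function(t_ck, t_cd8, t_foxp3) {
  vals <- c(t_ck = t_ck, t_cd8 = t_cd8, t_foxp3 = t_foxp3)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("thresholds must be finite and nonnegative")
  }
  structure(as.list(vals), class = "threshold_set")
}

#' Classify cells from channel intensities
#'
#' Assigns each cell exactly one class by thresholding its mean channel
#' intensities ("exceeds" is implemented as `>=` throughout):
#' \describe{
#'   \item{treg}{CD8 and FoxP3 both at/above threshold (double positive).}
#'   \item{cd8}{CD8 at/above threshold, FoxP3 below.}
#'   \item{foxp3_only}{FoxP3 at/above threshold, CD8 below.}
#'   \item{tumor}{CK at/above threshold and no lymphocyte marker at
#'     threshold — a cell cannot be both tumor and lymphocyte, so
#'     lymphocyte assignment takes priority over CK.}
#'   \item{unclassified}{none of the above.}
#' }
#' Classification is a pure per-cell function of the intensities and
#' thresholds; no neighborhood information is used.
#'
#' @param cells data.frame with columns `intensity_ck`, `intensity_cd8`,
#'   `intensity_foxp3` (other columns pass through untouched).
#' @param thresholds a [threshold_set()].
#' @return `cells` with a `cell_class` column (factor with levels tumor,
#'   cd8, treg, foxp3_only, unclassified).
#' @export
#' @examples
#' cells <- data.frame(intensity_ck = c(5, 10, 0),
#'                     intensity_cd8 = c(10, 10, 0),
#'                     intensity_foxp3 = c(10, 0, 0))
#' classify_cells(cells, threshold_set(4, 4, 4))$cell_class
classify_cells <- function(cells, thresholds) {
  stopifnot(is.data.frame(cells), inherits(thresholds, "threshold_set"))
  needed <- c("intensity_ck", "intensity_cd8", "intensity_foxp3")
  miss <- setdiff(needed, names(cells))
  if (length(miss)) {
    stop("cell table lacks channel column(s): ", paste(miss, collapse = ", "))
  }
  for (col in needed) {
    bad <- which(!is.finite(cells[[col]]))
    if (length(bad)) {
      stop("missing or non-finite '", col, "' at row(s) ",
           paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
    if (any(cells[[col]] < 0)) stop("negative intensities in '", col, "'")
  }
  ck <- cells$intensity_ck >= thresholds$t_ck
  cd8 <- cells$intensity_cd8 >= thresholds$t_cd8
  fox <- cells$intensity_foxp3 >= thresholds$t_foxp3

  cls <- rep("unclassified", nrow(cells))
  cls[ck & !cd8 & !fox] <- "tumor"
  cls[cd8 & fox] <- "treg"
  cls[cd8 & !fox] <- "cd8"
  cls[!cd8 & fox] <- "foxp3_only"
  cells$cell_class <- factor(cls, levels = c("tumor", "cd8", "treg",
                                             "foxp3_only", "unclassified"))
  cells
}

#' Tally cell classes for a single TMA core
#'
#' @param cells classified rows all sharing one `(participant_id, core_id)`.
#' @return one-row data.frame: ids, per-class counts, `n_total`,
#'   `passed_qc` (NA until [qc_filter_cores()]).
#' @export
summarize_core <- function(cells) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) > 0 &&
      (length(unique(cells$core_id)) > 1 ||
       length(unique(cells$participant_id)) > 1)) {
    stop("summarize_core() expects cells from exactly one core; got ",
         length(unique(cells$core_id)), " core ids")
  }
  tab <- table(factor(cells$cell_class,
                      levels = c("tumor", "cd8", "treg", "foxp3_only",
                                 "unclassified")))
  data.frame(
    participant_id = if (nrow(cells)) cells$participant_id[1] else NA_character_,
    core_id = if (nrow(cells)) cells$core_id[1] else NA_character_,
    n_tumor = as.integer(tab[["tumor"]]),
    n_cd8 = as.integer(tab[["cd8"]]),
    n_treg = as.integer(tab[["treg"]]),
    n_foxp3_only = as.integer(tab[["foxp3_only"]]),
    n_unclassified = as.integer(tab[["unclassified"]]),
    n_total = nrow(cells),
    passed_qc = NA,
    stringsAsFactors = FALSE
  )
}

#' Tally cell classes for every core in a classified cell table
#'
#' @param cells classified cell table (any number of cores).
#' @return data.frame with one [summarize_core()] row per core.
#' @export
summarize_cores <- function(cells) {
  stopifnot(is.data.frame(cells), "cell_class" %in% names(cells))
  if (nrow(cells) == 0) return(summarize_core(cells)[0, ])
  out <- do.call(rbind, lapply(split(cells, cells$core_id), summarize_core))
  rownames(out) <- NULL
  out[order(out$participant_id, out$core_id), , drop = FALSE]
}

#' Flag TMA cores that fail quality control
#'
#' The source workflow removed any core with fewer than 1000 tumor cells
#' and fewer than 3000 total cells. Read literally this is a conjunction,
#' and `mode = "and"` (the default) removes a core only when *both*
#' counts are below their bounds; `mode = "or"` applies the stricter
#' reading, removing a core that fails *either* bound. Cores are flagged,
#' never dropped from the summary; downstream pooling uses `passed_qc`.
#'
#' @param summaries output of [summarize_cores()].
#' @param min_tumor,min_total nonnegative integer bounds.
#' @param mode `"and"` or `"or"` (see Details).
#' @return `summaries` with `passed_qc` set.
#' @export
qc_filter_cores <- function(summaries, min_tumor = 1000, min_total = 3000,
                            mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (min_tumor < 0 || min_total < 0) {
    stop("QC bounds must be nonnegative")
  }
  low_tumor <- summaries$n_tumor < min_tumor
  low_total <- summaries$n_total < min_total
  removed <- if (mode == "and") low_tumor & low_total else low_tumor | low_total
  summaries$passed_qc <- !removed
  attr(summaries, "qc") <- list(min_tumor = min_tumor, min_total = min_total,
                                mode = mode)
  summaries
}
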