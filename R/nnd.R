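#' Tumor-to-CD8 nearest-neighbor distances within one TMA core
#'
#' For each tumor cell, the Euclidean distance to the closest CD8 target
#' in the same core, truncated at `cap` (default 1000 microns, the
#' physical bound set by a 1 mm core). Distances are meaningful only
#' within a core — cores are physically distinct tissue — so this
#' function is always applied per core and never across cores.
#'
#' Cores with no CD8 target are handled by policy: `"assign-cap"` (the
#' default) gives every tumor cell the cap, so a participant whose cores
#' lack CD8 cells ends up with proximity near 0 rather than silently
#' vanishing from the analysis; `"drop-core"` excludes the core (returns
#' `NULL`).
#'
#' The computation is exact (vectorized all-pairs, chunked to bound
#' memory), not an approximate neighbor search.
#'
#' @param tumor_xy,cd8_xy two-column numeric matrices of micron
#'   coordinates (x, y) in a common frame.
#' @param cap truncation distance in microns (> 0).
#' @param no_cd8_policy `"assign-cap"` or `"drop-core"`.
#' @return numeric vector, one distance per tumor cell (attribute
#'   `n_capped` counts distances set to the cap), or `NULL` when a
#'   CD8-free core is dropped. An empty tumor set yields `numeric(0)`.
#' @export
#' @examples
#' nearest_neighbor_distances(cbind(0, 0), cbind(3, 4))  # 5
nearest_neighbor_distances <- function(tumor_xy, cd8_xy, cap = 1000,
                                       no_cd8_policy = c("assign-cap",
                                                         "drop-core")) {
  no_cd8_policy <- match.arg(no_cd8_policy)
  if (!is.finite(cap) || cap <= 0) stop("cap must be a positive length")
  tumor_xy <- as.matrix(tumor_xy)
  cd8_xy <- as.matrix(cd8_xy)
  n_t <- nrow(tumor_xy)
  if (n_t == 0) {
    return(structure(numeric(0), n_capped = 0L))
  }
  if (nrow(cd8_xy) == 0) {
    if (no_cd8_policy == "drop-core") return(NULL)
    return(structure(rep(cap, n_t), n_capped = n_t))
  }
  if (ncol(tumor_xy) != 2 || ncol(cd8_xy) != 2) {
    stop("coordinate matrices must have two columns (x, y)")
  }
  # chunk tumor cells so each cross-distance block stays < ~8 MB
  chunk <- max(1L, floor(1e6 / nrow(cd8_xy)))
  d <- numeric(n_t)
  cx <- cd8_xy[, 1]; cy <- cd8_xy[, 2]
  for (start in seq(1L, n_t, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_t)
    # direct coordinate differences: numerically identical to the naive
    # per-pair formula, unlike the inner-product expansion
    d2 <- outer(tumor_xy[idx, 1], cx, "-")^2 +
      outer(tumor_xy[idx, 2], cy, "-")^2
    d[idx] <- sqrt(apply(d2, 1L, min))
  }
  n_capped <- sum(d > cap)
  d[d > cap] <- cap
  structure(d, n_capped = as.integer(n_capped))
}

#' Pool log10 nearest-neighbor distances across a participant's cores
#'
#' The raw distances are highly right-skewed, so the analysis works on
#' base-10 logarithms. Pooling is a plain concatenation of each passed
#' core's log10 distances (not an average of per-core moments), so
#' participants with unequal core sizes are weighted by tumor-cell count.
#'
#' @param core_distances list of per-core distance vectors (microns), as
#'   returned by [nearest_neighbor_distances()]; `NULL` entries (dropped
#'   cores) are skipped.
#' @param participant_id identifier attached to the sample.
#' @return list of class `"nnd_sample"`: `participant_id`, `values`
#'   (log10 microns), `n_distances`, `capped_count`.
#' @export
pool_participant <- function(core_distances, participant_id) {
  if (!is.list(core_distances)) core_distances <- list(core_distances)
  core_distances <- Filter(Negate(is.null), core_distances)
  capped <- sum(vapply(core_distances,
                       function(d) as.integer(attr(d, "n_capped") %||% 0L),
                       integer(1)))
  values <- unlist(core_distances, use.names = FALSE)
  if (is.null(values)) values <- numeric(0)
  if (any(values <= 0)) {
    stop("nonpositive nearest-neighbor distance for participant ",
         participant_id,
         ": coincident tumor/CD8 centroids indicate a corrupt upstream table")
  }
  structure(list(participant_id = participant_id,
                 values = log10(values),
                 n_distances = length(values),
                 capped_count = capped),
            class = "nnd_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
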