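#' Voxel-wise Pearson correlation between two participants' series
#'
#' Correlates the two time series at every mask voxel. Voxels where either
#' series has zero variance get r = 0; their count is recorded in the
#' `n_zero_variance` attribute so downstream inference can flag voxels that
#' are degenerate in many pairs.
#'
#' @param a,b [masked_series()] (or plain voxels-by-time matrices) over the
#'   same voxel set and length >= 3.
#' @return numeric vector of correlations, one per voxel.
#' @export
pearson_map <- function(a, b) {
  ma <- if (inherits(a, "masked_series")) a$matrix else a
  mb <- if (inherits(b, "masked_series")) b$matrix else b
  if (inherits(a, "masked_series") && inherits(b, "masked_series") &&
      !identical(a$voxel_ids, b$voxel_ids))
    stop("series cover different voxel sets")
  if (!identical(dim(ma), dim(mb)))
    stop(sprintf("series dimensions differ: %s vs %s",
                 paste(dim(ma), collapse = "x"),
                 paste(dim(mb), collapse = "x")))
  if (ncol(ma) < 3) stop("need at least 3 time points")
  ca <- ma - rowMeans(ma)
  cb <- mb - rowMeans(mb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  r <- numeric(nrow(ma))
  ok <- den > 0
  r[ok] <- rowSums(ca * cb)[ok] / den[ok]
  attr(r, "n_zero_variance") <- sum(!ok)
  r
}

#' Fisher r-to-z transform
#'
#' z = atanh(r) after clamping |r| to 1 - 1e-7 so perfect correlations map to
#' a large finite value (about 8.41) instead of infinity.
#'
#' @param r correlations in [-1, 1] (values beyond 1 by more than 1e-8 are an
#'   error).
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' All unordered participant pairs
#' @param ids participant identifiers.
#' @return data.frame with columns `i`, `j` (ids, i before j) and `i_idx`,
#'   `j_idx` (positions), one row per unordered pair in lexicographic index
#'   order.
#' @export
participant_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2) stop("need at least 2 participants")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]],
             i_idx = idx[, 1], j_idx = idx[, 2], stringsAsFactors = FALSE)
}

new_pair_maps <- function(z, pairs, scope, voxel_ids, type,
                          baseline_subtracted = FALSE) {
  structure(list(z = z, pairs = pairs, scope = scope, voxel_ids = voxel_ids,
                 type = type, baseline_subtracted = baseline_subtracted),
            class = "pair_maps")
}

#' @export
print.pair_maps <- function(x, ...) {
  cat(sprintf("Pair maps: %d voxels x %d pairs x %d %ss%s\n",
              dim(x$z)[1], dim(x$z)[2], dim(x$z)[3], x$type,
              if (x$baseline_subtracted) " (baseline subtracted)" else ""))
  invisible(x)
}

#' Fisher-z ISC maps for all participant pairs and segments
#'
#' One voxel-wise Fisher-z correlation map per unordered participant pair per
#' stimulus segment. Maps are symmetric in the pair by construction.
#'
#' @param series_by_participant named list; per participant, a list of
#'   voxel-by-time matrices in the same segment order (as produced by
#'   [preprocess_cohort()]).
#' @param segments SegmentTable describing the shared segment order (columns
#'   stimulus_id, frame, topic).
#' @param voxel_ids canonical voxel indices of the matrix rows.
#' @return a `pair_maps` object: `z` is a voxels x pairs x segments array.
#' @export
all_pair_maps <- function(series_by_participant, segments, voxel_ids = NULL) {
  n <- length(series_by_participant)
  if (n < 2) stop("need at least 2 participants")
  ids <- names(series_by_participant)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(n))
  n_seg <- nrow(segments)
  for (nm in seq_len(n)) {
    if (length(series_by_participant[[nm]]) != n_seg)
      stop("participant ", ids[nm], " is missing segments: has ",
           length(series_by_participant[[nm]]), ", expected ", n_seg)
  }
  pairs <- participant_pairs(ids)
  v <- nrow(series_by_participant[[1]][[1]])
  z <- array(NA_real_, c(v, nrow(pairs), n_seg))
  for (s in seq_len(n_seg)) {
    centered <- lapply(series_by_participant, function(p) {
      m <- p[[s]]
      m - rowMeans(m)
    })
    ss <- lapply(centered, function(m) rowSums(m^2))
    for (k in seq_len(nrow(pairs))) {
      ci <- centered[[pairs$i_idx[k]]]
      cj <- centered[[pairs$j_idx[k]]]
      den <- sqrt(ss[[pairs$i_idx[k]]] * ss[[pairs$j_idx[k]]])
      r <- numeric(v)
      ok <- den > 0
      r[ok] <- rowSums(ci * cj)[ok] / den[ok]
      z[, k, s] <- fisher_z(r)
    }
  }
  scope <- segments[, c("stimulus_id", "frame", "topic"), drop = FALSE]
  new_pair_maps(z, pairs, scope, voxel_ids, type = "segment")
}

#' Average pair maps by condition
#'
#' Arithmetic mean of the Fisher-z maps within each frame (or frame-by-topic)
#' group, per pair.
#'
#' @param pm a segment-level `pair_maps` object.
#' @param grouping `"frame"` or `"frame_topic"`.
#' @return a condition-level `pair_maps` object; `scope` lists the conditions.
#' @export
average_by_condition <- function(pm, grouping = c("frame", "frame_topic")) {
  stopifnot(inherits(pm, "pair_maps"), pm$type == "segment")
  grouping <- match.arg(grouping)
  key <- if (grouping == "frame") pm$scope$frame else
    paste(pm$scope$frame, pm$scope$topic, sep = ":")
  groups <- unique(key)
  v <- dim(pm$z)[1]; p <- dim(pm$z)[2]
  z <- array(NA_real_, c(v, p, length(groups)))
  for (g in seq_along(groups)) {
    idx <- which(key == groups[g])
    if (length(idx) == 0) stop("empty condition group: ", groups[g])
    acc <- pm$z[, , idx[1]]
    for (s in idx[-1]) acc <- acc + pm$z[, , s]
    z[, , g] <- acc / length(idx)
  }
  scope <- if (grouping == "frame") {
    data.frame(condition = groups, frame = groups, stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(groups, ":", fixed = TRUE)
    data.frame(condition = groups,
               frame = vapply(parts, `[`, "", 1),
               topic = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  }
  new_pair_maps(z, pm$pairs, scope, pm$voxel_ids, type = "condition",
                baseline_subtracted = pm$baseline_subtracted)
}

#' Unmatched-segment baseline map for one participant pair
#'
#' Correlates participant i's segment A with participant j's segment B for
#' unmatched ordered segment combinations (A != B), truncating both series to
#' the shorter length, Fisher-z transforms and averages. The result estimates
#' stimulus-nonspecific correlation (scanner noise, shared drift) and is
#' subtracted from the stimulus-specific maps by [subtract_baseline()]. All
#' ordered combinations are used when there are at most `max_combinations`,
#' otherwise a seeded uniform subsample.
#'
#' @param series_i,series_j lists of voxel-by-time matrices, one per segment.
#' @param max_combinations cap on sampled combinations (default 200).
#' @param seed seed for the subsample.
#' @return numeric vector: mean Fisher-z baseline per voxel, with attribute
#'   `n_combinations`.
#' @export
baseline_map <- function(series_i, series_j, max_combinations = 200,
                         seed = 1) {
  s <- length(series_i)
  if (s < 2 || length(series_j) < 2)
    stop("need at least 2 segments per participant for an unmatched baseline")
  combos <- expand.grid(a = seq_len(s), b = seq_len(length(series_j)))
  combos <- combos[combos$a != combos$b, , drop = FALSE]
  if (nrow(combos) == 0) stop("no unmatched segment combinations")
  if (nrow(combos) > max_combinations) {
    set.seed(as.integer(seed))
    combos <- combos[sample.int(nrow(combos), max_combinations), ,
                     drop = FALSE]
  }
  acc <- 0
  for (k in seq_len(nrow(combos))) {
    x <- series_i[[combos$a[k]]]
    y <- series_j[[combos$b[k]]]
    len <- min(ncol(x), ncol(y))
    acc <- acc + fisher_z(pearson_map(x[, seq_len(len), drop = FALSE],
                                      y[, seq_len(len), drop = FALSE]))
  }
  out <- acc / nrow(combos)
  attr(out, "n_combinations") <- nrow(combos)
  out
}

#' Baseline maps for every participant pair
#'
#' @inheritParams baseline_map
#' @param series_by_participant named list as in [all_pair_maps()].
#' @return voxels x pairs matrix of mean baseline Fisher-z values; pair order
#'   matches [participant_pairs()].
#' @export
all_baseline_maps <- function(series_by_participant, max_combinations = 200,
                              seed = 1) {
  ids <- names(series_by_participant)
  pairs <- participant_pairs(ids)
  v <- nrow(series_by_participant[[1]][[1]])
  out <- matrix(NA_real_, v, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    out[, k] <- baseline_map(series_by_participant[[pairs$i_idx[k]]],
                             series_by_participant[[pairs$j_idx[k]]],
                             max_combinations = max_combinations,
                             seed = seed + k)
  }
  out
}

#' Subtract the unmatched-segment baseline from pair maps
#'
#' Element-wise subtraction of each pair's baseline map from its
#' stimulus-specific (or condition-averaged) Fisher-z maps. Refuses to
#' subtract twice.
#'
#' @param pm a `pair_maps` object.
#' @param baseline voxels x pairs matrix from [all_baseline_maps()].
#' @return the corrected `pair_maps` with `baseline_subtracted = TRUE`.
#' @export
subtract_baseline <- function(pm, baseline) {
  stopifnot(inherits(pm, "pair_maps"))
  if (pm$baseline_subtracted) stop("baseline already subtracted")
  if (!identical(dim(baseline), dim(pm$z)[1:2]))
    stop(sprintf("baseline is %s but maps are %d voxels x %d pairs",
                 paste(dim(baseline), collapse = "x"),
                 dim(pm$z)[1], dim(pm$z)[2]))
  z <- pm$z
  for (s in seq_len(dim(z)[3])) z[, , s] <- z[, , s] - baseline
  new_pair_maps(z, pm$pairs, pm$scope, pm$voxel_ids, pm$type,
                baseline_subtracted = TRUE)
}
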