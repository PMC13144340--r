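#' A participant's 4D BOLD run
#'
#' @param participant_id participant label.
#' @param data 4D numeric array (x, y, z, t) with t >= 2 and finite values.
#' @param tr_s repetition time in seconds, > 0.
#' @param provenance list of source path / processing flags.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(participant_id, data, tr_s, provenance = list()) {
  if (length(dim(data)) != 4)
    stop("data must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2) stop("run must have at least 2 volumes")
  if (!all(is.finite(data))) stop("run contains non-finite values")
  if (tr_s <= 0) stop("tr_s must be positive")
  structure(list(participant_id = as.character(participant_id),
                 data = data, tr_s = tr_s, provenance = provenance),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run %s: %dx%dx%d grid, %d volumes, TR %.2f s\n",
              x$participant_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Time series at mask voxels
#'
#' Rows are mask voxels in canonical order: ascending linear index with x
#' fastest, then y, then z (R's native array order), so maps vectorize
#' reproducibly.
#'
#' @param matrix voxels-by-time numeric matrix.
#' @param voxel_ids linear indices of the rows into the mask grid.
#' @return object of class `masked_series`.
#' @export
masked_series <- function(matrix, voxel_ids) {
  if (nrow(matrix) != length(voxel_ids))
    stop("row count must equal number of voxel ids")
  structure(list(matrix = matrix, voxel_ids = voxel_ids),
            class = "masked_series")
}

#' Extract mask voxel time series from a run
#'
#' @param run a [bold_run()].
#' @param mask 3D 0/1 array on the same grid as the run.
#' @return a [masked_series()] (voxels x time), values copied unchanged.
#' @export
apply_mask <- function(run, mask) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
    stop(sprintf("mask grid %s does not match run grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(d[1:3], collapse = "x")))
  ids <- which(mask != 0)
  if (length(ids) == 0) stop("mask is empty: no voxels to extract")
  m <- matrix(run$data, prod(d[1:3]), d[4])[ids, , drop = FALSE]
  masked_series(m, ids)
}

#' Regress nuisance signals out of a run
#'
#' Replaces every voxel time series by its residual from a least-squares
#' projection onto an intercept plus the supplied nuisance regressors; voxel
#' means are removed by the intercept. The operation is idempotent.
#'
#' @param run a [bold_run()].
#' @param nuisance time-by-k data.frame or matrix (e.g. six motion
#'   parameters), row count equal to the run length. May have zero columns,
#'   in which case only the intercept (voxel mean) is removed.
#' @return a [bold_run()] of residuals.
#' @export
regress_out_nuisance <- function(run, nuisance) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  nt <- d[4]
  x <- as.matrix(nuisance)
  if (ncol(x) > 0 && nrow(x) != nt)
    stop(sprintf("nuisance has %d rows but run has %d volumes", nrow(x), nt))
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("nuis", seq_len(ncol(x)))
  # identically-zero regressors carry no signal: drop them so the projection
  # falls back to the intercept instead of a spurious rank error
  keep <- apply(x, 2, function(col) any(col != 0))
  x <- x[, keep, drop = FALSE]
  cn <- cn[keep]
  design <- matrix(1, nt, 1)
  if (ncol(x) > 0) design <- cbind(design, x)
  colnames(design) <- c("(intercept)", cn)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    dep <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop("nuisance design is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  y <- t(matrix(run$data, prod(d[1:3]), nt))  # time x all voxels
  res <- qr.resid(qx, y)
  out <- array(t(res), dim = d)
  prov <- run$provenance
  prov$nuisance_regressed <- TRUE
  bold_run(run$participant_id, out, run$tr_s, prov)
}

#' Polynomial detrending columns
#'
#' Orthogonal polynomial basis (degree 1..order) over the run, for appending
#' to nuisance regressors to remove slow scanner drift.
#' @param n_volumes run length.
#' @param order polynomial order (0 returns a zero-column matrix).
#' @return n_volumes x order matrix.
#' @export
detrend_basis <- function(n_volumes, order = 2) {
  if (order < 1) return(matrix(numeric(0), n_volumes, 0))
  b <- poly(seq_len(n_volumes), degree = order)
  colnames(b) <- paste0("poly", seq_len(order))
  unclass(b)
}

#' Cut a run into analysis-ready stimulus segments
#'
#' Volume indices are 0-based; a volume belongs to a segment if its
#' acquisition onset lies in `[onset, onset + duration)`. The first
#' `n_exclude_volumes` volumes of each segment are dropped to skip the initial
#' hemodynamic transient (8 volumes = 12 s at TR 1.5 s), so
#' `first_volume = floor(onset / tr) + n_exclude_volumes` and
#' `last_volume = floor((onset + duration) / tr) - 1`.
#'
#' @param run a [bold_run()].
#' @param events data.frame with columns onset, duration, stimulus_id, frame,
#'   topic (seconds).
#' @param mask 3D 0/1 array on the run grid.
#' @param n_exclude_volumes transient volumes to drop per segment (default 8).
#' @param min_volumes minimum retained volumes per segment (default 10);
#'   shorter segments are an error.
#' @return list with `table` (SegmentTable: stimulus_id, frame, topic,
#'   onset_s, duration_s, first_volume, last_volume, rows in stable
#'   (stimulus_id, frame) order) and `series` (list of [masked_series()], one
#'   per table row).
#' @export
extract_segments <- function(run, events, mask, n_exclude_volumes = 8,
                             min_volumes = 10) {
  stopifnot(inherits(run, "bold_run"))
  need <- c("onset", "duration", "stimulus_id", "frame", "topic")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  nt <- dim(run$data)[4]
  tr <- run$tr_s
  if (any(events$onset + events$duration > nt * tr + 1e-9))
    stop("event extends beyond run duration")

  first <- floor(events$onset / tr) + n_exclude_volumes
  last <- floor((events$onset + events$duration) / tr) - 1
  tab <- data.frame(stimulus_id = events$stimulus_id, frame = events$frame,
                    topic = events$topic, onset_s = events$onset,
                    duration_s = events$duration,
                    first_volume = as.integer(first),
                    last_volume = as.integer(last),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$stimulus_id, tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  short <- tab$last_volume - tab$first_volume + 1 < min_volumes
  if (any(short))
    stop("segments shorter than ", min_volumes, " volumes after exclusion: ",
         paste(sprintf("%s/%s", tab$stimulus_id[short], tab$frame[short]),
               collapse = ", "))

  ms <- apply_mask(run, mask)
  series <- lapply(seq_len(nrow(tab)), function(s) {
    cols <- (tab$first_volume[s]:tab$last_volume[s]) + 1L  # 0-based -> R index
    masked_series(ms$matrix[, cols, drop = FALSE], ms$voxel_ids)
  })
  list(table = tab, series = series)
}

#' Preprocess a whole cohort
#'
#' Per participant: regress out the motion regressors plus polynomial
#' detrending columns, then cut the run into masked stimulus segments.
#'
#' @param cohort an `isc_cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param n_exclude_volumes transient volumes to drop per segment.
#' @param detrend polynomial detrend order appended to the nuisance columns
#'   (0 disables).
#' @return list with `series_by_participant` (named list; per participant a
#'   list of voxel-by-time matrices, one per segment row), `segments` (the
#'   shared SegmentTable), `mask`, `voxel_ids`.
#' @export
preprocess_cohort <- function(cohort, n_exclude_volumes = 8, detrend = 2) {
  stopifnot(inherits(cohort, "isc_cohort"))
  out <- vector("list", length(cohort$runs))
  names(out) <- names(cohort$runs)
  tab <- NULL
  ids <- NULL
  for (nm in names(cohort$runs)) {
    run <- cohort$runs[[nm]]
    nuis <- as.matrix(cohort$nuisance[[nm]])
    if (detrend >= 1)
      nuis <- cbind(nuis, detrend_basis(dim(run$data)[4], detrend))
    run <- regress_out_nuisance(run, nuis)
    ex <- extract_segments(run, cohort$events, cohort$mask,
                           n_exclude_volumes = n_exclude_volumes)
    if (is.null(tab)) {
      tab <- ex$table
      ids <- ex$series[[1]]$voxel_ids
    }
    out[[nm]] <- lapply(ex$series, function(s) s$matrix)
  }
  list(series_by_participant = out, segments = tab, mask = cohort$mask,
       voxel_ids = ids)
}

# ---- dataset directory I/O -------------------------------------------------

# write a table with doubles at full precision so datasets round-trip exactly
write_table_exact <- function(df, file, sep) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
}

nifti_from_array <- function(arr, voxel_size_mm, tr_s = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (is.null(tr_s)) rep(voxel_size_mm, 3) else
    c(rep(voxel_size_mm, 3), tr_s)
  RNifti::pixdim(img) <- pd
  img
}

#' Write a cohort to a dataset directory
#'
#' Layout: `sub-XX_bold.nii` 4D runs, `mask.nii`, `events.tsv` (onset,
#' duration, stimulus_id, frame, topic), `sub-XX_nuisance.tsv` (6 columns),
#' `covariates.csv`, `truth.json` (ground truth without the latent streams),
#' and `manifest.json` with per-file MD5 hashes.
#'
#' @param cohort an `isc_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "isc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- cohort$config$voxel_size_mm
  files <- character(0)
  for (nm in names(cohort$runs)) {
    f <- file.path(dir, paste0(nm, "_bold.nii"))
    RNifti::writeNifti(nifti_from_array(cohort$runs[[nm]]$data, vox,
                                        cohort$runs[[nm]]$tr_s), f,
                       datatype = "double")
    files <- c(files, f)
    g <- file.path(dir, paste0(nm, "_nuisance.tsv"))
    write_table_exact(cohort$nuisance[[nm]], g, sep = "\t")
    files <- c(files, g)
  }
  f <- file.path(dir, "mask.nii")
  RNifti::writeNifti(nifti_from_array(cohort$mask, vox), f)
  files <- c(files, f)
  f <- file.path(dir, "events.tsv")
  write_table_exact(cohort$events, f, sep = "\t")
  files <- c(files, f)
  f <- file.path(dir, "covariates.csv")
  write_table_exact(cohort$covariates, f, sep = ",")
  files <- c(files, f)
  truth <- cohort$truth
  truth$latent_streams <- NULL
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  manifest <- list(
    package = "iscpipe",
    tr_s = cohort$config$tr_s,
    voxel_size_mm = vox,
    participants = names(cohort$runs),
    seed = cohort$config$seed,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from a dataset directory
#'
#' Inverse of [write_cohort()]; the round trip preserves arrays, TR and
#' voxel size.
#'
#' @param dir dataset directory containing a `manifest.json`.
#' @return an `isc_cohort` (with `truth` if `truth.json` is present; `config`
#'   is a minimal stub carrying grid, TR and voxel size).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  participants <- manifest$participants
  runs <- list()
  nuisance <- list()
  for (nm in participants) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, "_bold.nii")))
    tr <- RNifti::pixdim(img)[4]
    runs[[nm]] <- bold_run(nm, unclass(img)[, , , , drop = FALSE], tr,
                           provenance = list(source = dir))
    nuisance[[nm]] <- read.table(file.path(dir, paste0(nm, "_nuisance.tsv")),
                                 header = TRUE, sep = "\t")
  }
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii"))
  mask <- array(as.integer(unclass(mask_img) != 0), dim = dim(mask_img))
  events <- read.table(file.path(dir, "events.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  covariates <- read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  cfg <- list(grid_dims = dim(mask), tr_s = manifest$tr_s,
              voxel_size_mm = manifest$voxel_size_mm, seed = manifest$seed)
  structure(list(runs = runs, events = events, nuisance = nuisance,
                 covariates = covariates, mask = mask, truth = truth,
                 config = cfg),
            class = "isc_cohort")
}
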