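#' TFCE parameters
#'
#' Defaults follow the standard settings of the method: extent exponent
#' E = 0.5, height exponent H = 2, threshold step dh = max(|stat|)/100 (when
#' `dh = NULL`), 6-connectivity.
#'
#' @param E extent exponent, >= 0.
#' @param H height exponent, >= 0.
#' @param dh threshold step (> 0), or `NULL` to use max(|stat|)/100 per map.
#' @param connectivity 6, 18 or 26.
#' @return object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 6) {
  if (E < 0 || H < 0) stop("E and H must be >= 0")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel p, integrates cluster extent and height over all thresholds:
#' \deqn{TFCE(p) = \sum_{h = dh, 2dh, \dots \le v(p)} e_h(p)^E \, h^H \, dh}
#' where \eqn{e_h(p)} is the voxel count of the connected component containing
#' p at threshold h. Negative values are enhanced on the negated map and
#' re-signed.
#'
#' @param stat 3D statistic array (same grid as `mask`), or a numeric vector
#'   of values at the mask voxels in canonical order.
#' @param mask 3D 0/1 array.
#' @param params a [tfce_params()].
#' @return Enhanced map in the same shape as `stat` (3D array in, 3D array
#'   out; vector in, vector out).
#' @export
tfce <- function(stat, mask, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  voxel_ids <- which(mask != 0)
  if (length(voxel_ids) == 0) stop("mask is empty")
  as_array <- !is.null(dim(stat))
  vals <- if (as_array) {
    if (!identical(dim(stat), dim(mask)))
      stop("stat and mask grids differ")
    stat[voxel_ids]
  } else {
    if (length(stat) != length(voxel_ids))
      stop("stat length does not match mask voxel count")
    as.numeric(stat)
  }
  if (!all(is.finite(vals))) stop("statistic map contains non-finite values")
  out <- tfce_values(vals, dim(mask), voxel_ids, params)
  if (as_array) {
    res <- array(0, dim = dim(mask))
    res[voxel_ids] <- out
    res
  } else out
}

# core on masked values; dh resolved here (max|stat|/100 when NULL)
tfce_values <- function(vals, dims, voxel_ids, params) {
  vmax <- max(abs(vals))
  if (vmax == 0) return(numeric(length(vals)))
  dh <- if (is.null(params$dh)) vmax / 100 else params$dh
  tfce_cpp(vals, as.integer(voxel_ids - 1L), as.integer(dims),
           params$E, params$H, dh, params$connectivity)
}
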