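#' CT volume container
#'
#' A calibrated 3D image: an array of X-ray attenuation intensities in the
#' unsigned 16-bit range together with its voxel spacing and physical origin.
#' Arrays use R's native layout, `dim = c(nx, ny, nz)` with x varying
#' fastest (one z-slice per matrix plane, matching slice-stack acquisition);
#' the physical coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric 3D array of intensities in `[0, 65535]`.
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm/voxel.
#' @param origin numeric length-3 physical position of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume` with elements `data`, `spacing`
#'   and `origin`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 2)), spacing = c(0.3, 0.3, 0.3))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three extents must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm/voxel)")
  rng <- range(data, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("intensities must lie in [0, 65535]")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Label volume container
#'
#' Integer per-voxel grain labels on the same grid as a [ct_volume()]:
#' 0 is background, `k > 0` is grain `k`. Labels are kept compact
#' (`{0} U {1..K}`).
#'
#' @param labels integer 3D array of non-negative labels.
#' @inheritParams ct_volume
#' @param compact if `TRUE` (default) relabel to close gaps in the label set.
#' @return An object of class `label_volume` with elements `labels`,
#'   `spacing` and `origin`.
#' @export
label_volume <- function(labels, spacing = c(0.3, 0.3, 0.3),
                         origin = c(0, 0, 0), compact = TRUE) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  if (compact) labels <- compact_labels(labels)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm/voxel)")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_volume")
}

# close gaps so the label set is {0} U {1..K}, preserving numeric order
compact_labels <- function(labels) {
  present <- sort(unique(as.integer(labels)))
  present <- present[present > 0L]
  if (length(present) == 0L || identical(present, seq_along(present)))
    return(labels)
  map <- integer(max(present))
  map[present] <- seq_along(present)
  out <- labels
  nz <- labels > 0L
  out[nz] <- map[labels[nz]]
  out
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d grains\n",
              d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' Number of segmented grains
#'
#' @param labels a [label_volume()] (or a plain integer array of compact
#'   labels).
#' @return Integer count `K`, the largest label.
#' @export
count_grains <- function(labels) {
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  as.integer(max(0L, arr))
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: arrays are not on the same grid")
  invisible(TRUE)
}
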