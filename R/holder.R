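#' Coarse binarization of a CT volume
#'
#' First step of holder clearance: a global binary image with foreground =
#' intensities strictly above a threshold chosen by Otsu's method over the
#' full-volume histogram (or supplied directly).
#'
#' @param volume a [ct_volume()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold used when `method = "fixed"`.
#' @return Logical 3D array (foreground mask).
#' @export
coarse_binarize <- function(volume, method = c("otsu", "fixed"),
                            fixed_threshold = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed method needs `fixed_threshold`")
    fixed_threshold
  } else {
    otsu_threshold(intensity_histogram(volume))
  }
  volume$data > thr
}

#' Detect inner edges of a 2D slice mask
#'
#' Finds the boundaries of background holes enclosed by foreground — the
#' inner edges — ignoring the outer silhouette. Holes are background
#' components (4-connectivity) that do not touch the slice border; each
#' hole's contour is the set of foreground pixels 8-adjacent to it (standard
#' foreground-8 / hole-4 duality).
#'
#' @param slice_mask logical matrix.
#' @return A list of contours, each a list with `pixels` (two-column matrix
#'   of contour pixel coordinates), `area` (enclosed hole area in pixels)
#'   and `interior` (linear indices of the hole pixels). Empty list when the
#'   slice has no holes.
#' @export
detect_inner_edges <- function(slice_mask) {
  stopifnot(is.logical(slice_mask), length(dim(slice_mask)) == 2L)
  nx <- nrow(slice_mask); ny <- ncol(slice_mask)
  holes <- array(cpp_label3d(!slice_mask, nx, ny, 1L, 6L), dim = c(nx, ny))
  if (max(holes) == 0L) return(list())
  border_labels <- unique(c(holes[1, ], holes[nx, ], holes[, 1], holes[, ny]))
  ids <- setdiff(sort(unique(as.integer(holes))), c(0L, border_labels))
  lapply(ids, function(id) {
    hole <- holes == id
    contour <- dilate_2d_8(hole) & slice_mask
    list(pixels = which(contour, arr.ind = TRUE),
         area = sum(hole),
         interior = which(hole))
  })
}

# one-pixel 8-neighborhood dilation of a 2D mask
dilate_2d_8 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xt <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yt <- max(1, 1 - dy):min(ny, ny - dy)
    out[xt, yt] <- out[xt, yt] | m[xs, ys]
  }
  out
}

#' Select the holder edge among detected inner contours
#'
#' The holder interior dominates the field of view, so the holder edge is
#' the largest inner contour whose enclosed area reaches `min_size`;
#' `NULL` when no contour qualifies (the slice is treated as holder-free).
#'
#' @param contours list from [detect_inner_edges()].
#' @param min_size minimum enclosed area in pixels.
#' @return One contour, or `NULL`.
#' @export
select_holder_edge <- function(contours, min_size) {
  if (length(contours) == 0L) return(NULL)
  areas <- vapply(contours, function(ct) ct$area, numeric(1))
  ok <- which(areas >= min_size)
  if (length(ok) == 0L) return(NULL)
  contours[[ok[which.max(areas[ok])]]]
}

# fill 2D holes of `m`: union of m with background components not reaching
# the border (used to close grains sitting inside the selected hole)
fill_holes_2d <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  lab <- array(cpp_label3d(!m, nx, ny, 1L, 6L), dim = c(nx, ny))
  border_labels <- setdiff(unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny])),
                           0L)
  m | (lab > 0L & !(lab %in% border_labels))
}

#' Build the keep-mask of the holder interior
#'
#' Fills the selected inner contour of each slice (2D flood fill, enclosing
#' grains inside the holder), bridges slices where edge detection failed
#' with a 3D morphological closing (Euclidean ball of `closing_radius`
#' voxels), and keeps entirely any slice outside the detected holder range,
#' where the panicle may poke above the holder. The result is `TRUE` on
#' voxels to keep.
#'
#' @param volume a [ct_volume()] (grid reference).
#' @param per_slice_edges list over z of the selected contour (or `NULL`),
#'   as built by [clear_holder()] from [select_holder_edge()].
#' @param closing_radius radius of the closing ball in voxels.
#' @return Logical 3D array.
#' @export
build_holder_mask <- function(volume, per_slice_edges, closing_radius = 3) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  has_edge <- !vapply(per_slice_edges, is.null, logical(1))
  if (!any(has_edge)) stop("holder not found in any slice")
  zmin <- which(has_edge)[1]
  zmax <- rev(which(has_edge))[1]
  keep <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    if (z < zmin || z > zmax) {
      keep[, , z] <- TRUE
    } else if (has_edge[z]) {
      hole <- array(FALSE, dim = d[1:2])
      hole[per_slice_edges[[z]]$interior] <- TRUE
      keep[, , z] <- fill_holes_2d(hole)
    } # gaps are bridged by the closing below
  }
  if (closing_radius > 0) {
    inside <- keep
    inside[, , seq_len(d[3]) < zmin | seq_len(d[3]) > zmax] <- FALSE
    closed <- morph_close_3d(inside, closing_radius)
    keep <- keep | closed
  }
  keep
}

# 3D morphological closing with a Euclidean ball, via two distance
# transforms (dilation = within r of mask; erosion = deeper than r).
morph_close_3d <- function(mask, radius) {
  d <- dim(mask)
  d2 <- cpp_euclidean_dt_sq(!mask, d[1], d[2], d[3])
  dil <- mask | (array(d2, dim = d) <= radius^2)
  e2 <- cpp_euclidean_dt_sq(dil, d[1], d[2], d[3])
  array(e2, dim = d) > radius^2
}

#' Apply a keep-mask to a volume
#'
#' Voxels outside the mask are set to 0; voxels inside are untouched.
#'
#' @param volume a [ct_volume()].
#' @param mask logical array of the same shape (`TRUE` = keep).
#' @return A [ct_volume()].
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"))
  stopifnot_same_grid(volume$data, mask)
  out <- volume$data
  out[!mask] <- 0
  ct_volume(out, spacing = volume$spacing, origin = volume$origin)
}

#' Remove the scanning holder from a volume
#'
#' The six-step inner-edge method: (1) coarse global binarization, (2)
#' per-slice inner-edge detection, (3) size-based selection of the holder
#' edge, (4) 2D filling of the holder interior, (5) 3D morphological
#' closing, (6) masking. Because the method is geometric it succeeds even
#' when the holder's gray-level histogram completely overlaps the grains',
#' where any fixed grayscale threshold fails.
#'
#' @param volume a [ct_volume()].
#' @param min_size_frac minimum enclosed contour area as a fraction of the
#'   slice area (default 0.25: the holder interior dominates the field of
#'   view).
#' @param closing_radius closing ball radius in voxels.
#' @param binarize_method,fixed_threshold passed to [coarse_binarize()].
#' @return A list with `volume` (holder-cleared [ct_volume()]), `keep_mask`
#'   (logical array) and `n_slices_with_edge`.
#' @export
clear_holder <- function(volume, min_size_frac = 0.25, closing_radius = 3,
                         binarize_method = "otsu", fixed_threshold = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  bin <- coarse_binarize(volume, method = binarize_method,
                         fixed_threshold = fixed_threshold)
  d <- dim(bin)
  min_size <- min_size_frac * d[1] * d[2]
  edges <- lapply(seq_len(d[3]), function(z)
    select_holder_edge(detect_inner_edges(bin[, , z]), min_size))
  keep <- build_holder_mask(volume, edges, closing_radius)
  list(volume = apply_mask(volume, keep),
       keep_mask = keep,
       n_slices_with_edge = sum(!vapply(edges, is.null, logical(1))))
}
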