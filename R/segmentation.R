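#' Otsu's threshold from a 65,536-bin histogram
#'
#' Returns the intensity `t` maximizing the between-class variance
#' `w0(t) * w1(t) * (mu0(t) - mu1(t))^2` of the split into intensities
#' `<= t` (background) and `> t` (foreground). Ties are broken toward the
#' lowest threshold, so the result is identical to an exhaustive scan over
#' all candidate thresholds.
#'
#' @param counts numeric vector of bin counts; bin `i` counts intensity
#'   `i - 1` (length 65,536 for 16-bit data, but any length >= 2 works).
#' @return The threshold intensity (foreground is strictly above it).
#' @export
otsu_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: fewer than two occupied bins")
  n <- length(counts)
  total <- sum(counts)
  levels <- seq_len(n) - 1
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * levels)
  mu_t <- s0[n] / total
  # candidates t = levels[1..n-1]; both classes must be non-empty
  w0c <- w0[-n]
  s0c <- s0[-n]
  valid <- w0c > 0 & w0c < total
  mu0 <- s0c / w0c
  mu1 <- (s0[n] - s0c) / (total - w0c)
  sigma_b <- (w0c / total) * (1 - w0c / total) * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  levels[which.max(sigma_b)]
}

#' Intensity histogram of a volume
#'
#' @param volume a [ct_volume()] (or numeric array).
#' @param exclude_zero drop exactly-zero voxels (those masked out by holder
#'   clearance) before counting.
#' @return Numeric vector of 65,536 bin counts (bin `i` = intensity `i-1`;
#'   non-integer intensities are floored).
#' @export
intensity_histogram <- function(volume, exclude_zero = FALSE) {
  v <- if (inherits(volume, "ct_volume")) volume$data else volume
  v <- as.vector(v)
  if (exclude_zero) v <- v[v != 0]
  b <- floor(v)
  b[b < 0] <- 0
  b[b > 65535] <- 65535
  tabulate(as.integer(b) + 1L, nbins = 65536L)
}

#' Segment grain foreground by Otsu thresholding
#'
#' Applies [otsu_threshold()] to the holder-cleared volume's histogram
#' (excluding masked-out zero voxels by default, so the cleared region does
#' not distort the bimodal grain/background histogram) and returns the
#' strict-above mask.
#'
#' @param volume a [ct_volume()].
#' @param exclude_zero see [intensity_histogram()].
#' @return Logical 3D array. The chosen threshold is attached as attribute
#'   `"threshold"`.
#' @export
segment_foreground <- function(volume, exclude_zero = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  thr <- otsu_threshold(intensity_histogram(volume, exclude_zero))
  structure(volume$data > thr, threshold = thr)
}

#' Distance transform of a binary mask
#'
#' Per-voxel distance (in voxels) to the nearest background voxel.
#' `"chessboard"` is the Chebyshev (L-infinity) lattice metric computed with
#' an exact two-pass chamfer; `"euclidean"` is the exact Euclidean
#' transform.
#'
#' @param mask logical 3D array.
#' @param metric `"chessboard"` (default) or `"euclidean"`.
#' @return Numeric 3D array of distances (0 exactly on background), with
#'   attribute `"metric"`.
#' @export
distance_transform <- function(mask, metric = c("chessboard", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  out <- if (metric == "chessboard") {
    cpp_chessboard_dt(mask, d[1], d[2], d[3])
  } else {
    sqrt(cpp_euclidean_dt_sq(mask, d[1], d[2], d[3]))
  }
  structure(array(out, dim = d), metric = metric)
}

#' Watershed markers from merged distance-map maxima
#'
#' Detects the regional maxima of the distance map (connected equal-value
#' plateaus with no strictly higher neighbor) and merges maxima regions
#' that belong to the same grain, by transitive closure of two criteria:
#'
#' * **proximity** — the minimum lattice distance between the two regions
#'   (under the map's own metric) is below `merge_threshold`. Maxima within
#'   one grain sit closer together than the grain's radius, whereas the
#'   maxima of two distinct touching grains are a grain diameter apart, so
#'   the threshold is naturally "related to the radius of the object";
#' * **ridge connectivity** — the two regions are connected inside the
#'   thresholded set `dist >= max(peak_a, peak_b) - 1`. A noise dip on the
#'   core ridge of a single grain never cuts more than one quantization
#'   level below the peaks, while the neck between two touching grains
#'   does, so this criterion removes spurious in-grain splits without
#'   bridging a genuine contact. It is only applied at levels >= 2: for
#'   the flattest objects (peak distance 2) level 1 would be the whole
#'   component and the criterion carries no information.
#'
#' Merging is confined to each connected foreground component, so maxima
#' of disjoint grains are never fused however small their gap. With
#' `merge_threshold = 0` the markers are the raw regional maxima (no
#' merging of either kind — the classic over-segmenting baseline); with
#' `merge_threshold = NULL` each component uses its own radius estimate
#' (its peak distance value plus half a voxel for the integer-distance
#' truncation) as the proximity scale.
#'
#' @param dist distance map from [distance_transform()].
#' @param merge_threshold merge distance in voxels (>= 0), or `NULL` for
#'   the per-component automatic radius scale.
#' @return Integer 3D array of marker labels (0 outside markers).
#' @export
merged_maxima <- function(dist, merge_threshold = 0) {
  d <- dim(dist)
  mx <- cpp_regional_maxima(as.numeric(dist), d[1], d[2], d[3])
  K <- max(mx)
  if (K == 0L || identical(merge_threshold, 0)) return(array(mx, dim = d))
  comp <- cpp_label3d(dist > 0, d[1], d[2], d[3], 26L)
  ncomp <- max(comp)
  thr_by_comp <- if (is.null(merge_threshold)) {
    peaks_c <- vapply(split(as.numeric(dist)[comp > 0L], comp[comp > 0L]),
                      max, numeric(1))
    as.numeric(peaks_c)[order(as.integer(names(peaks_c)))] + 0.5
  } else {
    stopifnot(merge_threshold >= 0)
    rep(as.numeric(merge_threshold), ncomp)
  }
  metric_code <- if (identical(attr(dist, "metric"), "euclidean")) 1L else 0L
  map <- cpp_merge_regions(mx, comp, d[1], d[2], d[3], thr_by_comp,
                           metric_code)
  # ridge-connectivity merging on top of the proximity groups
  nz_idx <- which(mx > 0L)
  first_idx <- nz_idx[!duplicated(mx[nz_idx])]
  first_idx <- first_idx[order(mx[first_idx])]      # representative voxel
  peaks <- vapply(split(as.numeric(dist)[nz_idx], mx[nz_idx]), max,
                  numeric(1))
  peaks <- as.numeric(peaks)[order(as.integer(names(peaks)))]
  rcomp <- comp[first_idx]
  groups <- map                                      # group id per region
  for (L in setdiff(sort(unique(peaks - 1)), c(0, 1))) {
    labL <- cpp_label3d(dist >= L, d[1], d[2], d[3], 26L)
    conn <- labL[first_idx]
    for (cid in unique(rcomp)) {
      rs <- which(rcomp == cid)
      if (length(rs) < 2L) next
      for (a in rs) for (b in rs) {
        if (a >= b) next
        if (max(peaks[a], peaks[b]) - 1 != L) next
        if (conn[a] != 0L && conn[a] == conn[b] && groups[a] != groups[b])
          groups[groups == groups[b]] <- groups[a]
      }
    }
  }
  groups <- match(groups, unique(groups))
  out <- array(0L, dim = d)
  nz <- mx > 0L
  out[nz] <- groups[mx[nz]]
  out
}

#' Split a foreground mask into grains by marker-based watershed
#'
#' Priority flooding of the negated distance map restricted to the mask:
#' voxels are claimed by the nearest marker in decreasing-distance order, so
#' dividing surfaces appear only between distinct markers. Every mask voxel
#' connected to a marker receives exactly one label.
#'
#' @param mask logical 3D array.
#' @param markers integer marker array from [merged_maxima()].
#' @param dist distance map from [distance_transform()].
#' @param connectivity flooding connectivity (6, 18 or 26).
#' @return Integer 3D array of labels. With an empty marker set the whole
#'   mask becomes a single grain, with a warning.
#' @export
watershed_split <- function(mask, markers, dist, connectivity = 26) {
  stopifnot_same_grid(mask, markers)
  stopifnot_same_grid(mask, dist)
  d <- dim(mask)
  if (max(markers) == 0L) {
    warning("empty marker set: treating the whole mask as one grain")
    return(array(as.integer(mask), dim = d))
  }
  array(cpp_watershed(as.integer(markers), mask, as.numeric(dist),
                      d[1], d[2], d[3], as.integer(connectivity)),
        dim = d)
}

#' Label connected components and filter small objects
#'
#' For a logical mask, labels connected components at the given
#' connectivity; for an already-labeled array, keeps the labeling. Objects
#' smaller than `min_volume` voxels (dust, branch fragments) are removed and
#' the labels compacted to `1..K`.
#'
#' @param x logical mask or integer label array.
#' @param connectivity 6, 18 or 26 (grains are compact bright blobs; 26 is
#'   the default).
#' @param min_volume minimum object size in voxels; `NULL` (default) uses
#'   25% of the median object volume with an absolute floor of 10 voxels,
#'   recomputed per panicle so no hand-tuned constant is needed.
#' @return Integer 3D array of compact labels.
#' @export
label_and_filter <- function(x, connectivity = 26, min_volume = NULL) {
  d <- dim(x)
  lab <- if (is.logical(x)) {
    array(cpp_label3d(x, d[1], d[2], d[3], as.integer(connectivity)), dim = d)
  } else {
    array(as.integer(x), dim = d)
  }
  K <- max(lab)
  if (K == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  if (is.null(min_volume))
    min_volume <- max(10, 0.25 * stats::median(sizes[sizes > 0]))
  drop <- which(sizes < min_volume)
  if (length(drop) > 0L) lab[lab %in% drop] <- 0L
  compact_labels(lab)
}

#' Full grain segmentation of a holder-cleared volume
#'
#' Otsu foreground segmentation, distance transform, marker extraction with
#' radius-scale merging, watershed splitting of touching grains, and size
#' filtering, returning a [label_volume()].
#'
#' @param volume holder-cleared [ct_volume()].
#' @param metric distance metric, see [distance_transform()].
#' @param merge_threshold marker merge distance in voxels; `NULL` (default)
#'   merges at each component's own minor-radius scale: the maximum
#'   distance value inside a connected component approximates that
#'   component's minor radius, and half a voxel is added because the
#'   integer chessboard distance truncates the true radius.
#' @param connectivity labeling/flooding connectivity.
#' @param min_volume small-object threshold, see [label_and_filter()].
#' @param exclude_zero see [segment_foreground()].
#' @return A [label_volume()] with attributes `"threshold"` (Otsu),
#'   `"merge_threshold"` and `"n_markers"`.
#' @export
segment_grains <- function(volume, metric = "chessboard",
                           merge_threshold = NULL, connectivity = 26,
                           min_volume = NULL, exclude_zero = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  mask <- segment_foreground(volume, exclude_zero)
  thr <- attr(mask, "threshold")
  dist <- distance_transform(mask, metric)
  markers <- merged_maxima(dist, merge_threshold)
  lab <- suppressWarnings(watershed_split(mask, markers, dist, connectivity))
  lab <- label_and_filter(lab, connectivity, min_volume)
  out <- label_volume(lab, spacing = volume$spacing, origin = volume$origin,
                      compact = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "merge_threshold") <- merge_threshold %||%
    estimate_minor_radius(mask, dist, connectivity)
  attr(out, "n_markers") <- max(markers)
  out
}

# median over connected components of the maximum distance value — an
# estimate of the typical grain minor radius in voxels — plus half a voxel
# for the truncation of integer lattice distances. Dust components with
# radius < 2 voxels are ignored.
estimate_minor_radius <- function(mask, dist, connectivity = 26) {
  d <- dim(mask)
  lab <- cpp_label3d(mask, d[1], d[2], d[3], as.integer(connectivity))
  K <- max(lab)
  if (K == 0L) return(0)
  peak <- vapply(split(as.numeric(dist)[lab > 0L], lab[lab > 0L]), max,
                 numeric(1))
  peak <- peak[peak >= 2]
  if (length(peak) == 0L) return(0)
  stats::median(peak) + 0.5
}
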