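#' Synthetic panicle phantoms
#'
#' The phantom generator renders a known scene — ellipsoidal grains inside a
#' hollow cylindrical plastic holder, optionally blurred and corrupted with
#' additive Gaussian noise — on the same grid and bit depth as the scanner
#' output, together with ground-truth labels and analytic per-grain traits.
#' Every downstream stage of the pipeline is validated against these truths.
#'
#' @name phantom
NULL

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Uniformly random rotation matrix
#'
#' QR-based Haar-uniform rotation with determinant +1, used to orient
#' phantom grains.
#'
#' @param seed optional integer; when given, sampling is local and the
#'   global RNG state is untouched.
#' @return 3x3 orthonormal rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_d)
    q <- q %*% diag(sign(diag(qr.R(qr_d))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Phantom scene specification
#'
#' @param shape integer grid extents `(nx, ny, nz)` in voxels.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param holder `NULL` for no holder, or a list with `inner_radius` (mm),
#'   `wall_thickness` (mm) and `intensity`; the holder is a hollow cylinder
#'   along z centered in the field of view.
#' @param grains list of grain entries, each a list with `center` (mm),
#'   `semi_axes` `(a >= b >= c)` in mm, `rotation` (3x3 orthonormal; columns
#'   are the grain's principal axes in world coordinates) and `intensity`.
#' @param background_intensity scalar background level.
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param blur_sigma Gaussian blur in voxels applied before noise.
#' @param branches optional list of dim connecting cylinders, each a list
#'   with `from`, `to` (mm), `radius` (mm) and `intensity`; emulates rachis
#'   branches.
#' @param seed integer seed making blur/noise deterministic.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = 0.3,
                         holder = NULL, grains = list(),
                         background_intensity = 100, noise_sigma = 0,
                         blur_sigma = 0, branches = list(), seed = 1L) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(shape) == 3L, all(shape >= 1), all(spacing > 0))
  for (g in grains) {
    ax <- g$semi_axes
    if (length(ax) != 3L || any(ax <= 0) || ax[1] < ax[2] || ax[2] < ax[3])
      stop("grain semi-axes must satisfy a >= b >= c > 0")
    R <- g$rotation %||% diag(3)
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      stop("grain rotation matrix is not orthonormal")
    if ((g$intensity %||% 30000) <= background_intensity)
      stop("grain intensity must exceed the background intensity")
  }
  if (!is.null(holder)) {
    stopifnot(holder$inner_radius > 0, holder$wall_thickness > 0)
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 holder = holder, grains = grains,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 branches = branches, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Voxelize one ellipsoidal grain
#'
#' A voxel center `v` belongs to the grain iff the rotated, scaled offset
#' satisfies the ellipsoid inequality
#' `sum((t(R) %*% (v - center) / semi_axes)^2) <= 1`.
#'
#' @param grain one grain entry (see [phantom_spec()]).
#' @param shape grid extents `(nx, ny, nz)`.
#' @param spacing voxel spacing (mm).
#' @param origin physical position of voxel (1,1,1).
#' @return Integer matrix of voxel indices (columns x, y, z), zero rows if
#'   the ellipsoid misses the grid (with a warning).
#' @export
voxelize_ellipsoid <- function(grain, shape, spacing, origin = c(0, 0, 0)) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  ax <- grain$semi_axes
  if (any(ax < min(spacing) / 2)) {
    warning("ellipsoid voxelization is empty (semi-axes below voxel scale)")
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  R <- grain$rotation %||% diag(3)
  ctr <- grain$center
  # bounding box of the rotated ellipsoid: half-extent along axis e_i is
  # sqrt(sum((R[i,] * semi_axes)^2))
  half <- sqrt((R^2) %*% (ax^2))[, 1]
  lo <- pmax(1L, floor((ctr - half - origin) / spacing) + 1L)
  hi <- pmin(shape, ceiling((ctr + half - origin) / spacing) + 1L)
  if (any(lo > hi)) {
    warning("ellipsoid lies entirely outside the grid")
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- origin[1] + (xs - 1) * spacing[1] - ctr[1]
  gy <- origin[2] + (ys - 1) * spacing[2] - ctr[2]
  gz <- origin[3] + (zs - 1) * spacing[3] - ctr[3]
  nxs <- length(xs); nys <- length(ys); nzs <- length(zs)
  px <- rep(gx, times = nys * nzs)
  py <- rep(rep(gy, each = nxs), times = nzs)
  pz <- rep(gz, each = nxs * nys)
  loc <- cbind(px, py, pz) %*% R          # t(R) %*% offset, row-wise
  q <- (loc[, 1] / ax[1])^2 + (loc[, 2] / ax[2])^2 + (loc[, 3] / ax[3])^2
  keep <- q <= 1
  if (!any(keep)) {
    warning("ellipsoid voxelization is empty (degenerate semi-axes?)")
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  idx <- which(keep) - 1L
  cbind(x = xs[1] + idx %% nxs,
        y = ys[1] + (idx %/% nxs) %% nys,
        z = zs[1] + idx %/% (nxs * nys))
}

# Knud Thomsen approximation of the ellipsoid surface area (p = 1.6075,
# relative error < 1.1%).
ellipsoid_surface_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Render a phantom volume with ground truth
#'
#' Renders background, holder, branches and grains, applies optional
#' Gaussian blur then additive Gaussian noise (clipped to `[0, 65535]`), and
#' returns the volume together with pre-noise truth labels and analytic
#' per-grain traits. Deterministic given `spec$seed`. Voxels claimed by
#' several overlapping grains are assigned to the grain with the nearer
#' center.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()]), `truth` (list with
#'   `labels` ([label_volume()]), `traits` data.frame of analytic per-grain
#'   values, `grain_count`, `holder_mask`, `interior_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  sp <- spec$spacing
  vol <- array(as.numeric(spec$background_intensity), dim = shp)
  n <- prod(shp)
  holder_mask <- NULL
  interior_mask <- NULL
  if (!is.null(spec$holder)) {
    cx <- (shp[1] - 1) / 2 * sp[1]
    cy <- (shp[2] - 1) / 2 * sp[2]
    gx <- ((seq_len(shp[1]) - 1) * sp[1] - cx)
    gy <- ((seq_len(shp[2]) - 1) * sp[2] - cy)
    r2 <- outer(gx^2, gy^2, "+")
    rin <- spec$holder$inner_radius
    rout <- rin + spec$holder$wall_thickness
    wall2d <- r2 >= rin^2 & r2 < rout^2
    interior2d <- r2 < rin^2
    holder_mask <- array(wall2d, dim = shp)
    interior_mask <- array(interior2d, dim = shp)
    vol[holder_mask] <- spec$holder$intensity
  }
  for (br in spec$branches) {
    idx <- voxelize_segment(br, shp, sp)
    if (nrow(idx) > 0)
      vol[idx] <- br$intensity
  }
  labels <- array(0L, dim = shp)
  # squared distance to the center of the currently owning grain, for
  # nearer-center tie-breaking on overlaps
  owner_d2 <- array(Inf, dim = shp)
  traits <- list()
  k <- 0L
  for (g in spec$grains) {
    idx <- withCallingHandlers(
      voxelize_ellipsoid(g, shp, sp),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(idx) == 0L) next
    k <- k + 1L
    vol[idx] <- g$intensity %||% 30000
    pos <- sweep(sweep(idx - 1, 2, sp, "*"), 2, g$center, "-")
    d2 <- rowSums(pos^2)
    lin <- as.integer(idx[, 1] + shp[1] * (idx[, 2] - 1L) +
                        shp[1] * shp[2] * (idx[, 3] - 1L))
    take <- d2 < owner_d2[lin]
    labels[lin[take]] <- k
    owner_d2[lin[take]] <- d2[take]
    ax <- g$semi_axes
    traits[[k]] <- data.frame(
      label = k,
      length = 2 * ax[1], width = 2 * ax[2], thickness = 2 * ax[3],
      volume = 4 / 3 * pi * prod(ax),
      surface_area = ellipsoid_surface_area(ax[1], ax[2], ax[3]),
      voxel_count = nrow(idx),
      cx = g$center[1], cy = g$center[2], cz = g$center[3])
  }
  with_seed(spec$seed, {
    if (spec$blur_sigma > 0)
      vol <- array(cpp_gaussian_blur(as.numeric(vol), shp[1], shp[2], shp[3],
                                     spec$blur_sigma, spec$blur_sigma,
                                     spec$blur_sigma), dim = shp)
    if (spec$noise_sigma > 0)
      vol <- vol + array(stats::rnorm(n, 0, spec$noise_sigma), dim = shp)
  })
  vol[vol < 0] <- 0
  vol[vol > 65535] <- 65535
  truth_traits <- if (k > 0) do.call(rbind, traits) else
    data.frame(label = integer(0), length = numeric(0), width = numeric(0),
               thickness = numeric(0), volume = numeric(0),
               surface_area = numeric(0), voxel_count = integer(0),
               cx = numeric(0), cy = numeric(0), cz = numeric(0))
  list(volume = ct_volume(vol, spacing = sp),
       truth = list(labels = label_volume(labels, spacing = sp),
                    traits = truth_traits,
                    grain_count = k,
                    holder_mask = holder_mask,
                    interior_mask = interior_mask))
}

# voxels within `radius` of the segment from -> to (branch cylinders)
voxelize_segment <- function(br, shape, spacing) {
  p0 <- br$from; p1 <- br$to; r <- br$radius
  half <- pmax(abs(p1 - p0) / 2, r) + r
  ctr <- (p0 + p1) / 2
  lo <- pmax(1L, floor((ctr - half) / spacing) + 1L)
  hi <- pmin(shape, ceiling((ctr + half) / spacing) + 1L)
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nxs <- length(xs); nys <- length(ys)
  px <- rep((xs - 1) * spacing[1], times = nys * length(zs))
  py <- rep(rep((ys - 1) * spacing[2], each = nxs), times = length(zs))
  pz <- rep((zs - 1) * spacing[3], each = nxs * nys)
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((px - p0[1]) * v[1] + (py - p0[2]) * v[2] + (pz - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (px - (p0[1] + t * v[1]))^2 + (py - (p0[2] + t * v[2]))^2 +
    (pz - (p0[3] + t * v[3]))^2
  keep <- d2 <= r^2
  idx <- which(keep) - 1L
  cbind(xs[1] + idx %% nxs, ys[1] + (idx %/% nxs) %% nys,
        zs[1] + idx %/% (nxs * nys))
}

#' Standard panicle phantom: grains in a holder
#'
#' Builds a [phantom_spec()] that emulates the scanning conditions the
#' pipeline targets: a 128^3 grid at 0.3 mm isotropic spacing, a plastic
#' holder of 15 mm inner radius and 1.5 mm wall, and rice-grain-sized
#' ellipsoids (semi-axes ~3.5 x 1.5 x 1.0 mm, ~8% size variation, random
#' orientation) placed without contact except for the requested number of
#' touching pairs, which are laid side by side with ~10% overlap of their
#' width axes. Default noise is 5% of the grain/background contrast.
#'
#' @param n_grains total number of grains (including pair members).
#' @param n_touching_pairs number of side-by-side touching pairs.
#' @param shape,spacing grid geometry.
#' @param grain_intensity,holder_intensity,background_intensity intensity
#'   levels; set `holder_intensity = grain_intensity` to reproduce the
#'   histogram-overlap failure mode that defeats fixed-threshold holder
#'   removal.
#' @param noise_sigma additive noise SD; default 5% of contrast.
#' @param blur_sigma blur in voxels.
#' @param seed placement and noise seed.
#' @return A [phantom_spec()].
#' @export
panicle_phantom_spec <- function(n_grains = 20, n_touching_pairs = 0,
                                 shape = c(128, 128, 128), spacing = 0.3,
                                 grain_intensity = 30000,
                                 holder_intensity = 12000,
                                 background_intensity = 100,
                                 noise_sigma = 0.05 *
                                   (grain_intensity - background_intensity),
                                 blur_sigma = 0, seed = 1L) {
  stopifnot(n_grains >= 2 * n_touching_pairs)
  spacing3 <- rep(as.numeric(spacing), length.out = 3L)
  field <- shape * spacing3
  inner_radius <- min(15, 0.78 * min(field[1], field[2]) / 2)
  wall <- 1.5
  ctr_xy <- (shape[1:2] - 1) / 2 * spacing3[1:2]
  mean_axes <- c(3.5, 1.5, 1.0)
  margin <- mean_axes[1] * 1.35
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 3)  # placed grain centers
    radii <- numeric(0)                      # their circumscribed radii
    grains <- list()
    draw_axes <- function() sort(mean_axes * (1 + stats::runif(3, -0.08, 0.08)),
                                 decreasing = TRUE)
    fits <- function(ctr, excl, skip = integer(0)) {
      r_xy <- sqrt(sum((ctr[1:2] - ctr_xy)^2))
      if (r_xy > inner_radius - excl - 0.5) return(FALSE)
      if (ctr[3] < excl || ctr[3] > field[3] - excl) return(FALSE)
      keep <- setdiff(seq_along(radii), skip)
      all(sqrt(colSums((t(centers[keep, , drop = FALSE]) - ctr)^2)) >
            excl + radii[keep] + 0.2)
    }
    sample_center <- function(excl) {
      for (i in 1:8000) {
        r <- (inner_radius - margin) * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        z <- stats::runif(1, margin, field[3] - margin)
        ctr <- c(ctr_xy[1] + r * cos(th), ctr_xy[2] + r * sin(th), z)
        if (fits(ctr, excl)) return(ctr)
      }
      stop("could not place phantom grains without contact; reduce n_grains")
    }
    add_grain <- function(ctr, ax, R) {
      centers <<- rbind(centers, ctr)
      radii <<- c(radii, ax[1])
      grains[[length(grains) + 1L]] <<-
        list(center = ctr, semi_axes = ax, rotation = R,
             intensity = grain_intensity)
    }
    n_singles <- n_grains - 2L * n_touching_pairs
    for (i in seq_len(n_singles)) {
      ax <- draw_axes()
      add_grain(sample_center(ax[1]), ax, random_rotation())
    }
    for (i in seq_len(n_touching_pairs)) {
      ax1 <- draw_axes(); ax2 <- draw_axes()
      done <- FALSE
      for (attempt in 1:200) {
        R <- random_rotation()
        # tip contact along the shared length axis: the neck at the contact
        # is thin, which is what lets a distance watershed find the divide
        offset_len <- stats::runif(1, 0.95, 0.97) * (ax1[1] + ax2[1])
        ctr1 <- sample_center(ax1[1])
        ctr2 <- ctr1 + R[, 1] * offset_len
        if (fits(ctr2, ax2[1])) {
          add_grain(ctr1, ax1, R)
          add_grain(ctr2, ax2, R)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place a touching pair; reduce n_grains")
    }
    phantom_spec(shape = shape, spacing = spacing3,
                 holder = list(inner_radius = inner_radius,
                               wall_thickness = wall,
                               intensity = holder_intensity),
                 grains = grains,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = seed)
  })
}

#' Single-grain phantom for over-segmentation tests
#'
#' One randomly oriented rice-grain ellipsoid on a small grid, no holder,
#' with boundary roughness from unblurred additive noise.
#'
#' @param seed placement/noise seed.
#' @param shape,spacing grid geometry.
#' @param noise_sigma noise SD (default 5% of contrast).
#' @param semi_axes grain semi-axes in mm.
#' @return A [phantom_spec()].
#' @export
single_grain_phantom_spec <- function(seed = 1L, shape = c(64, 64, 64),
                                      spacing = 0.3,
                                      noise_sigma = 0.05 * 29900,
                                      semi_axes = c(3.5, 1.5, 1.0)) {
  spacing3 <- rep(as.numeric(spacing), length.out = 3L)
  ctr <- (shape - 1) / 2 * spacing3
  phantom_spec(shape = shape, spacing = spacing3, holder = NULL,
               grains = list(list(center = ctr, semi_axes = semi_axes,
                                  rotation = random_rotation(seed),
                                  intensity = 30000)),
               background_intensity = 100,
               noise_sigma = noise_sigma, blur_sigma = 0, seed = seed)
}
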