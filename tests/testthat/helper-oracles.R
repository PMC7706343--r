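# Independent oracles and small fixture builders used across the suite.

# Exhaustive Otsu scan: walks every candidate threshold, accumulating class
# weights and sums step by step; ties resolved toward the lowest threshold.
brute_force_otsu <- function(counts) {
  n <- length(counts)
  lv <- seq_len(n) - 1
  total <- sum(counts)
  total_sum <- sum(counts * lv)
  w0 <- 0
  s0 <- 0
  best <- -1
  best_t <- NA_real_
  for (t in seq_len(n - 1)) { # threshold value lv[t]
    w0 <- w0 + counts[t]
    s0 <- s0 + counts[t] * lv[t]
    if (w0 == 0 || w0 == total) next
    mu0 <- s0 / w0
    mu1 <- (total_sum - s0) / (total - w0)
    v <- (w0 / total) * (1 - w0 / total) * (mu0 - mu1)^2
    if (v > best) {   # strict: ties keep the lowest threshold
      best <- v
      best_t <- lv[t]
    }
  }
  best_t
}

# random bimodal 16-bit histogram: two Gaussian-ish peaks of random location,
# spread and mass
random_bimodal_histogram <- function(seed) {
  set.seed(seed)
  h <- numeric(65536)
  centers <- sort(sample(2000:60000, 2))
  while (diff(centers) < 5000) centers <- sort(sample(2000:60000, 2))
  for (i in 1:2) {
    sd_i <- runif(1, 200, 3000)
    x <- round(rnorm(round(runif(1, 2000, 20000)), centers[i], sd_i))
    x <- x[x >= 0 & x <= 65535]
    t <- table(x)
    h[as.integer(names(t)) + 1L] <- h[as.integer(names(t)) + 1L] + as.numeric(t)
  }
  h
}

# voxelized axis-aligned or rotated ellipsoid mask on a cubic grid; the
# center sits on a lattice point so axis-aligned tips are sampled
make_ellipsoid_mask <- function(semi_axes, spacing = 0.3, rotation = diag(3),
                                pad_mm = 3) {
  n <- ceiling((2 * max(semi_axes) + 2 * pad_mm) / spacing)
  g <- list(center = rep(floor((n - 1) / 2) * spacing, 3),
            semi_axes = sort(semi_axes, decreasing = TRUE),
            rotation = rotation, intensity = 1000)
  idx <- voxelize_ellipsoid(g, rep(n, 3), spacing)
  m <- array(FALSE, rep(n, 3))
  m[idx] <- TRUE
  m
}

# Knud Thomsen ellipsoid surface area (error < 1.1%)
kt_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# largest connected component of a mask
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(panicleCT:::cpp_label3d(mask, d[1], d[2], d[3], 26L), d)
  lab == which.max(tabulate(lab[lab > 0L]))
}

# single informative trait among 22 (9 classes x 10 panicles); all other
# traits carry no class signal
one_informative_trait_data <- function(seed, informative = 7L) {
  set.seed(seed)
  x <- matrix(rnorm(90 * 22), 90, 22)
  y <- factor(rep(1:9, each = 10))
  shifts <- seq(0, 8, length.out = 9)
  for (k in 1:9)
    x[y == k, informative] <- x[y == k, informative] + shifts[k]
  colnames(x) <- panicleCT:::PANICLE_TRAIT_NAMES
  list(x = x, y = y)
}
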