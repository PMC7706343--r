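#' Synthetic variety trait matrix
#'
#' Generates a labeled 22-trait matrix emulating a multi-variety panicle
#' study: each variety's mean is shifted by `shift` within-class standard
#' deviations on its own pair of traits (traits `2k-1` and `2k` for variety
#' `k`), all remaining traits are pure noise. Any two varieties thus differ
#' by `shift` SDs on four traits, which keeps the classes separable even
#' for classifiers that cannot discard the noise traits. With `shift = 0`
#' the labels are pure noise and accuracy should fall to chance.
#'
#' @param n_classes number of varieties (at most 11 with 22 traits).
#' @param n_per panicles per variety.
#' @param shift between-class mean shift in within-class SD units.
#' @param seed RNG seed.
#' @return List with `x` (matrix, columns named after the 22 traits) and
#'   `y` (factor of variety labels).
#' @export
synthetic_varieties <- function(n_classes = 9, n_per = 10, shift = 5,
                                seed = 1L) {
  p <- length(PANICLE_TRAIT_NAMES)
  stopifnot(2 * n_classes <= p)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_classes * n_per * p), n_classes * n_per, p)
    y <- factor(rep(seq_len(n_classes), each = n_per))
    for (k in seq_len(n_classes)) {
      x[y == k, 2 * k - 1] <- x[y == k, 2 * k - 1] + shift
      x[y == k, 2 * k] <- x[y == k, 2 * k] + shift
    }
    colnames(x) <- PANICLE_TRAIT_NAMES
    list(x = x, y = y)
  })
}

#' Stepwise discriminant analysis feature selection
#'
#' Wilks'-lambda stepwise selection as used for variety discrimination from
#' panicle traits. At each step the candidate with the largest partial F
#' enters if its p-value is below `p_enter`; after every entry, included
#' features whose partial F p-value has risen above `p_remove` are removed
#' (interrelated traits can lose their discriminating ability once a
#' better one is in). The procedure stops when no entry or removal applies,
#' and canonical discriminant functions are then fitted on the selected
#' set. Because the partial-F statistics are scale-free, the selection is
#' invariant to affine rescaling of individual traits.
#'
#' By default the entry p-value is Bonferroni-adjusted for every candidate
#' test a full stepwise path can perform (`p * (p + 1) / 2` for `p` traits),
#' so `p_enter` bounds the familywise probability that the whole procedure
#' admits any uninformative trait; with many candidate traits an unadjusted
#' threshold admits noise traits in a majority of datasets. Informative
#' traits, whose partial-F p-values are many orders of magnitude below any
#' threshold, are unaffected. `adjust = "none"` reproduces the classic
#' raw-threshold behavior.
#'
#' @param x numeric matrix or data.frame of traits (rows = panicles).
#' @param y class labels (factor or coercible).
#' @param p_enter entry probability threshold (default 0.05).
#' @param p_remove removal probability threshold (default 0.1, must exceed
#'   `p_enter`).
#' @param adjust multiplicity adjustment of the entry test:
#'   `"bonferroni"` (default) or `"none"`.
#' @return Object of class `sda_result`: `features` (selected, in entry
#'   order), `scaling` (canonical coefficients), `centroids` (class
#'   centroids in discriminant space), `xbar`, `levels`, `wilks`.
#'   With no feature passing entry, an empty (warned) selection.
#' @export
sda_select <- function(x, y, p_enter = 0.05, p_remove = 0.1,
                       adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  g <- nlevels(y)
  if (g < 2L) stop("need at least 2 classes")
  if (p_enter >= p_remove) stop("p_enter must be smaller than p_remove")
  p_all <- ncol(x)
  # total and within-class SSCP matrices
  Tm <- crossprod(scale(x, center = TRUE, scale = FALSE))
  Wm <- matrix(0, p_all, p_all)
  for (lv in levels(y)) {
    xi <- x[y == lv, , drop = FALSE]
    Wm <- Wm + crossprod(scale(xi, center = TRUE, scale = FALSE))
  }
  wilks <- function(S) {
    if (length(S) == 0L) return(1)
    det(Wm[S, S, drop = FALSE]) / det(Tm[S, S, drop = FALSE])
  }
  ok_subset <- function(S) {
    ts <- Tm[S, S, drop = FALSE]
    is.finite(rcond(ts)) && rcond(ts) > 1e-12
  }
  S <- integer(0)
  repeat {
    changed <- FALSE
    # entry
    cand <- setdiff(seq_len(p_all), S)
    lam_S <- wilks(S)
    best_f <- -Inf; best_j <- NA_integer_; best_p <- NA_real_
    df2 <- n - g - length(S)
    if (df2 > 0 && p_enter > 0) {
      for (j in cand) {
        Sj <- c(S, j)
        if (!ok_subset(Sj)) next # collinear with included features
        lam <- wilks(Sj)
        if (!is.finite(lam) || lam <= 0 || lam > lam_S + 1e-12) next
        f <- (df2 / (g - 1)) * (lam_S / lam - 1)
        pv <- stats::pf(f, g - 1, df2, lower.tail = FALSE)
        if (adjust == "bonferroni")
          pv <- min(1, pv * p_all * (p_all + 1) / 2)
        if (pv < p_enter && f > best_f) {
          best_f <- f; best_j <- j; best_p <- pv
        }
      }
    }
    if (!is.na(best_j)) {
      S <- c(S, best_j)
      changed <- TRUE
    }
    # removal sweep
    repeat {
      if (length(S) == 0L) break
      lam_S <- wilks(S)
      df2r <- n - g - length(S) + 1
      worst_p <- -Inf; worst_j <- NA_integer_
      for (j in S) {
        lam_wo <- wilks(setdiff(S, j))
        f <- (df2r / (g - 1)) * (lam_wo / lam_S - 1)
        pv <- stats::pf(f, g - 1, df2r, lower.tail = FALSE)
        if (pv > worst_p) { worst_p <- pv; worst_j <- j }
      }
      if (worst_p > p_remove) {
        S <- setdiff(S, worst_j)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  majority <- levels(y)[which.max(table(y))]
  if (length(S) == 0L) {
    warning("no feature passed the entry criterion; empty selection")
    return(structure(list(features = integer(0),
                          feature_names = character(0),
                          scaling = NULL, centroids = NULL, xbar = NULL,
                          levels = levels(y), majority = majority,
                          wilks = 1),
                     class = "sda_result"))
  }
  sel <- x[, S, drop = FALSE]
  fit <- MASS::lda(sel, grouping = y)
  xbar <- colMeans(sel)
  centroids <- scale(fit$means, center = xbar, scale = FALSE) %*% fit$scaling
  structure(list(features = S,
                 feature_names = colnames(x)[S] %||% as.character(S),
                 scaling = fit$scaling, centroids = centroids,
                 xbar = xbar, levels = levels(y), majority = majority,
                 wilks = wilks(S)),
            class = "sda_result")
}

#' Predict classes with a fitted discriminant model
#'
#' Projects samples onto the canonical discriminant functions and assigns
#' each to the class with the nearest centroid in discriminant space (ties
#' go to the lowest class id). The returned scores are the coordinates used
#' for the classic two-function scatter plots.
#'
#' @param model an `sda_result` from [sda_select()].
#' @param newdata matrix/data.frame with the same trait columns as
#'   training.
#' @return List with `class` (factor) and `scores` (matrix of discriminant
#'   coordinates).
#' @export
lda_predict <- function(model, newdata) {
  stopifnot(inherits(model, "sda_result"))
  if (length(model$features) == 0L)
    stop("model has an empty feature selection; cannot predict")
  newdata <- as.matrix(newdata)
  sel <- newdata[, model$features, drop = FALSE]
  scores <- scale(sel, center = model$xbar, scale = FALSE) %*% model$scaling
  d2 <- outer(rowSums(scores^2), rowSums(model$centroids^2), "+") -
    2 * scores %*% t(model$centroids)
  cls <- apply(d2, 1, which.min) # which.min takes the first (lowest id) tie
  list(class = factor(model$levels[cls], levels = model$levels),
       scores = scores)
}

#' RBF-SVM with particle-swarm hyperparameter search
#'
#' Trains a radial-basis-function support vector machine whose cost `c` and
#' kernel width `gamma` are tuned by particle swarm optimization in
#' log10-space. Each particle's fitness is the stratified k-fold
#' cross-validation accuracy on the training data (folds fixed once per
#' call from `swarm$seed`, so the search is deterministic). Features are
#' standardized internally.
#'
#' @param x trait matrix (rows = samples).
#' @param y class labels.
#' @param c_range,gamma_range search ranges (positive).
#' @param swarm list of PSO settings: `particles` (20), `iterations` (50),
#'   `inertia` (0.72), `cognitive` and `social` (1.49), `seed` (1).
#' @param folds CV folds used as fitness (default 5).
#' @return Object of class `pso_svm`: fitted `model`, `best_c`,
#'   `best_gamma`, `fitness` (CV accuracy at the optimum), standardization
#'   parameters and the swarm trace.
#' @export
svm_pso_train <- function(x, y, c_range = c(1e-2, 1e4),
                          gamma_range = c(1e-4, 1e2),
                          swarm = list(), folds = 5) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  stopifnot(all(c_range > 0), all(gamma_range > 0))
  sw <- utils::modifyList(list(particles = 20L, iterations = 50L,
                               inertia = 0.72, cognitive = 1.49,
                               social = 1.49, seed = 1L), swarm)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  lo <- log10(c(c_range[1], gamma_range[1]))
  hi <- log10(c(c_range[2], gamma_range[2]))
  with_seed(sw$seed, {
    fold_id <- make_stratified_folds(y, folds)
    fitness <- function(pos) {
      cost <- 10^pos[1]; gamma <- 10^pos[2]
      correct <- 0L
      for (f in seq_len(max(fold_id))) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2L) next
        fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], type = "C-classification",
                          kernel = "radial", cost = cost, gamma = gamma,
                          scale = FALSE)
        pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }
    np <- sw$particles
    pos <- cbind(stats::runif(np, lo[1], hi[1]), stats::runif(np, lo[2], hi[2]))
    vmax <- (hi - lo) / 2
    vel <- cbind(stats::runif(np, -vmax[1], vmax[1]),
                 stats::runif(np, -vmax[2], vmax[2]))
    # among CV-tied settings prefer the smoother kernel (smaller gamma),
    # then the smaller cost: CV accuracy plateaus are wide and the smooth
    # end of a plateau generalizes better
    better <- function(fit_a, pos_a, fit_b, pos_b) {
      if (fit_a != fit_b) return(fit_a > fit_b)
      if (pos_a[2] != pos_b[2]) return(pos_a[2] < pos_b[2])
      pos_a[1] < pos_b[1]
    }
    pbest <- pos
    pbest_fit <- apply(pos, 1, fitness)
    gi <- 1L
    for (p in seq_len(np))
      if (better(pbest_fit[p], pbest[p, ], pbest_fit[gi], pbest[gi, ]))
        gi <- p
    gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    trace <- numeric(0)
    for (it in if (gbest_fit >= 1) integer(0) else seq_len(sw$iterations)) {
      r1 <- matrix(stats::runif(np * 2), np, 2)
      r2 <- matrix(stats::runif(np * 2), np, 2)
      vel <- sw$inertia * vel +
        sw$cognitive * r1 * (pbest - pos) +
        sw$social * r2 * (matrix(gbest, np, 2, byrow = TRUE) - pos)
      vel[, 1] <- pmin(pmax(vel[, 1], -vmax[1]), vmax[1])
      vel[, 2] <- pmin(pmax(vel[, 2], -vmax[2]), vmax[2])
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      fit_now <- apply(pos, 1, fitness)
      for (p in seq_len(np)) {
        if (better(fit_now[p], pos[p, ], pbest_fit[p], pbest[p, ])) {
          pbest[p, ] <- pos[p, ]
          pbest_fit[p] <- fit_now[p]
        }
        if (better(pbest_fit[p], pbest[p, ], gbest_fit, gbest)) {
          gbest <- pbest[p, ]
          gbest_fit <- pbest_fit[p]
        }
      }
      trace <- c(trace, gbest_fit)
      if (gbest_fit >= 1) break
    }
    model <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                        cost = 10^gbest[1], gamma = 10^gbest[2], scale = FALSE)
    structure(list(model = model, best_c = 10^gbest[1],
                   best_gamma = 10^gbest[2], fitness = gbest_fit,
                   center = ctr, scale = scl, levels = levels(y),
                   trace = trace, fold_id = fold_id),
              class = "pso_svm")
  })
}

make_stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (lv in levels(y)) {
    i <- which(y == lv)
    id[i] <- rep_len(seq_len(folds), length(i))[sample.int(length(i))]
  }
  id
}

#' Random-forest variety classifier
#'
#' Majority-vote ensemble of decision trees, each split drawn from a random
#' subset of `k_features` traits; deterministic given `seed`.
#'
#' @param x trait matrix.
#' @param y class labels.
#' @param n_trees number of trees (default 500).
#' @param k_features candidate features per split (default
#'   `floor(sqrt(ncol(x)))`).
#' @param seed RNG seed.
#' @return Object of class `rf_model` wrapping the fitted forest.
#' @export
rf_train <- function(x, y, n_trees = 500, k_features = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(k_features)) k_features <- max(1L, floor(sqrt(ncol(x))))
  fit <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees, mtry = k_features))
  structure(list(model = fit, levels = levels(y)), class = "rf_model")
}

#' Predict classes from a fitted variety classifier
#'
#' @param model an `sda_result`, `pso_svm` or `rf_model`.
#' @param newdata trait matrix with the training columns.
#' @return Factor of predicted classes.
#' @export
predict_class <- function(model, newdata) UseMethod("predict_class")

#' @export
predict_class.sda_result <- function(model, newdata) {
  # a model that selected no feature carries no discriminant information:
  # predict the majority training class
  if (length(model$features) == 0L)
    return(factor(rep(model$majority, nrow(as.matrix(newdata))),
                  levels = model$levels))
  lda_predict(model, newdata)$class
}

#' @export
predict_class.pso_svm <- function(model, newdata) {
  xs <- scale(as.matrix(newdata), center = model$center, scale = model$scale)
  stats::predict(model$model, xs)
}

#' @export
predict_class.rf_model <- function(model, newdata) {
  stats::predict(model$model, as.matrix(newdata))
}

#' Leave-one-out cross-validation of a variety classifier
#'
#' Fits the trainer n times, holding out one panicle each time; feature
#' selection and hyperparameter search run inside every fold, so no
#' information leaks from the held-out sample. Reports per-class accuracies
#' and the overall accuracy (the mean of the per-sample 0/1 outcomes, which
#' equals the class-size-weighted mean of the per-class accuracies).
#'
#' @param x trait matrix (rows = panicles).
#' @param y class labels.
#' @param trainer function `(x, y) -> model` accepted by
#'   [predict_class()], e.g. `function(x, y) sda_select(x, y)`.
#' @return List with `per_class` (named accuracy vector), `overall`,
#'   `predictions` (factor) and `n` per class.
#' @export
loo_cv <- function(x, y, trainer) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples for leave-one-out")
  if (any(table(y) < 2L))
    warning("some class has a single member; its fold trains without it")
  preds <- character(n)
  for (i in seq_len(n)) {
    fit <- trainer(x[-i, , drop = FALSE], y[-i])
    preds[i] <- as.character(predict_class(fit, x[i, , drop = FALSE]))
  }
  preds <- factor(preds, levels = levels(y))
  hit <- preds == y
  per_class <- vapply(levels(y), function(lv) mean(hit[y == lv]), numeric(1))
  list(per_class = per_class,
       overall = mean(hit),
       predictions = preds,
       n = table(y))
}
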