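test_that("stepwise selection finds the informative trait and only it", {
  d <- one_informative_trait_data(1)
  s <- sda_select(d$x, d$y)
  expect_identical(s$features, 7L)
  # duplicated informative feature: exactly one of the pair selected
  x2 <- d$x
  x2[, 8] <- x2[, 7]
  s2 <- sda_select(x2, d$y)
  expect_length(intersect(s2$features, c(7L, 8L)), 1L)
  # p_enter = 0: empty selection, with a warning
  expect_warning(s0 <- sda_select(d$x, d$y, p_enter = 0, p_remove = 0.1),
                 "empty selection")
  expect_length(s0$features, 0L)
  expect_error(lda_predict(s0, d$x), "empty feature selection")
  expect_error(sda_select(d$x, d$y, p_enter = 0.2, p_remove = 0.1),
               "p_enter")
})

test_that("selection is invariant to rescaling a single trait", {
  d <- one_informative_trait_data(2)
  s1 <- sda_select(d$x, d$y)
  x2 <- d$x
  x2[, 7] <- x2[, 7] * 1000 - 5
  x2[, 3] <- x2[, 3] / 1000
  s2 <- sda_select(x2, d$y)
  expect_identical(s1$features, s2$features)
})

test_that("discriminant prediction is nearest-centroid with a tie rule", {
  dv <- synthetic_varieties(n_classes = 4, n_per = 8, seed = 3)
  s <- sda_select(dv$x, dv$y)
  pred <- lda_predict(s, dv$x)
  expect_equal(mean(pred$class == dv$y), 1)          # separable: perfect
  expect_equal(ncol(pred$scores), min(3, ncol(s$scaling)))
  # class centroids map back to their own classes
  cent_x <- do.call(rbind, lapply(levels(dv$y), function(lv)
    colMeans(dv$x[dv$y == lv, , drop = FALSE])))
  pc <- lda_predict(s, cent_x)
  expect_identical(as.character(pc$class), levels(dv$y))
})

test_that("PSO-tuned SVM is deterministic and fits separable data", {
  dv <- synthetic_varieties(n_classes = 3, n_per = 8, seed = 4)
  sw <- list(particles = 8, iterations = 10, seed = 5)
  f1 <- svm_pso_train(dv$x, dv$y, swarm = sw, folds = 3)
  f2 <- svm_pso_train(dv$x, dv$y, swarm = sw, folds = 3)
  expect_identical(c(f1$best_c, f1$best_gamma), c(f2$best_c, f2$best_gamma))
  expect_equal(f1$fitness, 1)
  expect_equal(mean(predict_class(f1, dv$x) == dv$y), 1)
  # PSO fitness at the optimum is at least that of a coarse grid search
  # on the same folds
  grid_fit <- local({
    ctr <- colMeans(dv$x); scl <- apply(dv$x, 2, sd); scl[scl == 0] <- 1
    xs <- scale(dv$x, ctr, scl)
    folds <- panicleCT:::with_seed(5L,
      panicleCT:::make_stratified_folds(dv$y, 3))
    best <- 0
    for (lc in seq(log10(1e-2), log10(1e4), length.out = 5))
      for (lg in seq(log10(1e-4), log10(1e2), length.out = 5)) {
        correct <- 0
        for (f in 1:3) {
          tr <- folds != f
          fit <- e1071::svm(xs[tr, ], dv$y[tr], type = "C-classification",
                            kernel = "radial", cost = 10^lc, gamma = 10^lg,
                            scale = FALSE)
          correct <- correct + sum(predict(fit, xs[!tr, ]) == dv$y[!tr])
        }
        best <- max(best, correct / length(dv$y))
      }
    best
  })
  expect_gte(f1$fitness, grid_fit)
})

test_that("random forest wrapper is deterministic and separable-exact", {
  dv <- synthetic_varieties(n_classes = 3, n_per = 8, seed = 6)
  f1 <- rf_train(dv$x, dv$y, n_trees = 100, seed = 11)
  f2 <- rf_train(dv$x, dv$y, n_trees = 100, seed = 11)
  expect_identical(predict_class(f1, dv$x), predict_class(f2, dv$x))
  expect_equal(mean(predict_class(f1, dv$x) == dv$y), 1)
  # a single tree's forest predicts exactly like that tree
  f3 <- rf_train(dv$x, dv$y, n_trees = 1, seed = 11)
  expect_equal(mean(predict_class(f3, dv$x) == dv$y) > 0.8, TRUE)
})

test_that("leave-one-out accounting matches hand enumeration", {
  # n = 4, 2 classes, nearest-centroid by construction
  x <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  colnames(x) <- c("t1", "t2")
  y <- factor(c("a", "a", "b", "b"))
  trainer <- function(x, y) {
    cent <- do.call(rbind, lapply(levels(droplevels(y)), function(lv)
      colMeans(x[y == lv, , drop = FALSE])))
    structure(list(cent = cent, levels = levels(droplevels(y))),
              class = "nc_toy")
  }
  registerS3method("predict_class", "nc_toy", function(model, newdata) {
    d <- as.matrix(stats::dist(rbind(newdata, model$cent)))[1, -1]
    factor(model$levels[which.min(d)], levels = model$levels)
  }, envir = asNamespace("panicleCT"))
  res <- loo_cv(x, y, trainer)
  # hand enumeration: every held-out point is closer to its own class's
  # remaining centroid
  expect_equal(res$overall, 1)
  expect_equal(unname(res$per_class), c(1, 1))
  # accounting identity: overall equals the class-size-weighted mean
  dv <- synthetic_varieties(n_classes = 3, n_per = 5, shift = 1.5, seed = 9)
  r <- suppressWarnings(loo_cv(dv$x, dv$y, function(x, y) sda_select(x, y)))
  w <- as.numeric(r$n) / sum(r$n)
  expect_equal(r$overall, sum(w * r$per_class), tolerance = 1e-12)
  expect_equal(r$overall, mean(r$predictions == dv$y), tolerance = 1e-12)
})

test_that("held-out labels never leak into the prediction", {
  dv <- synthetic_varieties(n_classes = 3, n_per = 6, seed = 10)
  i <- 5L
  fit <- sda_select(dv$x[-i, ], dv$y[-i])
  p1 <- predict_class(fit, dv$x[i, , drop = FALSE])
  y2 <- dv$y
  y2[i] <- levels(dv$y)[3]   # corrupt the held-out label
  fit2 <- sda_select(dv$x[-i, ], y2[-i])
  p2 <- predict_class(fit2, dv$x[i, , drop = FALSE])
  expect_identical(as.character(p1), as.character(p2))
})
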