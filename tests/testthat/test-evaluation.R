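test_that("confusion matrix counts true/predicted pairs", {
  expect_equal(unname(confusion_matrix(c(0, 1, 1), c(0, 0, 1), 2)),
               matrix(c(1, 1, 0, 1), 2))
  y <- c(0L, 1L, 2L, 1L, 0L)
  cm <- confusion_matrix(y, y, 3)
  expect_equal(unname(diag(cm)), c(2L, 2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm0 <- confusion_matrix(y, rep(0L, 5), 3)
  expect_true(all(cm0[, 2:3] == 0))
  expect_error(confusion_matrix(c(0, 3), c(0, 0), 2), "\\[0, 2\\)")
})

test_that("classification report matches hand-enumerated metrics", {
  # y_true = [0,0,1,1], y_pred = [0,1,1,1]:
  # class 0: TP=1 FP=0 FN=1 -> P=1, R=.5, F1=2/3
  # class 1: TP=2 FP=1 FN=0 -> P=2/3, R=1, F1=0.8
  r <- classification_report(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(r$per_class$precision, c(1, 2 / 3))
  expect_equal(r$per_class$recall, c(0.5, 1))
  expect_equal(r$per_class$f1, c(2 / 3, 0.8))
  expect_equal(r$accuracy, 0.75)
  expect_equal(unname(r$macro_avg["f1"]), (2 / 3 + 0.8) / 2)
  expect_equal(unname(r$weighted_avg["f1"]), 0.5 * 2 / 3 + 0.5 * 0.8)
  expect_equal(sum(r$per_class$support), r$n)

  perfect <- classification_report(0:3, 0:3, 4)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(unname(perfect$macro_avg), rep(1, 3))
})

test_that("absent classes get zero metrics, zero support, macro inclusion", {
  r <- classification_report(c(0, 0, 1), c(0, 0, 1), 3)
  expect_equal(r$per_class$support[3], 0L)
  expect_equal(r$per_class$f1[3], 0)
  # macro includes the absent class as zero
  expect_equal(unname(r$macro_avg["f1"]), (1 + 1 + 0) / 3)
  # weighted average ignores it (weight 0) and stays 1
  expect_equal(unname(r$weighted_avg["f1"]), 1)
})

test_that("micro-averaged recall equals accuracy on random labelings", {
  set.seed(21)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    y <- sample(0:(K - 1), 60, replace = TRUE)
    p <- sample(0:(K - 1), 60, replace = TRUE)
    r <- classification_report(y, p, K)
    micro_recall <- sum(diag(r$confusion)) / sum(r$confusion)
    expect_equal(micro_recall, r$accuracy)
    expect_equal(unname(rowSums(r$confusion)), r$per_class$support)
  }
})

test_that("reconstruction RMSE matches closed forms", {
  x <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  expect_equal(reconstruction_rmse(x, x)$overall, 0)
  z <- array(0, c(2, 3, 4)); o <- array(1, c(2, 3, 4))
  expect_equal(reconstruction_rmse(z, o)$overall, 1)
  expect_equal(reconstruction_rmse(z, o)$per_channel, rep(1, 3))
  expect_equal(reconstruction_rmse(array(0, c(1, 1, 2)),
                                   array(c(3, 4), c(1, 1, 2)))$overall,
               sqrt(12.5))
  expect_error(reconstruction_rmse(z, array(0, c(2, 3, 5))), "identical")
})

test_that("latent embedding is the flattened classifier input", {
  net <- assemble(tiny_model("MCAE"), seed = 1)
  b <- window_batch(array(rnorm(5 * 2 * 16), c(5, 2, 16)),
                    rep(0:1, length.out = 5), rep("s", 5), 1L)
  emb <- extract_latent(net, b)
  expect_equal(dim(emb$features), c(5, (16 / 16) * 2))
  lat <- model_forward(net, b)$latent
  expect_equal(emb$features, matrix(lat, 5, 2))
  expect_identical(emb$features, extract_latent(net, b)$features)
  expect_equal(emb$labels, b$labels)
})

test_that("pca projection is deterministic and preserves variance", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5) %*% diag(c(3, 2, 1, 0.5, 0.1))
  p <- pca_project(X, 3)
  expect_equal(p$projection, pca_project(X, 3)$projection)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  # dual route: explained fractions from a covariance eigendecomposition
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$explained_variance_ratio, (ev / sum(ev))[1:3], tolerance = 1e-8)
  # sign convention: dominant loading positive
  for (j in 1:3) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("pca handles degenerate geometry", {
  t <- seq(0, 1, length.out = 10)
  line <- cbind(t, 2 * t, -t) + 5
  p <- pca_project(line, 3)
  expect_equal(p$explained_variance_ratio, c(1, 0, 0), tolerance = 1e-10)
  plane <- cbind(t, rev(t)^2, t + rev(t)^2)   # third column dependent
  pp <- pca_project(plane, 3)
  expect_equal(sum(pp$explained_variance_ratio[1:2]), 1, tolerance = 1e-10)
  # rank below n_components: zero-padded with a warning
  expect_warning(pr <- pca_project(matrix(rnorm(12), 6, 2), 3), "padding")
  expect_true(all(pr$projection[, 3] == 0))
  expect_error(pca_project(matrix(rnorm(6), 3, 2), 3), "more than 3")
})

test_that("activation comparison reports one row per activation and seed", {
  splits <- tiny_splits()
  cmp <- activation_comparison(splits, activations = c("relu", "selu"),
                               seeds = 1, config = tiny_model("AE"),
                               control = tiny_control(max_epochs = 2, variant = "AE"))
  expect_equal(nrow(cmp$table), 2)
  expect_equal(sort(unique(cmp$per_class$class)), c(0, 1))
  expect_true(all(c("val_huber", "rmse_overall") %in% names(cmp$table)))
  expect_true(all(cmp$examples$best_rmse <= cmp$examples$worst_rmse))
  # identical run is reproducible row by row
  cmp2 <- activation_comparison(splits, activations = c("relu", "selu"),
                                seeds = 1, config = tiny_model("AE"),
                                control = tiny_control(max_epochs = 2, variant = "AE"))
  expect_equal(cmp$table, cmp2$table)
})
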