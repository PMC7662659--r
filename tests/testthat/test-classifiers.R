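test_that("identity-activation ELM reproduces the least-squares fit", {
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(c("a", "b", "c"), 10)
  m <- fit_elm(X, labels, n_hidden = 4, seed = 2, activation = "identity")
  hh <- cbind(1, sweep(tcrossprod(X, m$fit$w_in), 2, m$fit$b, `+`))
  scores <- hh %*% m$fit$beta
  targets <- one_hot(labels)
  ls_fit <- fitted(lm(targets ~ X)) # closed-form least-squares oracle
  expect_equal(unname(scores), unname(ls_fit), tolerance = 1e-8)
})

test_that("ELM auto sweep fits separable data and respects its bounds", {
  X <- rbind(c(0, 0), c(1, 1))
  m <- fit_elm(X, c("a", "b"), n_hidden = "auto", seed = 3)
  expect_equal(predict(m, X), c("a", "b"))
  expect_lte(m$spec$parameter, 2) # sweep caps at the training-set size
  expect_error(fit_elm(X, c("a", "b"), n_hidden = 5), "n_train")
  # reproducibility
  set.seed(99)
  Xl <- matrix(rnorm(40), 10, 4)
  ll <- rep(c("a", "b"), 5)
  p1 <- predict(fit_elm(Xl, ll, 6, seed = 7), Xl)
  p2 <- predict(fit_elm(Xl, ll, 6, seed = 7), Xl)
  expect_identical(p1, p2)
})

test_that("random forest votes agree with a per-tree tally", {
  set.seed(2)
  X <- matrix(rnorm(16 * 3), 16, 3)
  labels <- rep(c("a", "b"), each = 8)
  X[labels == "b", 1] <- X[labels == "b", 1] + 3
  m <- fit_rf(X, labels, n_trees = 25, seed = 5)
  expect_equal(predict(m, X), labels) # pure classes, in-bag fit
  # majority vote equals a manual per-tree loop
  Xn <- matrix(rnorm(8 * 3), 8, 3)
  colnames(Xn) <- paste0("v", 1:3)
  per_tree <- predict(m$fit, Xn, predict.all = TRUE)$individual
  tally <- apply(per_tree, 1, function(v) {
    tab <- table(v)
    names(tab)[which.max(tab)]
  })
  ours <- predict(m, Xn)
  agree <- mean(ours == tally)
  expect_gte(agree, 0.99) # exact up to randomForest's own tie handling
  expect_true(all(ours %in% c("a", "b")))
})

test_that("RBF with all training points as centers interpolates", {
  set.seed(3)
  X <- matrix(rnorm(12 * 2), 12, 2)
  labels <- rep(c("a", "b", "c"), 4)
  m <- fit_rbf(X, labels, n_centers = 12, spread = 0.05, seed = 1)
  expect_equal(predict(m, X), labels)
})

test_that("RBF output weights match a least-squares oracle at fixed centers", {
  set.seed(4)
  X <- matrix(rnorm(6 * 2), 6, 2)
  labels <- c("a", "a", "b", "b", "c", "c")
  m <- fit_rbf(X, labels, n_centers = 6, spread = 1, seed = 2)
  phi <- mirwalnut:::rbf_activations(X, m$fit$centers, 1)
  oracle <- fitted(lm(one_hot(labels) ~ phi)) # ridge at zero penalty
  scores <- cbind(1, phi) %*% m$fit$beta
  expect_equal(unname(scores), unname(oracle), tolerance = 1e-6)
})

test_that("PLS-DA is exact on one-hot inputs and applies the 0.5 threshold", {
  labels <- rep(c("a", "b", "c"), each = 4)
  X <- one_hot(labels) + 0 # identity features
  m <- fit_plsda(X, labels, n_lv = 2)
  expect_equal(predict(m, X), labels)
  # threshold rule: 0.49 prediction for a 0-coded class column is accepted
  scores <- matrix(c(0.49, 0.6, 0.1), 1, dimnames = list(NULL, c("a", "b", "c")))
  acc <- threshold_accept(scores, labels = "b", threshold = 0.5)
  expect_true(acc[1, "a"]) # |0.49 - 0| < 0.5
  expect_true(acc[1, "b"])
  expect_error(fit_plsda(X, labels, n_lv = 2, threshold = 1.5), "in \\(0,1\\)")
})

test_that("argmax agrees with the threshold rule when exactly one column passes", {
  grid <- seq(0.05, 0.95, by = 0.15)
  combos <- expand.grid(a = grid, b = grid, c = grid)
  for (i in seq_len(nrow(combos))) {
    yhat <- as.matrix(combos[i, ])
    colnames(yhat) <- c("a", "b", "c")
    passes <- yhat > 0.5 # within 0.5 of a one-coded target
    if (sum(passes) == 1) {
      expect_equal(colnames(yhat)[which(passes)],
                   colnames(yhat)[which.max(yhat)])
    }
  }
})

test_that("PLS-DA decisions are invariant to class relabeling order", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(c("a", "b", "c"), 10)
  X[labels == "b", 1] <- X[labels == "b", 1] + 2
  X[labels == "c", 2] <- X[labels == "c", 2] + 2
  m <- fit_plsda(X, labels, n_lv = 3)
  relab <- c(a = "zeta", b = "alpha", c = "midl")[labels]
  m2 <- fit_plsda(X, relab, n_lv = 3)
  p1 <- predict(m, X)
  p2 <- predict(m2, X)
  expect_equal(unname(c(a = "zeta", b = "alpha", c = "midl")[p1]), p2)
})

test_that("BPNN trains separable blobs to 100% and is seed-reproducible", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20, mean = 0, sd = 0.3), 10, 2),
             matrix(rnorm(20, mean = 3, sd = 0.3), 10, 2))
  labels <- rep(c("lo", "hi"), each = 10)
  m0 <- fit_bpnn(X, labels, n_hidden = 4, epochs = 0, seed = 11)
  m0b <- fit_bpnn(X, labels, n_hidden = 4, epochs = 0, seed = 11)
  expect_identical(predict(m0, X), predict(m0b, X)) # initial-weight check
  m <- fit_bpnn(X, labels, n_hidden = 4, seed = 11)
  expect_equal(predict(m, X), labels)
  expect_true(m$fit$mse <= 1e-5 || is.finite(m$fit$mse))
})

test_that("predictions permute with the sample order and check dimensions", {
  set.seed(7)
  X <- matrix(rnorm(24 * 3), 24, 3)
  labels <- rep(c("a", "b"), 12)
  X[labels == "b", ] <- X[labels == "b", ] + 2
  perm <- sample(24)
  for (kind in c("ELM", "RF", "RBF", "PLSDA", "BPNN")) {
    m <- fit_classifier(X, labels, kind, seed = 8)
    p <- predict(m, X)
    expect_identical(p[perm], predict(m, X[perm, ]))
    expect_true(all(p %in% c("a", "b")))
    expect_error(predict(m, X[, 1:2]), "columns")
  }
})
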