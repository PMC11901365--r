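test_that("f_regression_rank: hand-derived F, constants last, perfect first", {
  r <- f_regression_rank(cbind(x = c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_equal(r$F, 8)                 # r^2 = 0.8 -> 0.8 * 2 / 0.2
  X <- cbind(noise = c(0.3, -1, 2, 0.1, 0.7, -0.2),
             const = rep(3, 6),
             exact = c(0, 0, 0, 1, 1, 1))
  y <- c(0, 0, 0, 1, 1, 1)
  rk <- f_regression_rank(X, y)
  expect_equal(rk$index[1], 3)         # identical to y -> infinite F, first
  expect_equal(rk$index[3], 2)         # constant -> F = 0, last
  expect_equal(rk$F[3], 0)
  expect_error(f_regression_rank(X, rep(1, 6)), class = "ab_single_class")
})

test_that("f_regression_rank equals the brute-force correlation oracle", {
  set.seed(51)
  for (rep_ in 1:5) {
    X <- matrix(rnorm(20 * 30), 20, 30)
    y <- rep(c(0, 1), c(9, 11))
    rk <- f_regression_rank(X, y)
    f_brute <- vapply(seq_len(30), function(j) {
      r2 <- suppressWarnings(cor(X[, j], y))^2
      if (is.na(r2)) 0 else r2 * 18 / (1 - r2)
    }, numeric(1))
    expect_equal(rk$index, order(-f_brute, seq_len(30)))
    expect_equal(rk$F, sort(f_brute, decreasing = TRUE), tolerance = 1e-10)
  }
})

test_that("select_k: top-k, ties to the lowest index, k overflow keeps all", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 2))
  rk <- f_regression_rank(X, c(0, 0, 1, 1))
  expect_equal(select_k(rk, 1)$indices, 1L)       # tie a/b -> lower index
  expect_equal(select_k(rk, 2)$indices, c(1L, 2L))
  expect_equal(sort(select_k(rk, 99)$indices), 1:3)
  expect_identical(select_k(rk, 2)$indices,
                   select_k(select_k(rk, 3)$scores, 2)$indices)  # idempotent
})

test_that("classifiers separate separable data and respect label symmetry", {
  set.seed(52)
  lf <- generate_labeled_features(labeled_feature_spec(n = 60, d = 10,
                                                       k_informative = 3,
                                                       effect = 4, seed = 52))
  for (kind in c("linear_margin", "ridge", "logistic")) {
    m <- train_classifier(lf$X, lf$y, kind = kind)
    pr <- predict(m, lf$X)
    cm <- table(lf$y, pr$label == "approved")
    expect_equal(mcc(cm["1", "TRUE"], cm["0", "TRUE"],
                     cm["0", "FALSE"], cm["1", "FALSE"]), 1)
  }
  # inverted labels negate the decision weights (ridge is exact)
  m1 <- train_classifier(lf$X, lf$y, kind = "ridge")
  m2 <- train_classifier(lf$X, 1 - lf$y, kind = "ridge")
  expect_equal(m1$w, -m2$w, tolerance = 1e-8)
  expect_error(train_classifier(lf$X, rep(1, 60)), class = "ab_single_class")
})

test_that("prediction thresholds are monotone and dimensions are checked", {
  set.seed(53)
  lf <- generate_labeled_features(labeled_feature_spec(n = 80, d = 8,
                                                       k_informative = 2,
                                                       effect = 1, seed = 53))
  m <- train_classifier(lf$X, lf$y)
  p5 <- predict(m, lf$X, threshold = 0.5)
  p8 <- predict(m, lf$X, threshold = 0.8)
  pos5 <- which(p5$label == "approved"); pos8 <- which(p8$label == "approved")
  expect_true(all(pos8 %in% pos5))
  expect_true(all(p5$probability >= 0 & p5$probability <= 1))
  expect_equal(nrow(predict(m, lf$X[0, , drop = FALSE])), 0L)
  expect_error(predict(m, lf$X[, 1:3]), class = "ab_dimension_mismatch")
})

test_that("mcc: anchors and exhaustive agreement with the correlation oracle", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(45, 5, 45, 5), 0.8)
  expect_equal(mcc(10, 10, 0, 0), 0)   # all-positive predictions
  # every 2x2 table with entries <= 5: mcc == Pearson phi when defined
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    truth <- rep(c(1, 1, 0, 0), c(tp, fn, fp, tn))
    pred <- rep(c(1, 0, 1, 0), c(tp, fn, fp, tn))
    phi <- if (length(truth) < 2) NA else suppressWarnings(cor(truth, pred))
    expect_equal(mcc(tp, fp, tn, fn), if (is.na(phi)) 0 else phi,
                 tolerance = 1e-12)
  }
})

test_that("cross_validate partitions samples and nails separable data", {
  set.seed(54)
  lf <- generate_labeled_features(labeled_feature_spec(n = 100, d = 200,
                                                       k_informative = 5,
                                                       effect = 3, seed = 54))
  cv <- cross_validate(lf$X, lf$y, k = 20, folds = 10, seed = 9)
  counts <- rowSums(cv$per_fold[, c("tp", "fp", "tn", "fn")])
  expect_equal(sum(counts), 100)       # each sample in exactly one test fold
  expect_gte(unname(cv$mean["mcc"]), 0.95)
  expect_error(cross_validate(lf$X[1:5, ], lf$y[1:5], k = 5, folds = 10),
               class = "ab_too_few_samples")
})

test_that("null labels give chance-level MCC; out-of-fold selection inflates it", {
  mccs_in <- mccs_out <- numeric(0)
  for (s in 1:6) {
    set.seed(s)
    X <- matrix(rnorm(40 * 800), 40, 800)
    y <- rep(0:1, 20)
    mccs_in <- c(mccs_in,
                 cross_validate(X, y, k = 50, folds = 5, seed = s)$mean["mcc"])
    mccs_out <- c(mccs_out,
                  cross_validate(X, y, k = 50, folds = 5, seed = s,
                                 select_within_folds = FALSE)$mean["mcc"])
  }
  expect_lt(abs(mean(mccs_in)), 0.2)
  # the leakage pitfall: selecting features on the full data before CV
  # makes pure noise look almost perfectly separable
  expect_gt(mean(mccs_out), mean(mccs_in) + 0.5)
})

test_that("planted informative features are recovered in the top-50", {
  for (s in 1:10) {
    lf <- generate_labeled_features(labeled_feature_spec(
      n = 200, d = 1000, k_informative = 5, effect = 2, seed = s))
    top50 <- select_k(f_regression_rank(lf$X, lf$y), 50)$indices
    expect_gte(sum(lf$informative %in% top50), 4)
  }
})

test_that("feature_positions attributes selected features to grid slots", {
  enc <- mock_encoder(dim = 3)
  lay <- layout_map(enc)
  # all k features in one slot -> a single bar of height k
  one_slot <- lay$index[lay$chain == "light" & lay$slot == "L50"]
  fp <- feature_positions(one_slot, lay)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$count, length(one_slot))
  expect_equal(fp$slot, "L50")
  # counts always sum to the selection size
  set.seed(55)
  pick <- sample(lay$index, 40)
  expect_equal(sum(feature_positions(pick, lay)$count), 40)
  expect_error(feature_positions(10^6, lay), class = "ab_unknown_index")
})

test_that("planted signal maps back to the planted grid slot", {
  # build a tiny planted-slot world: encode pairs, then shift all channels of
  # one slot for the positive class and check attribution finds that slot
  enc <- mock_encoder(dim = 2, seed = 9)
  lay <- layout_map(enc)
  p <- pad_pair(fx_heavy_numbered(), fx_kappa_numbered(), "_")
  v <- as.numeric(encode_pair(p, enc))
  set.seed(56)
  n <- 40
  X <- matrix(rep(v, each = n), n) + matrix(rnorm(n * length(v), sd = 0.1), n)
  y <- rep(0:1, each = n / 2)
  target <- lay$index[lay$slot == "H35"]
  X[y == 1, target] <- X[y == 1, target] + 2
  top <- select_k(f_regression_rank(X, y), 10)
  fp <- feature_positions(top, lay)
  expect_equal(fp$slot[which.max(fp$count)], "H35")
})
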