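test_that("kernel matches its closed forms and is positive semidefinite", {
  set.seed(2)
  u <- rnorm(10); v <- rnorm(10)

  expect_equal(rbf_kernel(u, u, delta = 3), 1)
  # scaled unit distance: ||u-v||^2 = delta -> exp(-1)
  w <- u; w[1] <- u[1] + sqrt(2)
  expect_equal(rbf_kernel(u, w, delta = 2), exp(-1))

  # brute-force sum-of-squares oracle, both forms
  d2 <- 0
  for (i in seq_along(u)) d2 <- d2 + (u[i] - v[i])^2
  expect_equal(rbf_kernel(u, v, delta = 1.7), exp(-d2 / 1.7), tolerance = 1e-12)
  expect_equal(rbf_kernel(u, v, delta = 1.7, form = "literal"), d2 / 1.7,
               tolerance = 1e-12)
  expect_error(rbf_kernel(u, v[1:5], delta = 1), "length")

  # kernel matrix on random samples: symmetric PSD
  m <- matrix(rnorm(8 * 30), 8, 30)
  K <- rbf_kernel_matrix(m, delta = 4)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # agrees with the scalar kernel
  expect_equal(K[2, 7], rbf_kernel(m[, 2], m[, 7], delta = 4), tolerance = 1e-12)
})

make_blobs <- function(n_per, centers, sd = 0.15, seed = 1) {
  set.seed(seed)
  x <- do.call(cbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(2 * n_per, sd = sd), 2, n_per) + centers[i, ]
  }))
  list(x = x, y = rep(phase_levels[seq_len(nrow(centers))], each = n_per))
}

test_that("one-vs-rest SVM separates blobs deterministically", {
  blobs <- make_blobs(15, rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3)))
  model <- train_svm(blobs$x, blobs$y, svm_config(delta = 1))

  # separable training data is classified perfectly
  pred <- predict(model, blobs$x)
  expect_equal(as.character(pred), blobs$y)

  # every one-vs-rest decision is positive exactly for its own class
  dec <- attr(pred, "decision")
  for (cls in phase_levels) {
    expect_true(all(dec[blobs$y == cls, cls] > 0))
  }

  # determinism on held-out data
  held <- make_blobs(10, rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3)), seed = 9)$x
  p1 <- predict(train_svm(blobs$x, blobs$y, svm_config(delta = 1)), held)
  expect_identical(as.character(p1), as.character(predict(model, held)))

  # contract errors
  expect_error(train_svm(blobs$x, rep("interphase", ncol(blobs$x))), "two classes")
  expect_error(predict(model, blobs$x[1, , drop = FALSE]), "dimension")
  expect_error(predict(model, blobs$x[, 0, drop = FALSE]), "zero columns")
})

test_that("decision ties break toward the canonical class order", {
  dec <- rbind(c(0.5, 0.5, 0.1), c(0.2, 0.7, 0.7))
  got <- topocode:::choose_label(dec, c("interphase", "prophase", "metaphase"))
  expect_equal(got, c("interphase", "prophase"))
  # symmetric two-point construction: the midpoint of two mirrored classes
  x <- rbind(c(-1, -1, 1, 1), c(0, 0, 0, 0))
  y <- c("interphase", "interphase", "prophase", "prophase")
  model <- train_svm(x, y, svm_config(delta = 1))
  mid <- predict(model, matrix(c(0, 0), 2, 1))
  dec_mid <- attr(mid, "decision")
  expect_lt(abs(dec_mid[1, 1] - dec_mid[1, 2]), 1e-6)
  expect_equal(as.character(mid), "interphase")
})

test_that("confusion counts match hand enumeration", {
  # perfect prediction: no false calls
  y <- rep(phase_levels, times = c(3, 2, 3, 2))
  cc <- confusion(y, y, "prophase")
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(2, 8, 0, 0))

  # 10 samples, 3 positives all found, 2 negatives miscalled positive
  true <- c(rep("metaphase", 3), rep("interphase", 7))
  pred <- c(rep("metaphase", 5), rep("interphase", 5))
  cc2 <- confusion(true, pred, "metaphase")
  expect_equal(c(cc2$TP, cc2$FP, cc2$FN, cc2$TN), c(3, 2, 0, 5))
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 10)

  # positives absent from both: TP = FN = 0, sensitivity undefined
  cc3 <- confusion(true, pred, "anaphase")
  expect_equal(c(cc3$TP, cc3$FN), c(0, 0))
  expect_true(is.na(compute_metrics(cc3)$sensitivity))
  expect_match(compute_metrics(cc3)$undefined, "sensitivity")

  expect_error(confusion(true, pred[1:5], "metaphase"), "length")
})

test_that("metric formulas, identities and invariances hold", {
  m <- compute_metrics(tibble::tibble(class = "x", TP = 9, TN = 0, FP = 0, FN = 1))
  expect_equal(m$sensitivity, 0.9)

  # perfect classifier: every metric 1, error rate 0
  mp <- compute_metrics(tibble::tibble(class = "x", TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(mp[c("sensitivity", "specificity", "precision",
                           "f1", "accuracy")]), rep(1, 5), ignore_attr = TRUE)
  expect_equal(mp$error_rate, 0)

  # F1 fixed point at precision = sensitivity = 0.5
  mf <- compute_metrics(tibble::tibble(class = "x", TP = 1, TN = 0, FP = 1, FN = 1))
  expect_equal(mf$precision, 0.5)
  expect_equal(mf$sensitivity, 0.5)
  expect_equal(mf$f1, 0.5)

  set.seed(33)
  for (i in 1:20) {
    tp <- sample(0:20, 1); tn <- sample(0:20, 1)
    fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + tn + fp + fn == 0) next
    mm <- compute_metrics(tibble::tibble(class = "x", TP = tp, TN = tn,
                                         FP = fp, FN = fn))
    expect_equal(mm$error_rate, 1 - mm$accuracy)  # exact identity
    if (!is.na(mm$f1)) {
      expect_lte(mm$f1, max(mm$precision, mm$sensitivity) + 1e-12)
    }
  }

  # report is invariant to sample order and aggregates sensibly
  true <- sample(phase_levels, 40, replace = TRUE)
  pred <- ifelse(runif(40) < 0.8, true, sample(phase_levels, 40, replace = TRUE))
  rep1 <- metrics_report(true, pred)
  perm <- sample(40)
  rep2 <- metrics_report(true[perm], pred[perm])
  expect_equal(rep1, rep2)
  expect_equal(rep1$accuracy[rep1$class == "overall"], mean(true == pred))
  expect_s3_class(autoplot(rep1), "ggplot")
})
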