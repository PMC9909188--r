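test_that("ruleScore applies the latency and duration rules", {
  expect_equal(ruleScore(2.2, 2.0, TRUE, 10, 0.5), 2L)
  expect_equal(ruleScore(10, 0, FALSE, 10, 0.5), 0L)
  expect_equal(ruleScore(1.0, 0.2, TRUE, 10, 0.5), 0L)
  expect_error(ruleScore(1, 1, TRUE, latThreshold = 0))
})

test_that("with a vanishing duration rule the score reduces to the responded flag", {
  set.seed(30)
  for (i in 1:50) {
    pl <- randomPlantedSegment()
    f <- segmentFeatures(pl$segment)
    s <- ruleScore(f$latency_s, f$duration_s, f$responded,
                   latThreshold = 10, durThreshold = 1e-12)
    expect_equal(s == 2L, f$responded)
  }
})

test_that("fitStump matches its exhaustive-search oracle", {
  st <- fitStump(c(1, 2, 9, 10), c(0, 0, 1, 1))
  expect_equal(st$threshold, 5.5)
  expect_equal(st$direction, "above_is_positive")
  expect_equal(st$balanced_accuracy, 1)

  st2 <- fitStump(c(3, 3, 3, 7), c(0, 0, 0, 1))
  expect_equal(st2$threshold, 5)

  # no informative split: balanced accuracy 0.5, smallest threshold wins
  st3 <- fitStump(c(1, 1, 2, 2), c(0, 1, 0, 1))
  expect_equal(st3$balanced_accuracy, 0.5)
  expect_equal(st3$threshold, -Inf)

  expect_error(fitStump(c(1, 2), c(1, 1)), "degenerate")
  expect_error(fitStump(c(2, 2), c(0, 1)), "degenerate")

  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    values <- round(runif(n, 0, 10), sample(0:2, 1))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2 || length(unique(values)) < 2) next
    fit <- fitStump(values, labels)
    orc <- oracleStump(values, labels)
    expect_equal(fit$balanced_accuracy, orc$ba, tolerance = 1e-12)
    expect_equal(fit$threshold, orc$threshold)
    expect_equal(fit$direction, orc$direction)
  }
})

test_that("fitJointClassifier matches a brute-force tree oracle", {
  # linearly separable toy set: one split suffices
  x <- cbind(latency_evaluator = c(10, 10, 10, 10, 1, 2, 3, 1),
             latency_caregiver = c(10, 10, 9, 10, 2, 1, 2, 3))
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  fit <- fitJointClassifier(x, labels)
  expect_equal(fit$model$type, "split")
  expect_equal(fit$model$left$type, "leaf")
  expect_equal(fit$model$right$type, "leaf")
  expect_equal(predict(fit, x), labels)

  set.seed(77)
  for (i in 1:30) {
    n <- 8
    x <- matrix(round(runif(n * 4, 0, 10), 1), n, 4)
    labels <- c(TRUE, TRUE, rep(FALSE, 2), runif(n - 4) < 0.5)
    fit <- fitJointClassifier(x, labels)
    orc <- oracleTree(x, labels)
    expect_equal(unname(predict(fit, x)), unname(orc(x)))
  }

  # all-identical features: constant majority classifier
  xc <- matrix(5, 7, 4)
  fit2 <- fitJointClassifier(xc, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                   FALSE))
  expect_equal(fit2$model$type, "leaf")
  expect_true(all(predict(fit2, xc)))
  expect_error(fitJointClassifier(xc, rep(TRUE, 7)), "degenerate")
})

test_that("cross-validation is stratified, deterministic and order-invariant", {
  set.seed(9)
  n <- 123
  x <- matrix(runif(n * 4), n, 4)
  labels <- rep(c(TRUE, FALSE), length.out = n)
  ids <- sprintf("s%03d", 1:n)
  cv <- crossvalPredict(x, labels, ids = ids, k = 10, seed = 4)
  # fold sizes differ by at most one within each stratum
  for (str in c(TRUE, FALSE)) {
    sizes <- table(cv$fold[cv$label == str])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv2 <- crossvalPredict(x, labels, ids = ids, k = 10, seed = 4)
  expect_equal(cv, cv2)
  # shuffling subject order changes nothing per subject
  perm <- sample(n)
  cv3 <- crossvalPredict(x[perm, ], labels[perm], ids = ids[perm],
                         k = 10, seed = 4)
  expect_equal(cv3, cv)
  # a different seed may move folds but still predicts everyone once
  expect_setequal(crossvalPredict(x, labels, ids = ids, seed = 5)$subject_id,
                  ids)
  expect_error(crossvalPredict(x[1:5, ], labels[1:5], k = 10), "at least")
})

test_that("riskScore maps feature profiles to the unit interval", {
  w <- data.frame(latency_evaluator = c(10, 0.0001, 5),
                  latency_caregiver = c(10, 0.0001, NA),
                  duration_evaluator = c(0, 3, 1.5),
                  duration_caregiver = c(0, 4, NA))
  r <- riskScore(w)
  expect_equal(r[1], 1)
  expect_equal(r[2], 0, tolerance = 1e-4)
  expect_equal(r[3], 0.5)   # evaluator only: (0.5 + 0.5)/2
})

test_that("diagnose tabulates predictions against clinical labels", {
  perfect <- diagnose(rep(c(TRUE, FALSE), c(10, 10)),
                      rep(c(TRUE, FALSE), c(10, 10)))
  expect_equal(unlist(perfect[c("tp", "fn", "fp", "tn")]),
               c(tp = 10L, fn = 0L, fp = 0L, tn = 10L))
  expect_error(diagnose(c(TRUE, FALSE), TRUE), "length mismatch")

  # reconstruct the reference computer-rated outcome from raw vectors
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(48, 12, 19, 44))
  clin <- rep(c(TRUE, TRUE, FALSE, FALSE), c(48, 12, 19, 44))
  tab <- diagnose(pred, clin)
  ref <- referenceDiagnosisTable("computer")
  expect_equal(unlist(tab[c("tp", "fn", "fp", "tn")]),
               unlist(ref[c("tp", "fn", "fp", "tn")]))
  expect_equal(attr(tab, "total"), 123)
})
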