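test_that("confusion metrics reproduce the reference diagnostic accuracies", {
  m <- confusionMetrics(referenceDiagnosisTable("computer"))
  expect_equal(round(100 * m$sensitivity, 1), 80.0)
  expect_equal(round(100 * m$specificity, 1), 69.8)
  expect_equal(round(100 * m$accuracy, 1), 74.8)

  h <- confusionMetrics(referenceDiagnosisTable("human"))
  expect_equal(round(100 * h$sensitivity, 1), 83.3)
  expect_equal(round(100 * h$specificity, 1), 82.5)
  expect_equal(round(100 * h$accuracy, 1), 82.9)

  p <- confusionMetrics(diagnosisTable(10, 0, 0, 10))
  expect_equal(unlist(p), c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_error(confusionMetrics(diagnosisTable(0, 0, 3, 4)), "margin")
})

test_that("agreement rates pool to the published total consistency", {
  expect_equal(agreementRate(c(0, 2, 2, 1), c(0, 2, 2, 1)), 1)
  expect_equal(agreementRate(c(0, 2, 2, 2), c(0, 2, 2, 0)), 0.75)
  expect_error(agreementRate(1:3, 1:2), "equal")
  pooled <- pooledAgreement(c(0.95, 0.87, 1.00, 0.87, 0.90, 0.97),
                            c(61, 31, 33, 60, 31, 32))
  expect_equal(round(pooled, 2), 0.92)
})

test_that("Cronbach's alpha follows the variance-ratio formula", {
  expect_equal(cronbachAlpha(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  expect_equal(cronbachAlpha(cbind(1:4, 2:5)), 1)  # perfect covariation
  expect_error(cronbachAlpha(cbind(rep(1, 4), rep(2, 4))), "zero")
  set.seed(12)
  a <- cronbachAlpha(cbind(rnorm(10000), rnorm(10000)))
  expect_lt(abs(a), 0.05)   # independent raters carry no shared signal
})

test_that("Kruskal-Wallis H matches hand computation and base R", {
  kw <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(round(kw$H, 3), 4.571)  # rank sums 3, 7, 11
  expect_equal(kw$df, 2L)

  same <- kruskalWallis(list(rep(2, 4), rep(2, 3), rep(2, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # no ties: classical 12/(N(N+1)) sum R_g^2/n_g - 3(N+1) closed form
  set.seed(3)
  for (i in 1:10) {
    g <- lapply(sample(2:4, 3, replace = TRUE) + 2, function(n) runif(n))
    kw <- kruskalWallis(g)
    x <- unlist(g); r <- rank(x); N <- length(x)
    Rg <- tapply(r, rep(seq_along(g), lengths(g)), sum)
    ng <- lengths(g)
    Hc <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
    expect_equal(kw$H, unname(Hc), tolerance = 1e-12)
  }

  # heavy ties: agree with the independently implemented reference
  set.seed(4)
  for (i in 1:10) {
    g <- lapply(c(8, 10, 7), function(n) sample(1:4, n, replace = TRUE))
    if (length(unique(unlist(g))) < 2) next
    kw <- kruskalWallis(g)
    ref <- stats::kruskal.test(unlist(g),
                               factor(rep(seq_along(g), lengths(g))))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Dunn post-hoc z and Bonferroni caps behave as specified", {
  set.seed(5)
  a <- rnorm(12)
  d <- dunnPosthoc(list(A = a, B = a, C = a + 50))
  ab <- d[d$pair == "A-B", ]
  expect_lt(abs(ab$z), 1e-9)
  expect_equal(ab$p_adj, 1)

  sep <- dunnPosthoc(list(lo = 1:5, mid = 101:105, hi = 201:205))
  expect_lt(sep$p_adj[sep$pair == "lo-hi"],
            sep$p_adj[sep$pair == "lo-mid"] + 1e-12)
  expect_gt(abs(sep$z[sep$pair == "lo-hi"]),
            abs(sep$z[sep$pair == "lo-mid"]))

  # every adjusted p is capped at 1 and never below the raw p
  set.seed(6)
  g <- lapply(1:4, function(i) rnorm(6))
  d2 <- dunnPosthoc(g)
  expect_true(all(d2$p_adj <= 1))
  expect_true(all(d2$p_adj >= d2$p - 1e-12))
})

test_that("Mann-Whitney AUC equals brute-force pair counting", {
  expect_equal(aucMannWhitney(c(0.9, 0.8, 0.1, 0.2),
                              c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(aucMannWhitney(rep(0.5, 10),
                              rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(aucMannWhitney(c(3, 1, 2, 0),
                              c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(aucMannWhitney(1:4, rep(TRUE, 4)), "both classes")

  set.seed(8)
  for (i in 1:100) {
    np <- sample(2:10, 1); nn <- sample(2:10, 1)
    s <- c(round(runif(np), 1), round(runif(nn), 1))
    lab <- rep(c(TRUE, FALSE), c(np, nn))
    brute <- mean(outer(s[lab], s[!lab],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(aucMannWhitney(s, lab)$auc, brute, tolerance = 1e-12)
  }
})

test_that("AUC and its flipped-label complement sum to one", {
  set.seed(13)
  s <- runif(30); lab <- runif(30) < 0.4
  lab[1:2] <- c(TRUE, FALSE)
  expect_equal(aucMannWhitney(s, lab)$auc +
                 aucMannWhitney(s, !lab)$auc, 1, tolerance = 1e-12)
})

test_that("DeLong machinery agrees with the pROC reference", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.4)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  same <- delongTest(s, s, lab)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  set.seed(14)
  lab <- rep(c(TRUE, FALSE), each = 25)
  a <- rnorm(50) + lab; b <- rnorm(50) + 0.5 * lab
  # antisymmetry under swapping the two curves
  expect_equal(delongTest(a, b, lab)$Z, -delongTest(b, a, lab)$Z,
               tolerance = 1e-12)
  # invariance under strictly monotone transforms of both score vectors
  dt <- delongTest(a, b, lab)
  dt2 <- delongTest(exp(a), exp(b), lab)
  expect_equal(dt$Z, dt2$Z, tolerance = 1e-12)

  # cross-check SE, Z and p against pROC
  ra <- pROC::roc(lab, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lab, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(dt$Z), abs(unname(ref$statistic)), tolerance = 1e-9)
  expect_equal(dt$p, ref$p.value, tolerance = 1e-9)
  roc1 <- aucMannWhitney(a, lab)
  expect_equal(roc1$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(roc1$se, sqrt(pROC::var(ra, method = "delong")),
               tolerance = 1e-9)
})

test_that("Pearson chi-square matches the closed form and base R", {
  cmp <- pearsonChi2(rbind(c(92, 31), c(102, 21)))
  expect_equal(round(cmp$chi2, 2), 2.44)
  expect_equal(pearsonChi2(rbind(c(10, 10), c(10, 10)))$chi2, 0)

  set.seed(15)
  for (i in 1:20) {
    t <- matrix(sample(5:60, 4), 2, 2)
    a <- t[1, 1]; b <- t[1, 2]; c_ <- t[2, 1]; d <- t[2, 2]
    n <- sum(t)
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    got <- pearsonChi2(t)
    expect_equal(got$chi2, closed, tolerance = 1e-9)
    ref <- stats::chisq.test(t, correct = FALSE)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    refY <- stats::chisq.test(t, correct = TRUE)
    expect_equal(pearsonChi2(t, continuityCorrection = TRUE)$chi2,
                 unname(refY$statistic), tolerance = 1e-9)
  }
})

test_that("group comparison report is order-invariant and honest about ties", {
  co <- generateCohort(cohortDesign(seed = 21))
  f <- cohortFeatures(co)
  rep1 <- compareGroupsReport(f, "evaluator")
  expect_named(rep1, c("score", "latency", "duration"))
  expect_true(all(rep1$latency$pairwise$p_adj <= 1))

  perm <- f[sample(nrow(f)), ]
  rep2 <- compareGroupsReport(perm, "evaluator")
  expect_equal(rep1, rep2)

  # identical groups: every adjusted pairwise p is exactly 1
  ident <- data.frame(subject_id = sprintf("s%02d", 1:60),
                      group = rep(c("ASD", "DD", "TD"), each = 20),
                      procedure = "evaluator", responded = TRUE,
                      latency_s = rep(seq(0.5, 10, length.out = 20), 3),
                      duration_s = rep(seq(0.5, 4, length.out = 20), 3))
  rep3 <- compareGroupsReport(ident, "evaluator")
  expect_true(all(rep3$latency$pairwise$p_adj == 1))
  expect_equal(unname(rep3$latency$median),
               rep(median(seq(0.5, 10, length.out = 20)), 3))
})
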