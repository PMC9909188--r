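#' Rule-based machine score for a response
#'
#' Emits the ordinal response-to-name score on the machine scale {0, 2}:
#' 2 when the child responded with latency at most `latThreshold` and
#' sustained the face for at least `durThreshold` seconds, else 0. The
#' machine never emits the intermediate score 1 (head turn without eye
#' contact), which requires gaze information unavailable to this pipeline.
#'
#' @param latency latency in seconds (vectorized).
#' @param duration duration in seconds.
#' @param responded logical response flag.
#' @param latThreshold maximum latency for a positive response (s, > 0).
#' @param durThreshold minimum duration for a positive response (s, > 0).
#' @return Integer vector of scores in {0, 2}.
#' @examples
#' ruleScore(2.2, 2.0, TRUE)          # 2
#' ruleScore(10, 0, FALSE)            # 0
#' ruleScore(1.0, 0.2, TRUE)          # 0: too brief
#' @export
ruleScore <- function(latency, duration, responded, latThreshold = 10,
                      durThreshold = 0.5) {
  stopifnot(latThreshold > 0, durThreshold > 0)
  ifelse(responded & latency <= latThreshold & duration >= durThreshold,
         2L, 0L)
}

#' Machine scores for a long feature table
#'
#' @param features long table from [cohortFeatures()].
#' @inheritParams ruleScore
#' @return data.frame `subject_id`, `procedure`, `score`, `source`.
#' @export
machineScores <- function(features, latThreshold = 10, durThreshold = 0.5) {
  data.frame(subject_id = features$subject_id,
             procedure = features$procedure,
             score = ruleScore(features$latency_s, features$duration_s,
                               features$responded, latThreshold,
                               durThreshold),
             source = "machine", stringsAsFactors = FALSE)
}

#' Fit a decision stump by balanced accuracy
#'
#' Exhaustive threshold search over the midpoints of consecutive sorted
#' distinct values plus -Inf/+Inf sentinels, maximizing training balanced
#' accuracy. Ties break toward the `"above_is_positive"` direction and the
#' smallest threshold. `"above_is_positive"` predicts positive for
#' `value > threshold`; `"below_is_positive"` for `value <= threshold`.
#'
#' @param values numeric feature vector (>= 2 distinct values).
#' @param labels binary labels (0/1 or logical); both classes required.
#' @param directionSearch search both directions (default TRUE); when
#'   FALSE only `"above_is_positive"` is considered.
#' @return A list of class `"StumpRule"` with `threshold`, `direction` and
#'   `balanced_accuracy`.
#' @export
fitStump <- function(values, labels, directionSearch = TRUE) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(values) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("degenerate-rule error: only one class present")
  if (length(unique(values)) < 2L)
    stop("degenerate-rule error: fewer than 2 distinct values")
  sv <- sort(unique(values))
  thr <- c(-Inf, (sv[-length(sv)] + sv[-1]) / 2, Inf)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  directions <- if (directionSearch)
    c("above_is_positive", "below_is_positive") else "above_is_positive"
  best <- NULL
  for (dir in directions) {
    for (t in thr) {
      pred <- if (dir == "above_is_positive") values > t else values <= t
      ba <- (sum(pred & labels == 1L) / nPos +
             sum(!pred & labels == 0L) / nNeg) / 2
      if (is.null(best) || ba > best$balanced_accuracy + 1e-12)
        best <- list(threshold = t, direction = dir, balanced_accuracy = ba)
    }
  }
  structure(best, class = "StumpRule")
}

#' @export
print.StumpRule <- function(x, ...) {
  cat(sprintf("StumpRule: positive when value %s %.6g (balanced accuracy %.3f)\n",
              if (x$direction == "above_is_positive") ">" else "<=",
              x$threshold, x$balanced_accuracy))
  invisible(x)
}

#' @export
predict.StumpRule <- function(object, newdata, ...) {
  if (object$direction == "above_is_positive") newdata > object$threshold
  else newdata <= object$threshold
}

.gini <- function(labels) {
  if (!length(labels)) return(0)
  p <- mean(labels)
  1 - p^2 - (1 - p)^2
}

.bestSplit <- function(x, labels) {
  n <- length(labels)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    sv <- sort(unique(x[, j]))
    if (length(sv) < 2L) next
    thr <- (sv[-length(sv)] + sv[-1]) / 2
    for (t in thr) {
      left <- x[, j] <= t
      imp <- (sum(left) * .gini(labels[left]) +
              sum(!left) * .gini(labels[!left])) / n
      if (is.null(best) || imp < best$impurity - 1e-12)
        best <- list(feature = j, threshold = t, impurity = imp)
    }
  }
  best
}

.growTree <- function(x, labels, depth, maxDepth) {
  nPos <- sum(labels); nNeg <- sum(!labels)
  # majority label; exact ties resolve to the negative (non-ASD) class
  leaf <- list(type = "leaf", label = nPos > nNeg, n = length(labels),
               n_pos = nPos)
  if (depth >= maxDepth || nPos == 0L || nNeg == 0L) return(leaf)
  sp <- .bestSplit(x, labels)
  if (is.null(sp) || sp$impurity >= .gini(labels) - 1e-12) return(leaf)
  left <- x[, sp$feature] <= sp$threshold
  list(type = "split", feature = colnames(x)[sp$feature],
       feature_index = sp$feature, threshold = sp$threshold,
       left = .growTree(x[left, , drop = FALSE], labels[left],
                        depth + 1L, maxDepth),
       right = .growTree(x[!left, , drop = FALSE], labels[!left],
                         depth + 1L, maxDepth))
}

#' Fit the joint two-procedure ASD classifier
#'
#' A depth-at-most-2 axis-aligned decision tree over the four response
#' features (latency and duration for each of the two call procedures),
#' grown by exhaustive search: every (feature, midpoint-threshold) pair is
#' scored by weighted Gini impurity; ties break toward the earliest
#' feature column (latency features are ordered first by
#' [widenFeatures()]) and the smallest threshold; leaves carry the
#' training majority label. With `method = "or"` a transparent fallback is
#' fitted instead: one balanced-accuracy stump per feature, predicting ASD
#' when any stump votes positive.
#'
#' @param x numeric matrix or data.frame of features (columns in
#'   tie-break order).
#' @param labels logical (TRUE = ASD); both classes required.
#' @param maxDepth maximum tree depth (default 2).
#' @param method `"tree"` (default) or `"or"`.
#' @return Object of class `"JointClassifier"`.
#' @export
fitJointClassifier <- function(x, labels, maxDepth = 2L,
                               method = c("tree", "or")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels), all(is.finite(x)))
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("degenerate training set: need at least 2 subjects per class")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  model <- if (method == "tree")
    .growTree(x, labels, 0L, as.integer(maxDepth))
  else
    list(type = "or",
         stumps = lapply(seq_len(ncol(x)), function(j)
           tryCatch(fitStump(x[, j], labels), error = function(e) NULL)))
  structure(list(method = method, model = model, features = colnames(x)),
            class = "JointClassifier")
}

.predictNode <- function(node, x) {
  if (node$type == "leaf") return(rep(node$label, nrow(x)))
  out <- logical(nrow(x))
  left <- x[, node$feature_index] <= node$threshold
  out[left] <- .predictNode(node$left, x[left, , drop = FALSE])
  out[!left] <- .predictNode(node$right, x[!left, , drop = FALSE])
  out
}

#' @export
predict.JointClassifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (object$method == "tree") return(.predictNode(object$model, x))
  votes <- vapply(seq_along(object$model$stumps), function(j) {
    st <- object$model$stumps[[j]]
    if (is.null(st)) rep(FALSE, nrow(x)) else predict(st, x[, j])
  }, logical(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  rowSums(votes) > 0
}

#' @export
print.JointClassifier <- function(x, ...) {
  cat("JointClassifier (", x$method, ") over features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stratified k-fold cross-validated predictions
#'
#' Folds are stratified by label; the fold assignment is a deterministic
#' function of (subject ids, labels, seed) and therefore invariant to the
#' order in which subjects are supplied: subjects are canonically sorted
#' by id within each stratum before the seeded shuffle. Each subject is
#' predicted exactly once by a classifier trained without its fold.
#'
#' @param x feature matrix/data.frame (rows = subjects).
#' @param labels logical labels (TRUE = ASD).
#' @param ids subject identifiers (default row names or indices).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold shuffle (default 0).
#' @param method classifier method, see [fitJointClassifier()].
#' @param maxDepth tree depth, see [fitJointClassifier()].
#' @return data.frame `subject_id`, `fold`, `predicted`, `label`, ordered
#'   by the canonical (label, id) sort.
#' @export
crossvalPredict <- function(x, labels, ids = NULL, k = 10L, seed = 0L,
                            method = "tree", maxDepth = 2L) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  n <- nrow(x)
  stopifnot(n == length(labels))
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k subjects (n = ", n, ", k = ", k, ")")
  if (is.null(ids)) ids <- if (!is.null(rownames(x))) rownames(x) else
    as.character(seq_len(n))
  if (anyDuplicated(ids)) stop("subject ids must be unique")

  ord <- order(labels, ids)   # canonical order: stratum then id
  x <- x[ord, , drop = FALSE]; labels <- labels[ord]; ids <- ids[ord]
  fold <- integer(n)
  rng <- .seededRNG(seed)
  for (str in c(FALSE, TRUE)) {
    idx <- which(labels == str)
    fold[idx] <- .shuffle(rep_len(seq_len(k), length(idx)), rng)
  }
  pred <- logical(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fitJointClassifier(x[!test, , drop = FALSE], labels[!test],
                              maxDepth = maxDepth, method = method)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  data.frame(subject_id = ids, fold = fold, predicted = pred,
             label = labels, stringsAsFactors = FALSE)
}

# Private RNG handle so fold shuffles do not disturb the global stream.
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- NULL
  env$seed <- as.integer(seed)
  env
}

.shuffle <- function(x, rng) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(rng$state)) set.seed(rng$seed) else
    assign(".Random.seed", rng$state, envir = globalenv())
  out <- sample(x)
  rng$state <- get(".Random.seed", globalenv())
  out
}

#' Continuous ASD risk score from response features
#'
#' Mean over available procedures of
#' `(latency / 10 + (1 - min(duration, cap) / cap)) / 2`: 1 for a
#' double non-response, approaching 0 for an instant, sustained response.
#' Used as the continuous variable for ROC analysis.
#'
#' @param wide wide feature table from [widenFeatures()].
#' @param durationCap saturation cap for the duration term (s, default 3).
#' @return Numeric vector in `[0, 1]` along the rows of `wide`.
#' @export
riskScore <- function(wide, durationCap = 3) {
  per <- function(lat, dur)
    (lat / 10 + (1 - pmin(dur, durationCap) / durationCap)) / 2
  e <- per(wide$latency_evaluator, wide$duration_evaluator)
  c_ <- per(wide$latency_caregiver, wide$duration_caregiver)
  out <- rowMeans(cbind(e, c_), na.rm = TRUE)
  if (any(is.nan(out))) stop("risk score needs at least one procedure")
  out
}

#' 2x2 predicted-vs-clinical diagnosis table
#'
#' @param tp,fn,fp,tn non-negative counts (positive class = ASD).
#' @return Object of class `"DiagnosisTable"`.
#' @export
diagnosisTable <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), total = sum(counts), class = "DiagnosisTable")
}

#' Tabulate predictions against clinical labels
#'
#' @param predicted logical predictions (TRUE = ASD).
#' @param clinical logical clinical labels (TRUE = ASD).
#' @return A [diagnosisTable()].
#' @export
diagnose <- function(predicted, clinical) {
  if (length(predicted) != length(clinical))
    stop("length mismatch between predictions and labels")
  predicted <- as.logical(predicted); clinical <- as.logical(clinical)
  diagnosisTable(tp = sum(predicted & clinical),
                 fn = sum(!predicted & clinical),
                 fp = sum(predicted & !clinical),
                 tn = sum(!predicted & !clinical))
}

#' @export
print.DiagnosisTable <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("ASD", "non-ASD"),
                              clinical = c("ASD", "non-ASD")))
  print(m)
  invisible(x)
}
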