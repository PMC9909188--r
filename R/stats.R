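#' Sensitivity, specificity and accuracy from a diagnosis table
#'
#' @param table a [diagnosisTable()].
#' @return List with `sensitivity` = tp/(tp+fn), `specificity` =
#'   tn/(fp+tn), `accuracy` = (tp+tn)/total, all in `[0, 1]`.
#' @examples
#' confusionMetrics(diagnosisTable(48, 12, 19, 44))  # 0.800 / 0.698 / 0.748
#' @export
confusionMetrics <- function(table) {
  stopifnot(inherits(table, "DiagnosisTable"))
  if (table$tp + table$fn == 0 || table$fp + table$tn == 0)
    stop("undefined-metric error: empty clinical margin")
  list(sensitivity = table$tp / (table$tp + table$fn),
       specificity = table$tn / (table$fp + table$tn),
       accuracy = (table$tp + table$tn) / attr(table, "total"))
}

#' Exact agreement rate between two score vectors
#'
#' @param scoresA,scoresB equal-length vectors of ordinal scores.
#' @return Fraction of positions with equal values.
#' @export
agreementRate <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB) || length(scoresA) == 0L)
    stop("score vectors must have equal, positive length")
  mean(scoresA == scoresB)
}

#' Pool per-stratum agreement rates, weighting by stratum size
#'
#' @param rates per-stratum agreement rates.
#' @param ns per-stratum sample sizes.
#' @return The n-weighted mean rate.
#' @examples
#' pooledAgreement(c(0.95, 0.87, 1.00, 0.87, 0.90, 0.97),
#'                 c(61, 31, 33, 60, 31, 32))   # 0.92
#' @export
pooledAgreement <- function(rates, ns) {
  stopifnot(length(rates) == length(ns), all(ns > 0))
  sum(rates * ns) / sum(ns)
}

#' Cronbach's alpha over rater columns
#'
#' `alpha = k/(k-1) * (1 - sum(var_j) / var(total))` with `k` raters as
#' columns and items as rows.
#'
#' @param ratings numeric matrix, items x raters (>= 2 raters, >= 2
#'   items).
#' @return Alpha; errors when the total variance is zero.
#' @export
cronbachAlpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  k <- ncol(ratings)
  if (k < 2L || nrow(ratings) < 2L)
    stop("need at least 2 raters and 2 items")
  vtot <- stats::var(rowSums(ratings))
  if (vtot == 0) stop("undefined: zero total variance")
  k / (k - 1) * (1 - sum(apply(ratings, 2, stats::var)) / vtot)
}

#' Kruskal-Wallis rank test with ties correction
#'
#' H computed from pooled midranks as
#' `(N - 1) * sum(n_g (rbar_g - rbar)^2) / sum((r_i - rbar)^2)` (the
#' ties-corrected form; without ties it reduces to the classical
#' `12/(N(N+1)) sum(R_g^2/n_g) - 3(N+1)`), with the p-value from the
#' chi-square distribution on g - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return List with `H`, `p`, `df`.
#' @export
kruskalWallis <- function(groups) {
  groups <- groups[vapply(groups, length, 1L) > 0]
  g <- length(groups)
  if (g < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("need total n >= 3")
  r <- rank(x)
  gid <- rep(seq_len(g), vapply(groups, length, 1L))
  rbar <- mean(r)
  ssBetween <- sum(tapply(r, gid, function(z) length(z) * (mean(z) - rbar)^2))
  ssTotal <- sum((r - rbar)^2)
  if (ssTotal == 0) return(list(H = 0, p = 1, df = g - 1L))
  H <- (N - 1) * ssBetween / ssTotal
  list(H = H, p = stats::pchisq(H, df = g - 1L, lower.tail = FALSE),
       df = g - 1L)
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' For each pair of groups the standardized statistic
#' `z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' on pooled midranks, with ties correction `T = sum(t^3 - t)` over tie
#' groups; two-sided normal p-values are Bonferroni-adjusted by the number
#' of pairs and capped at 1.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame `pair`, `z`, `p`, `p_adj`.
#' @export
dunnPosthoc <- function(groups) {
  groups <- groups[vapply(groups, length, 1L) > 0]
  g <- length(groups)
  if (g < 2L) stop("need at least 2 non-empty groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(g))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  gid <- rep(seq_len(g), vapply(groups, length, 1L))
  rbar <- tapply(r, gid, mean)
  n <- tabulate(gid, g)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(names(groups)[i], names(groups)[j], sep = "-"),
               z = unname(z), p = p, p_adj = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.delongComponents <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' AUC by the Mann-Whitney U statistic with DeLong standard error
#'
#' AUC = U / (n_pos * n_neg) with half credit for ties; the standard error
#' comes from the DeLong structural-components decomposition.
#'
#' @param scores numeric risk scores (higher = more ASD-like).
#' @param labels logical labels (TRUE = positive class).
#' @return List of class `"RocResult"`: `auc`, `se`, `n_pos`, `n_neg`.
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  cm <- .delongComponents(scores, labels)
  s10 <- if (cm$m > 1) stats::var(cm$v10) else 0
  s01 <- if (cm$n > 1) stats::var(cm$v01) else 0
  structure(list(auc = cm$auc, se = sqrt(s10 / cm$m + s01 / cm$n),
                 n_pos = cm$m, n_neg = cm$n), class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("AUC = %.4f (SE %.4f; %d pos, %d neg)\n", x$auc, x$se,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two score vectors measured on the same
#' subjects: `Z = (AUC_a - AUC_b) / se(diff)` with the covariance of the
#' difference from the DeLong structural components, and a two-sided
#' normal p-value.
#'
#' @param scoresA,scoresB risk scores for the same subjects.
#' @param labels logical labels (TRUE = positive class).
#' @return List with `Z`, `p`, `auc_a`, `auc_b`, and `degenerate = TRUE`
#'   with Z = 0, p = 1 when the difference has zero variance (e.g.
#'   identical score vectors).
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  ca <- .delongComponents(scoresA, labels)
  cb <- .delongComponents(scoresB, labels)
  v10 <- cbind(ca$v10, cb$v10)
  v01 <- cbind(ca$v01, cb$v01)
  s10 <- stats::cov(v10); s01 <- stats::cov(v01)
  S <- s10 / ca$m + s01 / ca$n
  varDiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (varDiff <= 1e-15)
    return(list(Z = 0, p = 1, auc_a = ca$auc, auc_b = cb$auc,
                degenerate = TRUE))
  Z <- (ca$auc - cb$auc) / sqrt(varDiff)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), auc_a = ca$auc,
       auc_b = cb$auc, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' `sum((O - E)^2 / E)` over the four cells with df = 1; Yates continuity
#' correction only when requested (the method-accuracy comparison in this
#' pipeline is reported uncorrected).
#'
#' @param table 2x2 numeric matrix of counts.
#' @param continuityCorrection apply the Yates correction (default FALSE).
#' @return List with `chi2`, `p`, `df = 1`.
#' @export
pearsonChi2 <- function(table, continuityCorrection = FALSE) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  n <- sum(table)
  E <- outer(rowSums(table), colSums(table)) / n
  if (any(E == 0)) stop("zero margin: expected counts must be positive")
  d <- abs(table - E)
  if (continuityCorrection) d <- pmax(d - 0.5, 0)
  chi2 <- sum(d^2 / E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Group comparison report for the RTN indicators
#'
#' For each indicator (machine score, latency, duration) and one call
#' procedure: per-group median and IQR, the Kruskal-Wallis omnibus test,
#' and Dunn/Bonferroni pairwise post-hoc comparisons. Invariant to subject
#' ordering.
#'
#' @param features long feature table from [cohortFeatures()].
#' @param procedure "evaluator" or "caregiver".
#' @param latThreshold,durThreshold machine-score thresholds, see
#'   [ruleScore()].
#' @return Named list (one entry per indicator) with `median`, `iqr`,
#'   `kruskal_wallis`, `pairwise`.
#' @export
compareGroupsReport <- function(features, procedure = "evaluator",
                                latThreshold = 10, durThreshold = 0.5) {
  ff <- features[features$procedure == procedure, , drop = FALSE]
  if (!nrow(ff)) stop("no rows for procedure ", procedure)
  ff$score <- ruleScore(ff$latency_s, ff$duration_s, ff$responded,
                        latThreshold, durThreshold)
  present <- intersect(.GROUPS, unique(ff$group))
  if (length(present) < 2L) stop("need at least 2 non-empty groups")
  out <- lapply(c(score = "score", latency = "latency_s",
                  duration = "duration_s"), function(col) {
    groups <- lapply(present, function(gr) ff[ff$group == gr, col])
    names(groups) <- present
    list(median = vapply(groups, stats::median, 1),
         iqr = vapply(groups, stats::IQR, 1),
         kruskal_wallis = kruskalWallis(groups),
         pairwise = dunnPosthoc(groups))
  })
  out
}
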