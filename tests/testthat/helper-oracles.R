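# Independent brute-force oracles used by the scoring and acceptance tests.

# naive exhaustive stump search: explicit counting over every candidate
# threshold in both directions, same tie rules as the contract states
oracleStump <- function(values, labels) {
  sv <- sort(unique(values))
  cand <- c(-Inf, (sv[-length(sv)] + sv[-1]) / 2, Inf)
  best <- NULL
  for (dir in c("above_is_positive", "below_is_positive")) {
    for (t in cand) {
      tp <- 0; tn <- 0
      for (i in seq_along(values)) {
        pos <- if (dir == "above_is_positive") values[i] > t else values[i] <= t
        if (pos && labels[i] == 1) tp <- tp + 1
        if (!pos && labels[i] == 0) tn <- tn + 1
      }
      ba <- (tp / sum(labels == 1) + tn / sum(labels == 0)) / 2
      if (is.null(best) || ba > best$ba + 1e-12)
        best <- list(threshold = t, direction = dir, ba = ba)
    }
  }
  best
}

# brute-force depth-2 tree: plain nested loops, same Gini/tie contract
oracleTree <- function(x, labels) {
  gini <- function(l) if (!length(l)) 0 else {
    p <- mean(l); 1 - p^2 - (1 - p)^2
  }
  bestSplit <- function(x, l) {
    best <- NULL
    for (j in seq_len(ncol(x))) {
      sv <- sort(unique(x[, j]))
      if (length(sv) < 2) next
      for (t in (sv[-length(sv)] + sv[-1]) / 2) {
        left <- x[, j] <= t
        imp <- (sum(left) * gini(l[left]) + sum(!left) * gini(l[!left])) /
          length(l)
        if (is.null(best) || imp < best$imp - 1e-12)
          best <- list(j = j, t = t, imp = imp)
      }
    }
    best
  }
  grow <- function(x, l, d) {
    leaf <- list(leaf = TRUE, lab = sum(l) > sum(!l))
    if (d >= 2 || all(l) || !any(l)) return(leaf)
    sp <- bestSplit(x, l)
    if (is.null(sp) || sp$imp >= gini(l) - 1e-12) return(leaf)
    left <- x[, sp$j] <= sp$t
    list(leaf = FALSE, j = sp$j, t = sp$t,
         L = grow(x[left, , drop = FALSE], l[left], d + 1),
         R = grow(x[!left, , drop = FALSE], l[!left], d + 1))
  }
  root <- grow(x, labels, 0)
  pred1 <- function(nd, row) {
    while (!nd$leaf) nd <- if (row[nd$j] <= nd$t) nd$L else nd$R
    nd$lab
  }
  function(x) apply(x, 1, function(r) pred1(root, r))
}
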