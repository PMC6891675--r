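# Independent oracles, deliberately sharing no code with the package
# internals: plain-loop implementations used to cross-check the shipped
# algorithms.

# Brute-force greedy maximin selection (Kennard-Stone rule).
bruteForceKS <- function(m, k) {
  n <- nrow(m)
  d <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  best <- NULL
  bestD <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > bestD + 1e-12) {
      bestD <- d(i, j)
      best <- c(i, j)
    }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(1:n, sel)
    score <- vapply(cand, function(c0)
      min(vapply(sel, function(s0) d(c0, s0), 0)), 0)
    sel <- c(sel, cand[which(score > max(score) - 1e-12)[1]])
  }
  sel
}

# Normal-equations least-squares oracle (centered predictors).
olsFit <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  b <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))[, 1]
  list(b = b, fitted = mean(y) + (Xc %*% b)[, 1])
}

# Double-loop cross-validation oracle with PLS1 predictions computed via
# the Krylov-subspace characterization of PLS
# (b_A = K (K' X'X K)^-1 K' X'y, K = [s, Ms, ..., M^{A-1} s]) — a
# different algorithm from the shipped NIPALS.
krylovCVOracle <- function(X, y, lvMax, folds, scalerType = "autoscale") {
  n <- nrow(X)
  press <- numeric(lvMax)
  for (f in sort(unique(folds))) {
    out <- folds == f
    Xtr <- X[!out, , drop = FALSE]
    Xte <- X[out, , drop = FALSE]
    mu <- colMeans(Xtr)
    sds <- if (scalerType == "autoscale") apply(Xtr, 2, sd) else
      rep(1, ncol(Xtr))
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sds, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sds, "/")
    ytr <- y[!out]
    ym <- mean(ytr)
    ys <- sd(ytr)
    Xc <- scale(Xtr, scale = FALSE)
    xm <- attr(Xc, "scaled:center")
    yc <- (ytr - ym) / ys
    s <- crossprod(Xc, yc)
    M <- crossprod(Xc)
    K <- s
    for (A in seq_len(lvMax)) {
      if (A > 1) K <- cbind(K, M %*% K[, A - 1])
      b <- K %*% solve(crossprod(K, M %*% K), crossprod(K, s))
      pred <- ym + ys * (sweep(Xte, 2, xm) %*% b)[, 1]
      press[A] <- press[A] + sum((y[out] - pred)^2)
    }
  }
  sqrt(press / n)
}
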