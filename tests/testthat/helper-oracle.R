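# Independent oracles. These deliberately share no code with the package:
# the SVM oracle solves the dual as a generic QP (quadprog), the RFE oracle
# retrains from scratch at every elimination, and the t oracle is the
# textbook closed form.

# weight vector of the soft-margin linear SVM via the dual QP
qp_svm_weights <- function(X, y, C = 1, ridge = 1e-9) {
  n <- nrow(X)
  K <- X %*% t(X)
  Q <- (y %o% y) * K + diag(ridge, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  a <- quadprog::solve.QP(Q, rep(1, n), A, b0, meq = 1)$solution
  drop(t(X) %*% (a * y))
}

# from-scratch RFE: genes x samples matrix (pre-standardized if desired),
# 0/1 labels; returns probe ids best-first; same tie rule as the package
# (later gene in current order eliminated first)
oracle_rfe <- function(v, labels, C = 1) {
  y <- ifelse(labels == 1, 1, -1)
  act <- rownames(v)
  out <- character(0)
  while (length(act) > 0) {
    w <- qp_svm_weights(t(v[act, , drop = FALSE]), y, C)
    cr <- w^2
    i <- max(which(cr == min(cr)))
    out <- c(out, act[i])
    act <- act[-i]
  }
  rev(out)
}

# pooled two-sample t and two-sided p, straight from the textbook formula
oracle_pooled_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  t <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = t, p = 2 * pt(-abs(t), n1 + n0 - 2), df = n1 + n0 - 2)
}
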