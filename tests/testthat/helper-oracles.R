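# Independent brute-force oracles used to pin expected values.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments (doubled smaller tail, capped at 1).
enumMannWhitneyP <- function(ctrl, case) {
  n1 <- length(ctrl); n2 <- length(case)
  pooled <- c(ctrl, case)
  stopifnot(!anyDuplicated(pooled))
  uObs <- sum(outer(ctrl, case, ">"))
  sets <- utils::combn(n1 + n2, n1)
  uAll <- apply(sets, 2L, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  pLo <- mean(uAll <= uObs)
  pHi <- mean(uAll >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Step-up BH adjustment written directly from the definition.
stepUpBH <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (k in seq_along(ord)) {
    i <- ord[k]
    rank <- m - k + 1L
    running <- min(running, p[i] * m / rank)
    adj[i] <- min(running, 1)
  }
  adj
}

# Naive greedy mRMR (MID scheme) recomputing every correlation term from
# scratch at each step.
naiveMrmr <- function(x, yb, nSelect) {
  mi <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    r <- max(min(cor(a, b), 1 - 1e-12), -(1 - 1e-12))
    -0.5 * log(1 - r^2)
  }
  feats <- colnames(x)
  sel <- character(0)
  for (step in seq_len(nSelect)) {
    cand <- setdiff(feats, sel)
    crit <- sapply(cand, function(f) {
      rel <- mi(x[, f], yb)
      red <- if (length(sel)) mean(sapply(sel, function(s) mi(x[, f], x[, s]))) else 0
      rel - red
    })
    ord <- order(-crit, cand)
    sel <- c(sel, cand[ord[1]])
  }
  sel
}

# Unpenalized logistic regression via base glm (IRLS).
glmLogisticOracle <- function(x, yb) {
  df <- data.frame(y = yb, x)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  stats::coef(fit)
}
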