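# Independent oracles used across the suite. These deliberately use naive
# loop/enumeration implementations, not the package's code paths.

# AUC by exhaustive concordant-pair counting (ties weight 1/2).
auc_bruteforce <- function(values, labels, positive = "PPG") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n, n_a) group assignments (no ties assumed).
mwu_enum_p <- function(a, b) {
  z <- c(a, b)
  na <- length(a)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- ustat(a, b)
  us <- apply(utils::combn(length(z), na), 2, function(idx) {
    ustat(z[idx], z[-idx])
  })
  lo <- mean(us <= obs + 1e-12)
  hi <- mean(us >= obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# Loop transcription of the NormFinder-type variance decomposition:
# log2, remove per-sample candidate averages, per-group shrunken mean
# deviation plus group-mean standard error, averaged over groups.
normfinder_oracle <- function(v, groups) {
  y <- log2(v)
  I <- nrow(y)
  for (j in seq_len(ncol(y))) y[, j] <- y[, j] - mean(y[, j])
  groups <- factor(groups)
  gl <- levels(groups)
  m_all <- numeric(I)
  for (i in seq_len(I)) m_all[i] <- mean(y[i, ])
  stab <- matrix(0, I, length(gl))
  for (k in seq_along(gl)) {
    idx <- which(groups == gl[k])
    ng <- length(idx)
    d <- vg <- numeric(I)
    for (i in seq_len(I)) {
      d[i] <- mean(y[i, idx]) - m_all[i]
      vg[i] <- stats::var(y[i, idx])
    }
    gamma2 <- sum(d^2) / (I - 1) - mean(vg) / ng
    if (gamma2 < 0) gamma2 <- 0
    for (i in seq_len(I)) {
      ds <- if (gamma2 > 0) d[i] * gamma2 / (gamma2 + vg[i] / ng) else 0
      stab[i, k] <- abs(ds) + sqrt(vg[i] / ng)
    }
  }
  data.frame(protein_id = rownames(v), stability = rowMeans(stab),
             stringsAsFactors = FALSE)
}

# Unpenalized logistic log-likelihood at the ML optimum via Newton-Raphson.
logistic_ll_oracle <- function(X, y, maxit = 200) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    step <- solve(crossprod(X * w, X), crossprod(X, y - mu))
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  eta <- drop(X %*% beta)
  sum(y * eta - log(1 + exp(eta)))
}

# Small complete abundance matrix with named dims, log-normal entries.
random_abundance <- function(p, n, seed = NULL, stage = "corrected") {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(2^(stats::rnorm(p * n, 20, 1)), p, n,
              dimnames = list(sprintf("P%03d", seq_len(p)),
                              sprintf("S%02d", seq_len(n))))
  abundance_matrix(v, stage = stage)
}

two_groups <- function(n1 = 6, n2 = 6) {
  factor(rep(c("GPG", "PPG"), c(n1, n2)), levels = c("GPG", "PPG"))
}
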