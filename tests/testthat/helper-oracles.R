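# Independent oracle implementations used to cross-check the package.
# These re-derive each statistic from its textbook definition by a different
# route than the package code (naive loops, enumeration, augmented QR).

# Z-test: direct formula recomputation
oracle_ztest <- function(fc, substrates) {
  sub <- fc[names(fc) %in% substrates]
  z <- (mean(sub) - mean(fc)) * sqrt(length(sub)) / sd(fc)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# KS statistic by explicit double loop over candidate thresholds
oracle_ks_d <- function(x, y) {
  d <- 0
  for (t in c(x, y)) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# Asymptotic two-sided Kolmogorov tail, summed term by term
oracle_kolmogorov_p <- function(d, n1, n2) {
  t <- sqrt(n1 * n2 / (n1 + n2)) * d
  if (t <= 0) return(1)
  j <- 1:300
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

# Wilcoxon rank-sum, normal approximation with tie correction, no
# continuity correction
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nt <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  list(W = W, p = 2 * pnorm(-abs(z)))
}

# Enrichment statistic by the naive full running sum over every ranked
# position (the package only visits substrate positions)
oracle_es <- function(fc, substrates) {
  ord <- order(fc, decreasing = TRUE)
  w <- abs(fc)[ord]
  hit <- names(fc)[ord] %in% substrates
  k <- sum(hit); N <- length(fc)
  NR <- sum(w[hit])
  steps <- ifelse(hit, w / NR, if (N == k) 0 else -1 / (N - k))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

# Exhaustive permutation p: enumerate every substrate set of size k.
# Mathematically tied |ES| values (distinct sets sharing an extremum) are
# counted as extreme up to float noise, matching the package convention.
oracle_ksea_exhaustive_p <- function(fc, substrates) {
  es_obs <- oracle_es(fc, substrates)
  k <- sum(names(fc) %in% substrates)
  sets <- combn(length(fc), k)
  es_all <- apply(sets, 2, function(s) {
    oracle_es(fc, names(fc)[s])
  })
  sum(abs(es_all) >= abs(es_obs) - 1e-12) / ncol(sets)
}

# Exact two-sample KS p by enumerating every assignment of group labels
oracle_ks_exact_p <- function(x, y) {
  d_obs <- oracle_ks_d(x, y)
  pooled <- c(x, y)
  sets <- combn(length(pooled), length(x))
  d_all <- apply(sets, 2, function(s) oracle_ks_d(pooled[s], pooled[-s]))
  mean(d_all >= d_obs - 1e-12)
}

# Ridge regression by augmented least squares (QR route):
# argmin ||Y - X b||^2 + lambda ||b||^2 solved as lsfit on rbind(X, sqrt(l) I)
oracle_ridge <- function(X, y, lambda) {
  Xa <- rbind(X, sqrt(lambda) * diag(ncol(X)))
  ya <- c(y, rep(0, ncol(X)))
  qr.solve(Xa, ya)
}

# AUC as the Mann-Whitney pairwise-comparison probability
oracle_auc <- function(pos, neg) {
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + (p > n) + 0.5 * (p == n)
  }
  conc / (length(pos) * length(neg))
}

# MSS by a direct dot-product recomputation
oracle_mss <- function(pwm, window) {
  letters <- strsplit(window, "")[[1]]
  ab <- colnames(pwm$f)
  cur <- 0; lo <- 0; hi <- 0
  for (i in seq_along(letters)) {
    cur <- cur + pwm$info[i] * pwm$f[i, match(letters[i], ab)]
    lo <- lo + pwm$info[i] * min(pwm$f[i, ])
    hi <- hi + pwm$info[i] * max(pwm$f[i, ])
  }
  as.numeric((cur - lo) / (hi - lo))
}
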