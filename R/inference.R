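# Per-kinase, per-condition activity scoring: one-sample Z-test, two-sample
# KS and Wilcoxon tests, permutation-based enrichment (KSEA/GSEA-style), and
# ridge multiple linear regression. All p-value methods are summarized as a
# signed score: sign(mean substrate fold change) * (-log10 p).

INFERENCE_METHODS <- c("ztest", "ks", "wilcoxon", "gsea", "mlr",
                       "ztest_weighted", "gsea_weighted")

#' Extract one condition's fold-change vector
#'
#' Non-missing fold changes for a single condition, named by residue-free
#' site match keys so that regulons from a [ks_network()] can be joined
#' directly.
#'
#' @param m a [site_quant()] matrix
#' @param condition condition id (column name)
#' @return named numeric vector
#' @export
condition_fc <- function(m, condition) {
  stopifnot(inherits(m, "site_quant"))
  if (!condition %in% m$conditions) stop("unknown condition: ", condition,
                                         call. = FALSE)
  v <- m$values[, condition]
  keep <- !is.na(v)
  stats::setNames(v[keep], m$sites$match_key[keep])
}

score_row <- function(method, statistic, p_value, n_sub, mean_fc) {
  signed <- if (is.na(p_value)) statistic else {
    s <- sign(mean_fc)
    s * (-log10(p_value))
  }
  list(method = method, statistic = unname(statistic),
       p_value = unname(p_value), n_sub = n_sub,
       mean_fc = mean_fc, signed_score = unname(signed))
}

split_regulon <- function(fc, substrates) {
  is_sub <- names(fc) %in% substrates
  list(sub = fc[is_sub], bg = fc[!is_sub], is_sub = is_sub)
}

#' One-sample Z-test activity score
#'
#' Compares the mean fold change of a kinase's quantified substrates to the
#' mean and standard deviation of all fold changes in the condition:
#' `z = (m_S - m_P) * sqrt(n_S) / delta`, with a two-sided p-value from the
#' standard normal. The background includes the substrate sites themselves.
#'
#' @param fc named fold-change vector from [condition_fc()]
#' @param substrates character vector of regulon site keys
#' @return list with `method`, `statistic`, `p_value`, `n_sub`, `mean_fc`,
#'   `signed_score`, or `NULL` when no substrate is quantified
#' @export
activity_ztest <- function(fc, substrates) {
  sp <- split_regulon(fc, substrates)
  n_s <- length(sp$sub)
  if (n_s == 0) return(NULL)
  if (length(fc) < 2) stop("need at least two quantified sites", call. = FALSE)
  delta <- sd(fc)
  if (delta == 0) stop("degenerate background: zero variance", call. = FALSE)
  m_s <- mean(sp$sub)
  z <- (m_s - mean(fc)) * sqrt(n_s) / delta
  p <- min(1, 2 * pnorm(-abs(z)))
  score_row("ztest", z, p, n_s, m_s)
}

# Asymptotic two-sided two-sample Kolmogorov distribution:
# Q(t) = 2 * sum_{j>=1} (-1)^{j-1} exp(-2 j^2 t^2), summed to convergence.
kolmogorov_q <- function(t, tol = 1e-14) {
  if (t <= 0) return(1)
  total <- 0
  for (j in 1:1000) {
    term <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * t^2)
    total <- total + term
    if (abs(term) < tol) break
  }
  min(1, max(0, total))
}

#' Kolmogorov-Smirnov activity score
#'
#' Two-sample two-sided KS statistic between the substrate and non-substrate
#' fold-change distributions (maximum absolute ECDF difference). By default
#' the p-value is exact (`stats::psmirnov`) when the pooled values are free
#' of ties — the asymptotic Kolmogorov p is conservative at the small
#' substrate counts typical of kinase regulons — and falls back to the
#' asymptotic series otherwise.
#'
#' @inheritParams activity_ztest
#' @param exact force the exact (`TRUE`) or asymptotic (`FALSE`) p-value;
#'   `NULL` (default) selects exact when there are no ties
#' @export
activity_ks <- function(fc, substrates, exact = NULL) {
  sp <- split_regulon(fc, substrates)
  n1 <- length(sp$sub); n2 <- length(sp$bg)
  if (n1 == 0) return(NULL)
  if (n2 == 0) stop("no non-substrate background sites", call. = FALSE)
  pooled <- sort(c(sp$sub, sp$bg))
  cdf1 <- findInterval(pooled, sort(sp$sub)) / n1
  cdf2 <- findInterval(pooled, sort(sp$bg)) / n2
  d <- max(abs(cdf1 - cdf2))
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- !ties
  if (exact && ties) {
    warning("ties present: falling back to the asymptotic KS p-value",
            call. = FALSE)
    exact <- FALSE
  }
  p <- if (exact) {
    stats::psmirnov(d, sizes = c(n1, n2), two.sided = TRUE,
                    lower.tail = FALSE)
  } else {
    kolmogorov_q(sqrt(n1 * n2 / (n1 + n2)) * d)
  }
  score_row("ks", d, p, n1, mean(sp$sub))
}

#' Wilcoxon rank-sum activity score
#'
#' Two-sample rank-sum test between substrate and non-substrate fold
#' changes, normal approximation with tie correction and no continuity
#' correction (as in `stats::wilcox.test(exact = FALSE, correct = FALSE)`).
#'
#' @inheritParams activity_ztest
#' @export
activity_wilcoxon <- function(fc, substrates) {
  sp <- split_regulon(fc, substrates)
  if (length(sp$sub) == 0) return(NULL)
  if (length(sp$bg) == 0) stop("no non-substrate background sites", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(sp$sub, sp$bg, exact = FALSE, correct = FALSE)
  )
  score_row("wilcoxon", ht$statistic, ht$p.value, length(sp$sub), mean(sp$sub))
}

#' Permutation-based enrichment activity score (KSEA)
#'
#' Modified weighted Kolmogorov-Smirnov statistic: sites are ranked by fold
#' change (descending); the running sum gains `|fc|/N_R` at substrate
#' positions (`N_R` = sum of substrate `|fc|`) and loses `1/(N - n_S)`
#' elsewhere; the enrichment score ES is the signed extremum. Significance is
#' empirical: the observed |ES| is compared against `n_perm` random substrate
#' sets of the same size, `p = (1 + #{|ES_null| >= |ES_obs|}) / (1 + n_perm)`.
#' With `exhaustive = TRUE` (small instances) every substrate set of size
#' `n_S` is enumerated instead and `p = #{|ES_s| >= |ES_obs|} / C(N, n_S)`.
#'
#' @inheritParams activity_ztest
#' @param n_perm number of random substrate sets for the empirical null
#' @param seed optional integer seed for the permutation stream
#' @param exhaustive enumerate all substrate sets instead of sampling
#'   (requires `choose(N, n_S) <= exhaustive_limit`)
#' @param exhaustive_limit guard on the enumeration size
#' @export
activity_ksea <- function(fc, substrates, n_perm = 10000, seed = NULL,
                          exhaustive = FALSE, exhaustive_limit = 1e5) {
  ord <- order(fc, decreasing = TRUE)
  ranked_abs <- abs(fc)[ord]
  pos <- which(names(fc)[ord] %in% substrates)
  k <- length(pos)
  if (k == 0) return(NULL)
  if (sum(ranked_abs[pos]) == 0) {
    stop("degenerate substrate set: all substrate fold changes are zero",
         call. = FALSE)
  }
  es <- ksea_es_cpp(ranked_abs, pos)
  n <- length(fc)
  # distinct substrate sets can tie in |ES| exactly (e.g. sharing the same
  # pre-hit minimum); count ties as extreme regardless of float summation
  # order (genuinely distinct |ES| values differ by far more than 1e-12)
  eps <- 1e-12
  if (exhaustive) {
    if (choose(n, k) > exhaustive_limit) {
      stop("choose(N, n_S) exceeds exhaustive_limit", call. = FALSE)
    }
    sets <- combn(n, k)
    null_es <- apply(sets, 2, function(s) ksea_es_cpp(ranked_abs, s))
    p <- sum(abs(null_es) >= abs(es) - eps) / ncol(sets)
  } else {
    maybe_set_seed(seed)
    null_es <- ksea_null_cpp(ranked_abs, k, as.integer(n_perm))
    p <- (1 + sum(abs(null_es) >= abs(es) - eps)) / (1 + n_perm)
  }
  sub_mean <- mean(fc[names(fc) %in% substrates])
  out <- score_row("gsea", es, p, k, sub_mean)
  out
}

#' Ridge multiple linear regression activity scores
#'
#' Models the condition fold-change vector as `Y = X beta + psi`, where
#' `X[i, j] = 1` when site i is a known substrate of kinase j. Solved as
#' penalized least squares `argmin ||Y - X beta||^2 + lambda ||beta||^2`
#' (no intercept; the penalty is not scaled by the sample count). The fitted
#' `beta` coefficients are the activity scores; no p-value is produced. L2
#' regularization tempers the collinearity of kinases sharing substrates.
#'
#' @inheritParams activity_ztest
#' @param network a [ks_network()] (or a named list of regulons)
#' @param lambda ridge penalty, default 0.1
#' @return data.frame with one row per kinase that has at least one
#'   quantified substrate
#' @export
activity_mlr <- function(fc, network, lambda = 0.1) {
  regs <- if (inherits(network, "ks_network")) regulons(network) else network
  keys <- names(fc)
  X <- vapply(regs, function(r) as.numeric(keys %in% r), numeric(length(fc)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(fc))
  colnames(X) <- names(regs)
  n_sub <- colSums(X)
  X <- X[, n_sub > 0, drop = FALSE]
  if (ncol(X) == 0) stop("no kinase has a quantified substrate", call. = FALSE)
  A <- crossprod(X) + diag(lambda, ncol(X))
  beta <- drop(solve(A, crossprod(X, fc)))
  data.frame(
    kinase = colnames(X),
    method = "mlr",
    statistic = unname(beta),
    p_value = NA_real_,
    n_sub = unname(n_sub[n_sub > 0]),
    mean_fc = vapply(colnames(X), function(k) mean(fc[X[, k] == 1]), numeric(1)),
    signed_score = unname(beta),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Infer activity scores for all kinases and conditions
#'
#' Runs one inference method over every (kinase, condition) cell of a
#' normalized quantification matrix. The weighted variants (`ztest_weighted`,
#' `gsea_weighted`) multiply each kinase's quantified substrate fold changes
#' by their matrix similarity score before applying the base statistic;
#' non-substrate fold changes are left unaltered, and kinases absent from
#' `mss_values` are skipped.
#'
#' @param m normalized [site_quant()] matrix
#' @param network a [ks_network()]
#' @param method one of `"ztest"`, `"ks"`, `"wilcoxon"`, `"gsea"`, `"mlr"`,
#'   `"ztest_weighted"`, `"gsea_weighted"`
#' @param mss_values data.frame `(kinase, site, mss)` from [mss_table()];
#'   required for the weighted methods
#' @param n_perm permutations for the `gsea` empirical null
#' @param lambda ridge penalty for `mlr`
#' @param min_quantified drop scores with fewer quantified substrates
#' @param seed base seed; each (kinase, condition) permutation stream derives
#'   its own child seed
#' @return data.frame with columns `kinase`, `condition`, `method`,
#'   `statistic`, `p_value`, `n_sub`, `mean_fc`, `signed_score`
#' @export
infer_activities <- function(m, network, method = "ztest", mss_values = NULL,
                             n_perm = 10000, lambda = 0.1, min_quantified = 1,
                             seed = NULL) {
  stopifnot(inherits(m, "site_quant"))
  method <- match.arg(method, INFERENCE_METHODS)
  if (!m$normalized) {
    warning("matrix is not quantile-normalized", call. = FALSE)
  }
  regs <- regulons(network)
  weighted <- method %in% c("ztest_weighted", "gsea_weighted")
  if (weighted) {
    if (is.null(mss_values)) stop("weighted methods require mss_values",
                                  call. = FALSE)
    mss_by_kin <- split(mss_values, mss_values$kinase)
    regs <- regs[names(regs) %in% names(mss_by_kin)]
  }
  rows <- vector("list", length(m$conditions) * max(1L, length(regs)))
  n_rows <- 0L
  stream <- 0L
  for (cond in m$conditions) {
    fc <- condition_fc(m, cond)
    if (method == "mlr") {
      res <- activity_mlr(fc, regs, lambda = lambda)
      res$condition <- cond
      n_rows <- n_rows + 1L
      rows[[n_rows]] <- res[, c("kinase", "condition", "method", "statistic",
                                "p_value", "n_sub", "mean_fc", "signed_score")]
      next
    }
    for (kin in names(regs)) {
      stream <- stream + 1L
      reg <- regs[[kin]]
      fc_use <- fc
      if (weighted) {
        w <- mss_by_kin[[kin]]
        # substrates without an MSS (e.g. missing flank) leave the regulon
        reg <- intersect(reg, w$site)
        if (length(reg) == 0) next
        fc_use <- weight_fold_changes(fc, reg, stats::setNames(w$mss, w$site))
      }
      r <- switch(method,
        ztest = ,
        ztest_weighted = activity_ztest(fc_use, reg),
        ks = activity_ks(fc_use, reg),
        wilcoxon = activity_wilcoxon(fc_use, reg),
        gsea = ,
        gsea_weighted = activity_ksea(fc_use, reg, n_perm = n_perm,
                                      seed = child_seed(seed, stream))
      )
      if (is.null(r) || r$n_sub < min_quantified) next
      n_rows <- n_rows + 1L
      rows[[n_rows]] <- data.frame(
        kinase = kin, condition = cond, method = method,
        statistic = r$statistic, p_value = r$p_value, n_sub = r$n_sub,
        mean_fc = r$mean_fc, signed_score = r$signed_score,
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_rows == 0) stop("no (kinase, condition) cell produced a score",
                        call. = FALSE)
  out <- do.call(rbind, rows[seq_len(n_rows)])
  if (method == "mlr") out <- out[out$n_sub >= min_quantified, , drop = FALSE]
  out$method <- method
  rownames(out) <- NULL
  out
}

#' Write an activity score table as TSV
#' @param scores data.frame from [infer_activities()]
#' @param path output path
#' @export
write_activities <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
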