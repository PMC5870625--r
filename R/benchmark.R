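# ROC / precision-recall benchmarking of activity scores against a gold
# standard of expected kinase regulations, with negative-pair sampling.

#' Sample negative kinase-condition pairs
#'
#' Uniform sample, without replacement, from the Cartesian product of the
#' gold-standard kinases and conditions, excluding the positive pairs; the
#' sample has the same size as the positive set, so every evaluation is
#' balanced.
#'
#' @param gold data.frame with columns `kinase`, `condition` (and usually
#'   `direction`)
#' @param seed optional integer seed
#' @return data.frame `(kinase, condition)`
#' @export
generate_negatives <- function(gold, seed = NULL) {
  stopifnot(all(c("kinase", "condition") %in% names(gold)))
  if (anyDuplicated(gold[, c("kinase", "condition")])) {
    stop("gold standard contains duplicate (kinase, condition) pairs",
         call. = FALSE)
  }
  grid <- expand.grid(kinase = unique(gold$kinase),
                      condition = unique(gold$condition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(gold$kinase, gold$condition, sep = "\r")
  grid <- grid[!paste(grid$kinase, grid$condition, sep = "\r") %in% pos_key, ,
               drop = FALSE]
  if (nrow(grid) < nrow(gold)) {
    stop("not enough non-positive pairs to sample ", nrow(gold),
         " negatives (", nrow(grid), " available)", call. = FALSE)
  }
  maybe_set_seed(seed)
  out <- grid[sample.int(nrow(grid), nrow(gold)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

lookup_scores <- function(scores, pairs) {
  key <- paste(scores$kinase, scores$condition, sep = "\r")
  idx <- match(paste(pairs$kinase, pairs$condition, sep = "\r"), key)
  idx
}

#' Evaluate activity scores against labeled pairs
#'
#' The classifier score of a pair is the absolute signed activity score
#' (regulation in either direction counts). Pairs without a score (substrates
#' not quantified) are dropped from both sets and counted. The ROC curve is a
#' threshold sweep with tied scores grouped into single steps and trapezoidal
#' AUC, which makes the AUC equal the Mann-Whitney U convention (ties count
#' one half). Precision at recall 0.5 is the precision at the smallest
#' achieved recall >= 0.5; if that recall is never achieved the precision at
#' maximum recall is reported with `recall_05_achieved = FALSE`.
#'
#' @param scores data.frame from [infer_activities()]
#' @param positives data.frame `(kinase, condition[, direction])`
#' @param negatives data.frame `(kinase, condition)`
#' @return object of class `benchmark_eval`: list with `auc`,
#'   `precision_at_recall_05`, `roc_points`, `pr_points`, `n_pos`, `n_neg`,
#'   `n_dropped_pos`, `n_dropped_neg`, `direction_accuracy`
#' @export
evaluate_scores <- function(scores, positives, negatives) {
  ip <- lookup_scores(scores, positives)
  im <- lookup_scores(scores, negatives)
  drop_p <- sum(is.na(ip)); drop_n <- sum(is.na(im))
  ip <- ip[!is.na(ip)]; im <- im[!is.na(im)]
  if (length(ip) == 0) stop("no scored positive pairs", call. = FALSE)
  s_pos <- abs(scores$signed_score[ip])
  s_neg <- abs(scores$signed_score[im])
  n_pos <- length(s_pos); n_neg <- length(s_neg)

  s <- c(s_pos, s_neg)
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # group tied scores into one threshold block
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[block_end]
  fp <- cumsum(1L - y)[block_end]
  tpr <- tp / n_pos
  fpr <- if (n_neg > 0) fp / n_neg else rep(0, length(fp))
  roc <- cbind(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc[, "fpr"]) * (utils::head(roc[, "tpr"], -1) +
                                     roc[-1, "tpr"]) / 2)
  precision <- tp / (tp + fp)
  recall <- tpr
  pr <- cbind(recall = recall, precision = precision)
  hit <- which(recall >= 0.5)
  achieved <- length(hit) > 0
  p_at_r05 <- if (achieved) precision[hit[1]] else precision[length(precision)]

  dir_acc <- NA_real_
  if (!is.null(positives$direction)) {
    expect_sign <- ifelse(positives$direction[!is.na(lookup_scores(scores, positives))] == "up", 1, -1)
    obs_sign <- sign(scores$signed_score[ip])
    dir_acc <- mean(obs_sign == expect_sign)
  }
  structure(
    list(auc = auc, precision_at_recall_05 = p_at_r05,
         recall_05_achieved = achieved, roc_points = roc, pr_points = pr,
         n_pos = n_pos, n_neg = n_neg,
         n_dropped_pos = drop_p, n_dropped_neg = drop_n,
         direction_accuracy = dir_acc),
    class = "benchmark_eval"
  )
}

#' @export
print.benchmark_eval <- function(x, ...) {
  cat(sprintf("benchmark_eval: AUC %.3f, precision@recall0.5 %.3f (%d pos / %d neg, %d+%d unscored)\n",
              x$auc, x$precision_at_recall_05, x$n_pos, x$n_neg,
              x$n_dropped_pos, x$n_dropped_neg))
  invisible(x)
}

#' Run the benchmark over repeated negative-set randomizations
#'
#' Draws `n_randomizations` independent negative sets, evaluates each, and
#' summarizes with the median AUC and median precision at recall 0.5.
#'
#' @param scores data.frame from [infer_activities()]
#' @param gold data.frame `(kinase, condition, direction)`
#' @param n_randomizations number of negative sets (default 60)
#' @param seed base seed; randomization r uses a derived child seed
#' @param stratum optional label carried into the result
#' @return object of class `benchmark_result`: list with `results` (one
#'   `benchmark_eval` per randomization), `auc` and
#'   `precision_at_recall_05` vectors, `median_auc`,
#'   `median_precision_at_recall_05`, `stratum`
#' @export
run_benchmark <- function(scores, gold, n_randomizations = 60, seed = NULL,
                          stratum = "all") {
  results <- lapply(seq_len(n_randomizations), function(r) {
    neg <- generate_negatives(gold, seed = child_seed(seed, r))
    evaluate_scores(scores, gold, neg)
  })
  auc <- vapply(results, `[[`, numeric(1), "auc")
  prec <- vapply(results, `[[`, numeric(1), "precision_at_recall_05")
  structure(
    list(results = results, auc = auc, precision_at_recall_05 = prec,
         median_auc = median(auc),
         median_precision_at_recall_05 = median(prec),
         n_randomizations = n_randomizations, stratum = stratum),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result [%s]: median AUC %.3f, median precision@recall0.5 %.3f over %d randomizations\n",
              x$stratum, x$median_auc, x$median_precision_at_recall_05,
              x$n_randomizations))
  invisible(x)
}

#' Benchmark separately for kinases with few vs many quantified substrates
#'
#' Partitions the scored pairs at `cut` quantified substrates (the score
#' table's `n_sub`) and benchmarks both strata independently; predictions
#' based on few quantified substrates are expected to perform worse.
#'
#' @inheritParams run_benchmark
#' @param cut substrate-count threshold (default 5: strata `<=5` and `>5`)
#' @return named list of `benchmark_result` (`low`, `high`); a stratum with
#'   no scored positives is `NULL` with a warning
#' @export
stratify_by_substrate_count <- function(scores, gold, cut = 5,
                                        n_randomizations = 60, seed = NULL) {
  low_scores <- scores[scores$n_sub <= cut, , drop = FALSE]
  high_scores <- scores[scores$n_sub > cut, , drop = FALSE]
  run_stratum <- function(sc, label, child) {
    idx <- lookup_scores(sc, gold)
    g <- gold[!is.na(idx), , drop = FALSE]
    n_cells <- length(unique(g$kinase)) * length(unique(g$condition))
    if (nrow(g) == 0 || n_cells - nrow(g) < nrow(g)) {
      # too few pairs (or a grid saturated by positives) to sample negatives
      warning("empty stratum: ", label, call. = FALSE)
      return(NULL)
    }
    run_benchmark(sc, g, n_randomizations = n_randomizations,
                  seed = child, stratum = label)
  }
  list(
    low = run_stratum(low_scores, paste0("<=", cut), child_seed(seed, 1L)),
    high = run_stratum(high_scores, paste0(">", cut), child_seed(seed, 2L))
  )
}

#' Down-sample every regulon to a common size
#'
#' Repeatedly subsamples each kinase's substrate set, without replacement,
#' to `target_size`; kinases with fewer substrates are dropped. Used to
#' compare evidence classes on equal footing.
#'
#' @param network a [ks_network()]
#' @param target_size substrates per kinase after down-sampling
#' @param n_repeats number of subsampled networks (default 25)
#' @param seed base seed
#' @return list of `ks_network` objects
#' @export
downsample_substrates <- function(network, target_size, n_repeats = 25,
                                  seed = NULL) {
  stopifnot(inherits(network, "ks_network"), target_size >= 1)
  keys <- match_key(network$protein, network$position)
  lapply(seq_len(n_repeats), function(r) {
    maybe_set_seed(child_seed(seed, r))
    pieces <- lapply(unique(network$kinase), function(kin) {
      rows <- which(network$kinase == kin)
      usite <- unique(keys[rows])
      if (length(usite) < target_size) return(NULL)
      pick <- sample(usite, target_size)
      network[rows[match(pick, keys[rows])], , drop = FALSE]
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces) == 0) stop("no kinase reaches target_size=", target_size,
                                  call. = FALSE)
    ks_network(do.call(rbind, pieces))
  })
}

#' Load the shipped gold standard of expected kinase regulations
#'
#' A transcription of the curated table of human kinases expected to be up-
#' or down-regulated under specific perturbations (kinase inhibitors, growth
#' factor stimulations, cell-cycle and DNA-damage conditions), for use as an
#' example benchmark input. Columns: `kinase`, `condition`, `direction`.
#'
#' @return data.frame `(kinase, condition, direction)`
#' @export
load_gold_standard <- function() {
  path <- system.file("extdata", "gold_standard_table1.tsv",
                      package = "ksinfer", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
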