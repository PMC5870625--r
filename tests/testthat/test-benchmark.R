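# Negative sampling, ROC/PR evaluation and the benchmark harness.

toy_scores <- function(gold, pos_score, neg_score) {
  grid <- expand.grid(kinase = unique(gold$kinase),
                      condition = unique(gold$condition),
                      stringsAsFactors = FALSE)
  key <- paste(grid$kinase, grid$condition)
  pos <- key %in% paste(gold$kinase, gold$condition)
  data.frame(
    kinase = grid$kinase, condition = grid$condition, method = "toy",
    statistic = NA_real_, p_value = NA_real_, n_sub = 10L, mean_fc = 1,
    signed_score = ifelse(pos, pos_score, neg_score),
    stringsAsFactors = FALSE
  )
}

test_that("negative pairs are sampled uniformly from the non-positive grid", {
  gold <- data.frame(kinase = c("K1", "K1", "K2"),
                     condition = c("c1", "c2", "c3"),
                     direction = "up", stringsAsFactors = FALSE)
  # 2 kinases x 3 conditions, 3 positives -> negatives are the other 3 cells
  neg <- generate_negatives(gold, seed = 1)
  expect_equal(nrow(neg), 3)
  expect_false(any(paste(neg$kinase, neg$condition) %in%
                     paste(gold$kinase, gold$condition)))

  # positives covering the full grid cannot be matched
  full <- expand.grid(kinase = c("K1", "K2"), condition = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  full$direction <- "up"
  expect_error(generate_negatives(full, seed = 1), "not enough")

  # every eligible cell is hit with near-equal frequency
  gold2 <- data.frame(kinase = c("K1", "K2", "K3"),
                      condition = c("c1", "c2", "c3"),
                      direction = "up", stringsAsFactors = FALSE)
  counts <- new.env()
  set.seed(99)
  for (i in 1:1000) {
    n <- generate_negatives(gold2)
    for (k in paste(n$kinase, n$condition)) {
      prev <- if (is.null(counts[[k]])) 0 else counts[[k]]
      counts[[k]] <- prev + 1
    }
  }
  freq <- unlist(as.list(counts)) / 1000
  expect_equal(length(freq), 6) # 9 cells - 3 positives
  expect_true(all(abs(freq - 0.5) < 0.06)) # 3 draws over 6 cells
})

test_that("ROC/PR evaluation handles separation, ties, and drops unscored pairs", {
  gold <- data.frame(kinase = paste0("K", 1:5),
                     condition = paste0("c", 1:5),
                     direction = "up", stringsAsFactors = FALSE)
  scores <- toy_scores(gold, pos_score = 10, neg_score = 1)
  neg <- generate_negatives(gold, seed = 2)
  ev <- evaluate_scores(scores, gold, neg)
  expect_equal(ev$auc, 1)
  expect_equal(ev$precision_at_recall_05, 1)
  expect_equal(ev$roc_points[1, ], c(fpr = 0, tpr = 0))
  expect_equal(unname(ev$roc_points[nrow(ev$roc_points), ]), c(1, 1))

  # identical scores everywhere: AUC 0.5 by the tie convention
  tied <- toy_scores(gold, 3, 3)
  expect_equal(evaluate_scores(tied, gold, neg)$auc, 0.5)

  # unscored pairs are dropped and counted
  sc2 <- scores[-1, ]
  ev2 <- evaluate_scores(sc2, gold, neg)
  expect_equal(ev2$n_pos + ev2$n_dropped_pos, 5)

  # direction accuracy reflects the score signs
  sc3 <- toy_scores(gold, 10, 1)
  sc3$signed_score[1] <- -10 # one positive with the wrong sign
  ev3 <- evaluate_scores(sc3, gold, neg)
  expect_equal(ev3$direction_accuracy, 4 / 5)
})

test_that("AUC equals the Mann-Whitney pairwise probability on random instances", {
  set.seed(201)
  for (i in 1:25) {
    n_pos <- sample(3:12, 1); n_neg <- sample(3:12, 1)
    # discrete scores force ties across the two sets
    s_pos <- sample(1:5, n_pos, replace = TRUE) + rnorm(n_pos, 0, 0.01 * (i %% 2))
    s_neg <- sample(1:5, n_neg, replace = TRUE)
    gold <- data.frame(kinase = paste0("K", seq_len(n_pos)),
                       condition = "c1", direction = "up",
                       stringsAsFactors = FALSE)
    negp <- data.frame(kinase = paste0("N", seq_len(n_neg)), condition = "c1",
                       stringsAsFactors = FALSE)
    scores <- data.frame(
      kinase = c(gold$kinase, negp$kinase), condition = "c1", method = "toy",
      statistic = NA, p_value = NA, n_sub = 1, mean_fc = 1,
      signed_score = c(s_pos, s_neg), stringsAsFactors = FALSE
    )
    ev <- evaluate_scores(scores, gold, negp)
    expect_equal(ev$auc, oracle_auc(abs(s_pos), abs(s_neg)),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(202)
  s_pos <- rnorm(40, 1); s_neg <- rnorm(40)
  gold <- data.frame(kinase = paste0("K", 1:40), condition = "c1",
                     direction = "up", stringsAsFactors = FALSE)
  negp <- data.frame(kinase = paste0("N", 1:40), condition = "c1",
                     stringsAsFactors = FALSE)
  scores <- data.frame(kinase = c(gold$kinase, negp$kinase), condition = "c1",
                       method = "toy", statistic = NA, p_value = NA,
                       n_sub = 1, mean_fc = 1,
                       signed_score = c(s_pos, s_neg),
                       stringsAsFactors = FALSE)
  ev <- evaluate_scores(scores, gold, negp)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 40)),
    predictor = abs(c(s_pos, s_neg)), quiet = TRUE, direction = "<"
  ))
  expect_equal(ev$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("repeated randomizations are deterministic and summarized by medians", {
  gold <- data.frame(kinase = paste0("K", 1:8), condition = paste0("c", 1:8),
                     direction = "up", stringsAsFactors = FALSE)
  scores <- toy_scores(gold, 5, 1)
  b1 <- run_benchmark(scores, gold, n_randomizations = 10, seed = 7)
  b2 <- run_benchmark(scores, gold, n_randomizations = 10, seed = 7)
  expect_equal(b1$auc, b2$auc)
  expect_equal(b1$median_auc, median(b1$auc))
  expect_equal(length(b1$results), 10)
  b3 <- run_benchmark(scores, gold, n_randomizations = 1, seed = 7)
  expect_equal(length(b3$results), 1)
})

test_that("substrate-count stratification partitions pairs conservatively", {
  gold <- data.frame(kinase = paste0("K", 1:10), condition = paste0("c", 1:10),
                     direction = "up", stringsAsFactors = FALSE)
  scores <- toy_scores(gold, 6, 1)
  scores$n_sub <- rep(c(3L, 9L), length.out = nrow(scores))
  st <- stratify_by_substrate_count(scores, gold, cut = 5,
                                    n_randomizations = 5, seed = 3)
  n_low <- st$low$results[[1]]$n_pos + st$low$results[[1]]$n_dropped_pos
  n_high <- st$high$results[[1]]$n_pos + st$high$results[[1]]$n_dropped_pos
  expect_equal(n_low + n_high, 10)

  # all counts above the cut: the low stratum is empty, the high is everything
  scores$n_sub <- 9L
  expect_warning(st2 <- stratify_by_substrate_count(scores, gold, cut = 5,
                                                    n_randomizations = 5,
                                                    seed = 3),
                 "empty stratum")
  expect_null(st2$low)
  expect_equal(st2$high$results[[1]]$n_pos, 10)
})

test_that("down-sampling trims every retained regulon to the target size", {
  ds <- simulate_dataset(simulation_config(
    n_sites = 200, n_kinases = 5, regulon_size_range = c(4, 12),
    n_conditions = 2, seed = 51
  ))
  reps <- downsample_substrates(ds$network, target_size = 6, n_repeats = 4,
                                seed = 8)
  expect_equal(length(reps), 4)
  orig <- regulon_sizes(ds$network)
  for (r in reps) {
    sz <- regulon_sizes(r)
    expect_true(all(sz == 6))
    expect_equal(sort(names(sz)), sort(names(orig)[orig >= 6]))
  }
  # repeats with different sub-seeds differ
  expect_false(identical(as.data.frame(reps[[1]]), as.data.frame(reps[[2]])))
  # target equal to the current size is an identity up to ordering
  one <- downsample_substrates(toy_network(), target_size = 3, n_repeats = 1,
                               seed = 1)[[1]]
  expect_equal(sort(match_key(one$protein, one$position)),
               sort(match_key(toy_network()$protein,
                              toy_network()$position))[1:3])
})

test_that("the shipped gold standard loads with the expected shape", {
  gs <- load_gold_standard()
  expect_equal(names(gs), c("kinase", "condition", "direction"))
  expect_equal(length(unique(gs$kinase)), 30)
  expect_true(all(gs$direction %in% c("up", "down")))
  expect_false(anyDuplicated(gs[, c("kinase", "condition")]) > 0)
})
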