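test_that("confusion-table metrics match hand-computed values", {
  cases <- list(
    # tp tn fp fn ->        SN   FPR   SP   ACC      MCC  Prec    F1
    list(90, 40, 10, 10, c(0.9, 0.2, 0.8, 13 / 15, 0.7, 0.9, 0.9)),
    list(30, 70, 0, 0, c(1, 0, 1, 1, 1, 1, 1)),
    list(25, 25, 25, 25, c(0.5, 0.5, 0.5, 0.5, 0, 0.5, 0.5)),
    list(70, 20, 30, 30, c(0.7, 0.6, 0.4, 0.6, 0.1, 0.7, 0.7)),
    list(9, 1, 9, 1, c(0.9, 0.9, 0.1, 0.5, 0, 0.5, 9 / 14))
  )
  for (cs in cases) {
    m <- compute_metrics(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(unname(unlist(m)), cs[[5]], tolerance = 1e-12)
  }
})

test_that("zero denominators yield 0 and are flagged", {
  m <- compute_metrics(tp = 0, tn = 50, fp = 0, fn = 50)
  expect_equal(m$MCC, 0)
  expect_equal(m$Precision, 0)
  expect_true(all(c("MCC", "Precision", "F1") %in% attr(m, "flagged")))
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 1, 1, 1), "negative")
})

test_that("metrics agree with a brute-force recount from raw predictions", {
  set.seed(77)
  for (rep in 1:5) {
    truth <- sample(c("positive", "negative"), 200, replace = TRUE)
    pred <- sample(c("positive", "negative"), 200, replace = TRUE)
    m <- compute_metrics(tp = sum(pred == "positive" & truth == "positive"),
                         tn = sum(pred == "negative" & truth == "negative"),
                         fp = sum(pred == "positive" & truth == "negative"),
                         fn = sum(pred == "negative" & truth == "positive"))
    expect_equal(m$ACC, mean(pred == truth))
    expect_equal(m$SN, mean(pred[truth == "positive"] == "positive"))
    expect_equal(m$SP, mean(pred[truth == "negative"] == "negative"))
  }
})

test_that("ROC handles perfect, mixed and tied rankings", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.7, 0.6),
                         c("positive", "positive", "negative",
                           "negative"))$area, 1)
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1),
                         c("positive", "negative", "positive",
                           "negative"))$area, 0.75)
  expect_equal(roc_curve(rep(0.4, 10),
                         rep(c("positive", "negative"), 5))$area, 0.5)
  expect_error(roc_curve(c(0.1, 0.2), c("positive", "positive")),
               "both classes")
})

test_that("AUROC equals the concordant-pair statistic", {
  mann_whitney <- function(scores, labels) {
    pos <- scores[labels == "positive"]
    neg <- scores[labels == "negative"]
    total <- 0
    for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
    total / (length(pos) * length(neg))
  }
  set.seed(55)
  for (rep in 1:12) {
    n <- sample(20:60, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- sample(c("positive", "negative"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$area,
                 mann_whitney(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- runif(100)
  labels <- ifelse(runif(100) < plogis(4 * scores - 2), "positive",
                   "negative")
  ours <- roc_curve(scores, labels)$area
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                        levels = c("negative", "positive"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("PR curve covers perfect, baseline and enumerated mixed cases", {
  expect_equal(pr_curve(c(0.9, 0.8, 0.7, 0.6),
                        c("positive", "positive", "negative",
                          "negative"))$area, 1)
  # all scores tied: AUPR is the positive fraction
  labels <- c(rep("positive", 3), rep("negative", 7))
  expect_equal(pr_curve(rep(0.5, 10), labels)$area, 0.3)
  expect_error(pr_curve(c(0.1, 0.2), rep("negative", 2)), "positive")

  # 4-sample mixed case against an exhaustive threshold oracle
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labs <- c("positive", "negative", "positive", "negative")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    rec[i] <- sum(pred & labs == "positive") / sum(labs == "positive")
    prec[i] <- sum(pred & labs == "positive") / sum(pred)
  }
  oracle <- sum(diff(c(0, rec)) * (utils::head(c(prec[1], prec), -1) +
                                     prec) / 2)
  expect_equal(pr_curve(scores, labs)$area, oracle, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and aces separable data", {
  set.seed(8)
  n <- 200
  pos <- data.frame(drug = sprintf("p%03d", 1:n), side_effect = "s",
                    q_fingerprint = runif(n, 0.7, 1),
                    q_structure = runif(n, 0.7, 1),
                    q_atc = runif(n, 0.7, 1),
                    q_literature = runif(n, 0.7, 1),
                    q_target = runif(n, 0.7, 1), label = "positive")
  neg <- pos
  neg$drug <- sprintf("n%03d", 1:n)
  neg[, 3:7] <- neg[, 3:7] - 0.65
  neg$label <- "negative"
  feats <- rbind(pos, neg)
  cv <- crossvalidate(feats, classifier_spec("tree-ensemble", seed = 3L),
                      k = 5L, seed = 3L)
  expect_equal(cv$metrics$ACC, 1)
  expect_equal(cv$roc$area, 1)

  cv2 <- crossvalidate(feats, classifier_spec("tree-ensemble", seed = 3L),
                       k = 5L, seed = 3L)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$scores, cv2$scores)

  # folds are shared across classifier families for comparability
  cv_svm <- crossvalidate(feats, classifier_spec("max-margin", seed = 3L),
                          k = 5L, seed = 3L)
  expect_identical(cv$folds, cv_svm$folds)
  expect_gt(cv_svm$metrics$ACC, 0.95)
  cv_ann <- crossvalidate(feats, classifier_spec("feed-forward", seed = 3L),
                          k = 5L, seed = 3L)
  expect_gt(cv_ann$metrics$ACC, 0.95)
})

test_that("shuffled labels give near-zero MCC", {
  set.seed(14)
  n <- 2000
  feats <- data.frame(drug = sprintf("d%04d", 1:n), side_effect = "s",
                      q_fingerprint = runif(n), q_structure = runif(n),
                      q_atc = runif(n), q_literature = runif(n),
                      q_target = runif(n),
                      label = sample(rep(c("positive", "negative"), n / 2)))
  mccs <- vapply(1:5, function(r) {
    f <- feats
    f$label <- sample(f$label)
    crossvalidate(f, classifier_spec("tree-ensemble", seed = r),
                  k = 5L, seed = r)$metrics$MCC
  }, numeric(1))
  expect_true(all(abs(mccs) < 0.1))
})

test_that("cross-validation guards degenerate inputs", {
  feats <- data.frame(drug = c("a", "b"), side_effect = "s",
                      q_fingerprint = c(0, 1), q_structure = 0, q_atc = 0,
                      q_literature = 0, q_target = 0,
                      label = c("positive", "negative"))
  expect_error(crossvalidate(feats,
                             classifier_spec("tree-ensemble"), k = 5L),
               "fewer than k")
  feats$label <- "positive"
  expect_error(crossvalidate(feats, classifier_spec("tree-ensemble"),
                             k = 2L),
               "both classes")
})

test_that("balance experiment draws exact negative counts, reproducibly", {
  set.seed(9)
  mk <- function(prefix, n, lo, hi, label) {
    data.frame(drug = sprintf("%s%03d", prefix, 1:n), side_effect = "s",
               q_fingerprint = runif(n, lo, hi),
               q_structure = runif(n, lo, hi), q_atc = runif(n, lo, hi),
               q_literature = runif(n, lo, hi),
               q_target = runif(n, lo, hi), label = label)
  }
  pos <- mk("p", 60, 0.6, 1, "positive")
  neg <- mk("n", 200, 0, 0.4, "negative")
  spec <- classifier_spec("tree-ensemble", seed = 2L)
  bal <- balance_experiment(pos, neg, "balanced-1x", spec,
                            n_repeats = 2L, seed = 5L, k = 3L)
  expect_length(bal, 2L)
  expect_equal(sum(bal[[1]]$folds > 0), 120L)
  imb <- balance_experiment(pos, neg, "imbalanced-2x", spec,
                            n_repeats = 2L, seed = 5L, k = 3L)
  expect_equal(length(imb[[1]]$scores), 180L)
  all_mode <- balance_experiment(pos, neg, "all", spec, seed = 5L, k = 3L)
  expect_length(all_mode, 1L)
  expect_equal(length(all_mode[[1]]$scores), 260L)

  imb2 <- balance_experiment(pos, neg, "imbalanced-2x", spec,
                             n_repeats = 2L, seed = 5L, k = 3L)
  expect_equal(imb[[1]]$scores, imb2[[1]]$scores)
  expect_error(balance_experiment(pos, neg[1:50, ], "imbalanced-2x", spec),
               "insufficient")
})
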