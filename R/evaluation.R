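#' Binary classification metrics from a confusion table
#'
#' Computes Recall (= SN = TPR), FPR, Specificity, Accuracy, Matthews
#' correlation coefficient, Precision and F1 from TP/TN/FP/FN counts. Any
#' measure whose denominator is zero is set to 0 and listed in the
#' `"flagged"` attribute.
#'
#' @param tp,tn,fp,fn Non-negative counts; their total must be positive.
#' @return Named list (class `metric_set`) with elements `SN`, `FPR`, `SP`,
#'   `ACC`, `MCC`, `Precision`, `F1`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  flagged <- character()
  safe <- function(num, den, label) {
    if (den == 0) {
      flagged <<- c(flagged, label)
      return(0)
    }
    num / den
  }
  sn <- safe(tp, tp + fn, "SN")
  fpr <- safe(fp, fp + tn, "FPR")
  sp <- safe(tn, tn + fp, "SP")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  mcc_den <- sqrt((tn + fn) * (tn + fp) * (tp + fn) * (tp + fp))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  precision <- safe(tp, tp + fp, "Precision")
  f1 <- safe(2 * precision * sn, precision + sn, "F1")
  out <- list(SN = sn, FPR = fpr, SP = sp, ACC = acc, MCC = mcc,
              Precision = precision, F1 = f1)
  attr(out, "flagged") <- flagged
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.4f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

# Order by score descending and accumulate TP/FP at each distinct score
# threshold; shared backbone of the ROC and PR constructions.
.threshold_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- labels == "positive" | labels == TRUE | labels == 1
  P <- sum(y)
  N <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))
  list(tp = tp[last], fp = fp[last], threshold = s[last], P = P, N = N)
}

#' ROC curve and area
#'
#' True-positive rate against false-positive rate at every distinct score
#' threshold (descending), anchored at (0, 0) and (1, 1); tied scores move
#' along a single diagonal segment. Area by the trapezoid rule, which makes
#' AUROC equal to the concordant-pair (Mann-Whitney) statistic with ties
#' counted half.
#'
#' @param scores Numeric prediction scores, larger = more positive.
#' @param labels Labels; `"positive"`/`TRUE`/`1` marks the positive class.
#' @return List (class `curve`) with `points` (data frame `x` = FPR,
#'   `y` = TPR) and `area`.
#' @export
roc_curve <- function(scores, labels) {
  pts <- .threshold_points(scores, labels)
  if (pts$P == 0L || pts$N == 0L) {
    stop("ROC requires both classes present")
  }
  x <- c(0, pts$fp / pts$N)
  y <- c(0, pts$tp / pts$P)
  area <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  structure(list(points = data.frame(x = x, y = y), area = area,
                 kind = "ROC"), class = "curve")
}

#' Precision-recall curve and area
#'
#' Precision against recall at every distinct score threshold (descending),
#' anchored at recall 0 with the precision of the strictest threshold. Area
#' by the trapezoid rule over recall by default; `method = "step"` gives
#' average precision instead.
#'
#' @inheritParams roc_curve
#' @param method `"trapezoid"` (default) or `"step"` (average precision).
#' @return List (class `curve`) with `points` (data frame `x` = recall,
#'   `y` = precision) and `area`.
#' @export
pr_curve <- function(scores, labels, method = c("trapezoid", "step")) {
  method <- match.arg(method)
  pts <- .threshold_points(scores, labels)
  if (pts$P == 0L) stop("PR requires at least one positive")
  recall <- pts$tp / pts$P
  precision <- ifelse(pts$tp + pts$fp > 0, pts$tp / (pts$tp + pts$fp), 1)
  x <- c(0, recall)
  y <- c(precision[1L], precision)
  area <- if (method == "trapezoid") {
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  } else {
    sum(diff(x) * utils::tail(y, -1L))
  }
  structure(list(points = data.frame(x = x, y = y), area = area,
                 kind = "PR"), class = "curve")
}

#' @export
print.curve <- function(x, ...) {
  cat(x$kind, " curve: ", nrow(x$points), " points, area ",
      sprintf("%.4f", x$area), "\n", sep = "")
  invisible(x)
}

#' Specify a classifier
#'
#' Families map to host engines: `tree-ensemble` -> [ranger::ranger()]
#' probability forest, `max-margin` -> [e1071::svm()] with probability
#' estimates, `feed-forward` -> [nnet::nnet()] single-hidden-layer
#' perceptron. Engine defaults are used except where the engine has no
#' default (the perceptron's hidden-layer size, set to 5).
#'
#' @param family One of `"tree-ensemble"`, `"max-margin"`, `"feed-forward"`.
#' @param params Named list of engine arguments overriding defaults.
#' @param seed Integer seed controlling engine randomness.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("tree-ensemble", "max-margin",
                                       "feed-forward"),
                            params = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

.feature_columns <- function(features) {
  grep("^q_", names(features), value = TRUE)
}

# Fit on labeled feature vectors; return a closure scoring new data in [0,1].
.fit_scorer <- function(spec, train, fold_seed) {
  cols <- .feature_columns(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  y <- factor(train$label, levels = c("negative", "positive"))
  if (spec$family == "tree-ensemble") {
    args <- c(list(x = x, y = y, probability = TRUE,
                   num.threads = 1L, seed = fold_seed), spec$params)
    fit <- do.call(ranger::ranger, args)
    function(newdata) {
      nd <- as.matrix(newdata[, cols, drop = FALSE])
      stats::predict(fit, data = nd, num.threads = 1L)$predictions[, "positive"]
    }
  } else if (spec$family == "max-margin") {
    set.seed(fold_seed)
    args <- c(list(x = x, y = y, probability = TRUE), spec$params)
    fit <- do.call(e1071::svm, args)
    function(newdata) {
      nd <- as.matrix(newdata[, cols, drop = FALSE])
      pred <- stats::predict(fit, nd, probability = TRUE)
      attr(pred, "probabilities")[, "positive"]
    }
  } else {
    set.seed(fold_seed)
    defaults <- list(size = 5L, maxit = 200L, decay = 1e-3, trace = FALSE)
    args <- utils::modifyList(defaults, spec$params)
    fit <- do.call(nnet::nnet, c(list(x = x, y = as.numeric(y) - 1), args))
    function(newdata) {
      nd <- as.matrix(newdata[, cols, drop = FALSE])
      as.numeric(stats::predict(fit, nd))
    }
  }
}

# Stratified fold assignment; errors when a class cannot cover every fold.
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop("class '", cls, "' has ", length(idx),
           " samples, fewer than k = ", k, " folds; cannot stratify")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by label and fixed by `seed`, so the assignment is
#' identical across classifier families for a given dataset. Out-of-fold
#' scores are pooled; point metrics use a 0.5 score cutoff.
#'
#' @param features Feature data frame from [featurize()] (columns `q_*` and
#'   `label`).
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and per-fold engine seeds.
#' @param threshold Score cutoff for the point metrics (default 0.5).
#' @return List with `metrics` (a `metric_set`), `roc`, `pr` (curves),
#'   `scores` (pooled out-of-fold scores), `folds` (assignment).
#' @export
crossvalidate <- function(features, spec, k = 10L, seed = 1L,
                          threshold = 0.5) {
  stopifnot(k >= 2L)
  labels <- features$label
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  fold <- .stratified_folds(labels, k, seed)
  scores <- numeric(nrow(features))
  for (f in seq_len(k)) {
    train <- features[fold != f, , drop = FALSE]
    if (length(unique(train$label)) < 2L) {
      stop("training fold ", f, " lost a class; re-stratify")
    }
    scorer <- .fit_scorer(spec, train, fold_seed = spec$seed + f)
    scores[fold == f] <- scorer(features[fold == f, , drop = FALSE])
  }
  y_pos <- labels == "positive"
  pred_pos <- scores >= threshold
  metrics <- compute_metrics(tp = sum(pred_pos & y_pos),
                             tn = sum(!pred_pos & !y_pos),
                             fp = sum(pred_pos & !y_pos),
                             fn = sum(!pred_pos & y_pos))
  list(metrics = metrics,
       roc = roc_curve(scores, labels),
       pr = pr_curve(scores, labels),
       scores = scores, folds = fold)
}

#' Balanced / imbalanced negative-subsampling experiment
#'
#' Repeats cross-validation on datasets built from all positives plus a
#' negative draw: mode `"all"` uses every negative once; `"balanced-1x"`
#' draws as many negatives as positives; `"imbalanced-2x"` draws twice as
#' many, each repeat an independent draw without replacement.
#'
#' @param positives,negatives Feature data frames (labels already set).
#' @param mode One of `"all"`, `"imbalanced-2x"`, `"balanced-1x"`.
#' @param spec A [classifier_spec()].
#' @param n_repeats Number of independent draws (default 5; ignored for
#'   `"all"`).
#' @param seed Integer seed.
#' @param k Folds per cross-validation.
#' @return List of per-repeat [crossvalidate()] results.
#' @export
balance_experiment <- function(positives, negatives,
                               mode = c("all", "imbalanced-2x", "balanced-1x"),
                               spec = classifier_spec(), n_repeats = 5L,
                               seed = 1L, k = 10L) {
  mode <- match.arg(mode)
  n_pos <- nrow(positives)
  n_need <- switch(mode, all = nrow(negatives), `imbalanced-2x` = 2L * n_pos,
                   `balanced-1x` = n_pos)
  if (nrow(negatives) < n_need) {
    stop("insufficient negatives: need ", n_need, ", have ", nrow(negatives))
  }
  if (mode == "all") n_repeats <- 1L
  lapply(seq_len(n_repeats), function(r) {
    if (mode == "all") {
      neg <- negatives
    } else {
      set.seed(seed + r)
      neg <- negatives[sample.int(nrow(negatives), n_need), , drop = FALSE]
    }
    crossvalidate(rbind(positives, neg), spec, k = k, seed = seed + r)
  })
}
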