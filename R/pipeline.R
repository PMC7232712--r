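#' Pipeline configuration
#'
#' Defaults follow the method's stated constants: restart probability 0.8,
#' convergence tolerance 1e-6, the nine-value threshold grid, tenfold
#' cross-validation. Passing `eps_grid = "auto"` derives a five-point
#' quantile grid from the observed probabilities instead
#' (see [probability_grid()]), which is the sensible choice on synthetic
#' worlds whose probability scale differs from the real network's.
#'
#' @param interactions,pairs Optional input paths (TSV); when `NULL` a
#'   synthetic world is generated from `world`.
#' @param channels Optional named list of five similarity-matrix paths
#'   (ignored for synthetic worlds, which carry their own channels).
#' @param world A [world_config()] used when simulating.
#' @param out_dir Optional directory for intermediate artifacts (TSV).
#' @param lam,theta Walk parameters.
#' @param eps_grid Numeric threshold grid, or `"auto"`.
#' @param folds Cross-validation folds.
#' @param model Classifier family (see [classifier_spec()]).
#' @param sweep Cross-validate at every grid threshold (`TRUE`) or only at
#'   the smallest (`FALSE`, default — the recommended operating point).
#' @param compare_random Also evaluate a random-negative baseline with the
#'   same number of negatives? Default TRUE.
#' @param seed Global seed; per-stage seeds are derived at fixed offsets.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions = NULL, pairs = NULL,
                            channels = NULL, world = world_config(),
                            out_dir = NULL, lam = 0.8, theta = 1e-6,
                            eps_grid = default_threshold_grid(),
                            folds = 10L, model = "tree-ensemble",
                            sweep = FALSE, compare_random = TRUE,
                            seed = 1L) {
  structure(list(interactions = interactions, pairs = pairs,
                 channels = channels, world = world, out_dir = out_dir,
                 lam = lam, theta = theta, eps_grid = eps_grid,
                 folds = as.integer(folds), model = model, sweep = sweep,
                 compare_random = compare_random, seed = as.integer(seed)),
            class = "pipeline_config")
}

# labeled feature table for positives plus one negative pair set
.features_for <- function(positives, negative_pairs, channels, index) {
  pos <- positives
  pos$label <- rep("positive", nrow(pos))
  neg <- negative_pairs[, c("drug", "side_effect"), drop = FALSE]
  neg$label <- rep("negative", nrow(neg))
  featurize(rbind(pos[, c("drug", "side_effect", "label")], neg),
            channels, index)
}

#' Run the full pipeline
#'
#' Stages: simulate (or read inputs) -> build network -> walk profiles ->
#' negative selection over the threshold grid -> FIRE comparator ->
#' feature construction -> cross-validated evaluation -> random-negative
#' comparison. Returns a machine-readable report; identical seeds give
#' identical reports.
#'
#' @param config A [pipeline_config()].
#' @return List (class `pipeline_report`) with per-stage results: world and
#'   network summaries, per-threshold negative counts (and purity when
#'   ground truth is available), FIRE overlap, evaluation metrics and curve
#'   areas, and the random-negative comparison.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  simulated <- is.null(config$interactions)
  if (simulated) {
    wc <- config$world
    wc$seed <- config$seed
    world <- generate_world(wc)
    records <- world$records
    positives <- world$pairs
    channels <- world$channels
    drugs <- world$drugs
  } else {
    if (!file.exists(config$interactions)) {
      stop("stage read-interactions: file not found: ", config$interactions)
    }
    if (is.null(config$pairs) || !file.exists(config$pairs)) {
      stop("stage read-pairs: pair table missing")
    }
    world <- NULL
    records <- read_interaction_table(config$interactions)
    positives <- read_pair_table(config$pairs)
    drugs <- sort(unique(c(records$drug_a, records$drug_b, positives$drug)))
    if (is.null(config$channels)) {
      stop("stage read-channels: similarity channel paths required for ",
           "real inputs")
    }
    channels <- lapply(config$channels, read_similarity_matrix,
                       drug_universe = drugs)
  }

  index <- build_index(positives)
  network <- build_network(records, drugs)
  profiles <- rwr_profiles(network, index, lam = config$lam,
                           theta = config$theta)

  grid <- config$eps_grid
  if (identical(grid, "auto")) grid <- probability_grid(profiles, index)

  nds_list <- lapply(grid, function(eps) {
    build_nds(network, index, eps, profiles = profiles)
  })
  counts <- vapply(nds_list, nrow, integer(1))
  purity <- if (!is.null(world)) {
    vapply(nds_list, function(nds) {
      world_truth_report(world, nds)$purity
    }, numeric(1))
  } else NULL

  fire <- fire_select(network, index, positives)
  nds0 <- nds_list[[1L]]
  nds0_key <- paste(nds0$drug, nds0$side_effect, sep = "\r")
  fire_key <- paste(fire$drug, fire$side_effect, sep = "\r")
  containment <- if (nrow(nds0) > 0L) mean(nds0_key %in% fire_key) else 1

  spec <- classifier_spec(config$model, seed = config$seed + 101L)
  eval_eps <- if (config$sweep) seq_along(grid) else 1L
  eval_eps <- eval_eps[counts[eval_eps] > 0L]  # empty sets cannot be trained on
  evaluations <- lapply(eval_eps, function(i) {
    feats <- .features_for(positives, nds_list[[i]], channels, index)
    cv <- crossvalidate(feats, spec, k = config$folds,
                        seed = config$seed + 211L)
    list(eps = unname(grid[i]), n_negatives = nrow(nds_list[[i]]),
         metrics = unclass(cv$metrics), auroc = cv$roc$area,
         aupr = cv$pr$area)
  })

  comparison <- NULL
  if (isTRUE(config$compare_random) && nrow(nds0) > 0L &&
      length(evaluations) > 0L) {
    rnd <- random_negative_pairs(drugs, names(index), positives,
                                 n = nrow(nds0), seed = config$seed + 307L)
    feats_rnd <- .features_for(positives, rnd, channels, index)
    cv_rnd <- crossvalidate(feats_rnd, spec, k = config$folds,
                            seed = config$seed + 211L)
    comparison <- list(selected_mcc = evaluations[[1L]]$metrics$MCC,
                       random_mcc = cv_rnd$metrics$MCC,
                       random_auroc = cv_rnd$roc$area)
  }

  report <- list(
    seed = config$seed,
    simulated = simulated,
    n_drugs = length(drugs),
    n_side_effects = length(index),
    n_positive_pairs = nrow(positives),
    n_edges = Matrix::nnzero(network$adjacency) / 2,
    eps_grid = unname(as.numeric(grid)),
    nds_counts = unname(counts),
    nds_purity = if (is.null(purity)) NULL else unname(purity),
    fire_count = nrow(fire),
    fire_containment_of_eps0 = containment,
    evaluations = evaluations,
    random_comparison = comparison
  )
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_interaction_table(records,
                            file.path(config$out_dir, "interactions.tsv"))
    write_pair_table(positives, file.path(config$out_dir, "pairs.tsv"))
    write_edge_list(network, file.path(config$out_dir, "edges.tsv"))
    nds_out <- nds_list[[1L]]
    utils::write.table(nds_out, file.path(config$out_dir, "nds_eps1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fire, file.path(config$out_dir, "fire.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  world: ", x$n_drugs, " drugs, ", x$n_side_effects,
      " side effects, ", x$n_positive_pairs, " positives, ", x$n_edges,
      " edges\n", sep = "")
  cat("  negatives per threshold: ",
      paste(x$nds_counts, collapse = ", "), "\n", sep = "")
  if (!is.null(x$nds_purity)) {
    cat("  purity per threshold: ",
        paste(sprintf("%.3f", x$nds_purity), collapse = ", "), "\n", sep = "")
  }
  e1 <- x$evaluations[[1L]]
  cat(sprintf("  at eps=%.3g: MCC=%.3f ACC=%.3f AUROC=%.3f AUPR=%.3f\n",
              e1$eps, e1$metrics$MCC, e1$metrics$ACC, e1$auroc, e1$aupr))
  if (!is.null(x$random_comparison)) {
    cat(sprintf("  random-negative baseline MCC=%.3f (selected %.3f)\n",
                x$random_comparison$random_mcc,
                x$random_comparison$selected_mcc))
  }
  invisible(x)
}

#' Cross-validated performance across a threshold grid
#'
#' Builds the negative set at each threshold, assembles features with all
#' positives, and cross-validates the classifier; the qualitative
#' expectation is that MCC does not improve as the threshold (and with it
#' the share of low-quality negatives) grows.
#'
#' @param world A [generate_world()] result.
#' @param eps_grid Threshold grid, or `NULL` for the quantile grid.
#' @param spec A [classifier_spec()].
#' @param folds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param lam,theta Walk parameters.
#' @return Data frame: `eps`, `n_negatives`, `purity`, `MCC`, `ACC`,
#'   `AUROC`, `AUPR`.
#' @export
run_threshold_sweep <- function(world, eps_grid = NULL,
                                spec = classifier_spec(), folds = 10L,
                                seed = 1L, lam = 0.8, theta = 1e-6) {
  index <- build_index(world$pairs)
  network <- build_network(world$records, world$drugs)
  profiles <- rwr_profiles(network, index, lam = lam, theta = theta)
  if (is.null(eps_grid)) eps_grid <- probability_grid(profiles, index)
  rows <- lapply(eps_grid, function(eps) {
    nds <- build_nds(network, index, eps, profiles = profiles)
    if (nrow(nds) == 0L) {
      return(data.frame(eps = unname(eps), n_negatives = 0L,
                        purity = NA_real_, MCC = NA_real_, ACC = NA_real_,
                        AUROC = NA_real_, AUPR = NA_real_))
    }
    feats <- .features_for(world$pairs, nds, world$channels, index)
    cv <- crossvalidate(feats, spec, k = folds, seed = seed)
    data.frame(eps = unname(eps), n_negatives = nrow(nds),
               purity = world_truth_report(world, nds)$purity,
               MCC = cv$metrics$MCC, ACC = cv$metrics$ACC,
               AUROC = cv$roc$area, AUPR = cv$pr$area)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
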