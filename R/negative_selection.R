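#' Default probability threshold grid
#'
#' The nine thresholds used to build and partition negative sample sets:
#' 0, 5e-7, 5e-6, 1e-5, 2e-5, 3e-5, 4e-5, 5e-5, 6e-5. These absolute values
#' are calibrated to a sparse real CCI network; for synthetic worlds use
#' [probability_grid()] to derive a grid from the observed probabilities.
#'
#' @return Named numeric vector (`eps1` .. `eps9`), strictly increasing.
#' @export
default_threshold_grid <- function() {
  stats::setNames(c(0, 5e-7, 5e-6, 1e-5, 2e-5, 3e-5, 4e-5, 5e-5, 6e-5),
                  paste0("eps", 1:9))
}

#' Quantile-based threshold grid for a probability profile
#'
#' Returns 0 followed by `k - 1` quantiles of the nonzero RWR probabilities
#' observed on non-positive drug/side-effect pairs, the last being their
#' maximum. This adapts the threshold grid to the probability scale of the
#' network at hand.
#'
#' @param profiles Drugs-by-side-effects probability matrix from
#'   [rwr_profiles()].
#' @param index Side-effect index; owners are excluded as positives.
#' @param k Number of grid points (default 5).
#' @return Strictly increasing numeric vector of length `k`, starting at 0.
#' @export
probability_grid <- function(profiles, index, k = 5L) {
  stopifnot(k >= 2L)
  pool <- unlist(lapply(names(index), function(s) {
    p <- profiles[, s]
    p[!(rownames(profiles) %in% index[[s]])]
  }), use.names = FALSE)
  pool <- pool[pool > 0]
  if (length(pool) == 0L) stop("no nonzero non-positive probabilities")
  qs <- stats::quantile(pool, probs = seq_len(k - 1L) / (k - 1L), names = FALSE)
  grid <- c(0, qs)
  if (any(diff(grid) <= 0)) stop("degenerate probability grid (tied quantiles)")
  stats::setNames(grid, paste0("eps", seq_len(k)))
}

#' Candidate negative pairs for one side effect
#'
#' Given the RWR probabilities computed with the side effect's owners as
#' seeds, returns every drug whose probability is at most `eps`, paired with
#' the side effect. Drugs forming a positive pair with the side effect are
#' excluded. Inclusion is `p <= eps` (not strict), so `eps = 0` selects
#' exactly the drugs unreachable from the seeds.
#'
#' @param side_effect Side-effect identifier.
#' @param probabilities Named numeric vector of per-drug probabilities (the
#'   `p` component of an [rwr()] result, or a column of [rwr_profiles()]).
#' @param eps Probability threshold.
#' @param positives Positive-pair data frame (`drug`, `side_effect`).
#' @return Data frame (`drug`, `side_effect`, `probability`) sorted by
#'   probability then drug identifier.
#' @export
select_candidates_for_side_effect <- function(side_effect, probabilities,
                                              eps, positives) {
  owners <- positives$drug[positives$side_effect == side_effect]
  keep <- probabilities <= eps & !(names(probabilities) %in% owners)
  out <- data.frame(drug = names(probabilities)[keep],
                    side_effect = rep(side_effect, sum(keep)),
                    probability = unname(probabilities[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$probability, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the negative sample set (NDS) under a threshold
#'
#' For every side effect, runs (or reuses) the random walk seeded at its
#' owning drugs and collects the candidate negatives with probability at
#' most `eps`. The union over side effects is the NDS.
#'
#' @param network A `drug_network`.
#' @param index Side-effect index; every side effect must have at least one
#'   owning drug in the network.
#' @param eps Probability threshold.
#' @param lam,theta Walk parameters (defaults 0.8 and 1e-6).
#' @param profiles Optional precomputed [rwr_profiles()] matrix; computing
#'   it once and passing it in is much faster when scanning a grid of
#'   thresholds.
#' @return Data frame (`drug`, `side_effect`, `probability`) with attribute
#'   `eps`.
#' @export
build_nds <- function(network, index, eps, lam = 0.8, theta = 1e-6,
                      profiles = NULL) {
  if (is.null(profiles)) {
    profiles <- rwr_profiles(network, index, lam = lam, theta = theta)
  }
  positives <- index_to_pairs(index)
  parts <- lapply(names(index), function(s) {
    select_candidates_for_side_effect(s, profiles[, s], eps, positives)
  })
  nds <- do.call(rbind, parts)
  rownames(nds) <- NULL
  attr(nds, "eps") <- eps
  nds
}

#' Assign negative samples to threshold parts
#'
#' Reproduces the printed partition of negatives over a threshold grid
#' `eps1 < eps2 < ... < epsk`: part 1 is `[0, eps1]`, part 2 is the open
#' interval `(eps1, eps2)`, and part `i >= 3` is `[eps(i-1), epsi)` — so the
#' boundary `eps2` belongs to part 3. A probability equal to the final grid
#' value is assigned to the last part.
#'
#' @param probabilities Numeric vector of RWR probabilities, each at most
#'   the last grid value.
#' @param grid Strictly increasing threshold grid.
#' @return Integer vector of part indices in `1..length(grid)`.
#' @export
partition_by_probability <- function(probabilities, grid) {
  grid <- as.numeric(grid)
  k <- length(grid)
  stopifnot(k >= 2L, all(diff(grid) > 0))
  if (any(probabilities < 0)) stop("negative probability")
  if (any(probabilities > grid[k])) {
    stop("probability above the last grid value (",
         format(max(probabilities)), " > ", format(grid[k]), ")")
  }
  part <- integer(length(probabilities))
  part[probabilities <= grid[1L]] <- 1L
  open2 <- probabilities > grid[1L] & probabilities < grid[2L]
  part[open2] <- 2L
  if (k >= 3L) {
    for (i in 3:k) {
      sel <- probabilities >= grid[i - 1L] & probabilities < grid[i]
      part[sel] <- i
    }
  }
  part[probabilities == grid[k]] <- k
  part
}

#' Distribution of interaction scores behind negative samples
#'
#' For each negative sample (drug d, side effect s), collects the
#' `combined_score` between d and every drug owning s, then histograms the
#' scores per part over `n_bins` equal-width intervals spanning (0, 999].
#' In include-zeros mode, zero scores (no direct edge) get their own first
#' bin; in exclude-zeros mode they are dropped and parts left with no score
#' are flagged. High-quality parts show all-zero scores: their drugs have no
#' direct link to any owner of the paired side effect.
#'
#' @param triples NDS data frame (`drug`, `side_effect`, `probability`).
#' @param network A `drug_network`.
#' @param index Side-effect index.
#' @param n_bins Number of positive-score bins (default 10).
#' @param include_zeros Keep zero scores in a dedicated bin? Default TRUE.
#' @param parts Optional precomputed part index per triple; default all 1.
#' @return List with `proportions` (parts x bins matrix, rows summing to 1
#'   where defined), `counts`, and `empty_parts` (flagged parts that had no
#'   score after zero-exclusion).
#' @export
score_distribution_diagnostic <- function(triples, network, index,
                                          n_bins = 10L, include_zeros = TRUE,
                                          parts = NULL) {
  stopifnot(n_bins >= 1L)
  if (is.null(parts)) parts <- rep(1L, nrow(triples))
  stopifnot(length(parts) == nrow(triples))
  A <- network$adjacency
  scores <- vector("list", nrow(triples))
  for (r in seq_len(nrow(triples))) {
    owners <- setdiff(index[[triples$side_effect[r]]], triples$drug[r])
    owners <- intersect(owners, network$nodes)
    scores[[r]] <- as.numeric(A[triples$drug[r], owners])
  }
  breaks <- seq(0, 999, length.out = n_bins + 1L)
  bin_labels <- paste0("(", utils::head(breaks, -1L), ",",
                       utils::tail(breaks, -1L), "]")
  if (include_zeros) bin_labels <- c("zero", bin_labels)
  part_levels <- sort(unique(parts))
  counts <- matrix(0L, length(part_levels), length(bin_labels),
                   dimnames = list(paste0("part", part_levels), bin_labels))
  for (r in seq_len(nrow(triples))) {
    sc <- scores[[r]]
    if (!include_zeros) sc <- sc[sc > 0]
    if (length(sc) == 0L) next
    zero <- sc == 0
    pos_bin <- findInterval(sc[!zero], breaks, left.open = TRUE,
                            all.inside = TRUE)
    row <- match(parts[r], part_levels)
    if (include_zeros) {
      counts[row, 1L] <- counts[row, 1L] + sum(zero)
      bins <- pos_bin + 1L
    } else {
      bins <- pos_bin
    }
    for (b in bins) counts[row, b] <- counts[row, b] + 1L
  }
  totals <- rowSums(counts)
  proportions <- counts / ifelse(totals > 0, totals, NA_real_)
  empty_parts <- rownames(counts)[totals == 0]
  list(proportions = proportions, counts = counts, empty_parts = empty_parts)
}

#' Uniformly random non-positive pairs
#'
#' The naive negative-sampling baseline: draws pairs uniformly from
#' (drugs x side effects) minus the positive pairs, without replacement.
#' Such draws can include latent positives — unvalidated true associations —
#' which the walk-based selection is designed to avoid.
#'
#' @param drugs Character vector of drugs.
#' @param side_effects Character vector of side effects.
#' @param positives Positive-pair data frame (`drug`, `side_effect`).
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @return Data frame (`drug`, `side_effect`).
#' @export
random_negative_pairs <- function(drugs, side_effects, positives, n, seed = 1L) {
  drugs <- sort(unique(drugs))
  side_effects <- sort(unique(side_effects))
  all_pairs <- expand.grid(drug = drugs, side_effect = side_effects,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(all_pairs$drug, all_pairs$side_effect, sep = "\r")
  pos_key <- paste(positives$drug, positives$side_effect, sep = "\r")
  candidates <- all_pairs[!(key %in% pos_key), , drop = FALSE]
  if (n > nrow(candidates)) {
    stop("requested ", n, " random negatives but only ", nrow(candidates),
         " non-positive pairs exist")
  }
  set.seed(seed)
  out <- candidates[sample.int(nrow(candidates), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
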