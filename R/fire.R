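# FIRE-style comparator: "finding reliable negative samples" adapted to the
# drug/side-effect setting. A pair's score is the strongest *direct* edge
# between the drug and the drugs owning the side effect; pairs with score
# zero (no direct link at all) are taken as negatives. Unlike the random
# walk, FIRE ignores distance beyond one hop, so it cannot grade the
# zero-score pairs any further.

#' FIRE score of one drug/side-effect pair
#'
#' Maximum `combined_score` edge weight between the drug and any owner of
#' the side effect (the drug itself excluded); exactly 0 when the drug has
#' no direct edge into the owner set.
#'
#' @param d Drug identifier (a network node).
#' @param s Side-effect identifier present in `index`.
#' @param network A `drug_network`.
#' @param index Side-effect index.
#' @return Non-negative score in combined_score units.
#' @export
fire_score <- function(d, s, network, index) {
  if (!s %in% names(index)) stop("unknown side effect: ", s)
  owners <- intersect(setdiff(index[[s]], d), network$nodes)
  if (length(owners) == 0L) return(0)
  max(as.numeric(network$adjacency[d, owners]))
}

#' FIRE negative selection
#'
#' All non-positive (drug, side effect) pairs whose FIRE score is zero.
#'
#' @param network A `drug_network`.
#' @param index Side-effect index.
#' @param positives Positive-pair data frame (`drug`, `side_effect`).
#' @return Data frame (`drug`, `side_effect`, `score`), score all zero.
#' @export
fire_select <- function(network, index, positives) {
  A <- network$adjacency
  out <- lapply(names(index), function(s) {
    owners <- intersect(index[[s]], network$nodes)
    pos_drugs <- positives$drug[positives$side_effect == s]
    cand <- setdiff(network$nodes, pos_drugs)
    if (length(owners) == 0L) {
      best <- stats::setNames(numeric(length(cand)), cand)
    } else {
      sub <- A[cand, owners, drop = FALSE]
      self <- match(cand, owners)
      hit <- which(!is.na(self))
      if (length(hit) > 0L) sub[cbind(hit, self[hit])] <- 0
      best <- apply(as.matrix(sub), 1L, max)
      names(best) <- cand
    }
    zero <- names(best)[best == 0]
    data.frame(drug = zero, side_effect = rep(s, length(zero)),
               score = numeric(length(zero)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$side_effect, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Overlap of the FIRE selection with the walk-based parts
#'
#' Cross-tabulates the FIRE zero-score set against the probability parts of
#' a walk-based negative set: per part, the fraction of its members that
#' FIRE also selects, and the distribution of the FIRE set over the parts
#' (members above the last grid value fall in `beyond_grid`).
#'
#' @param fire_set Data frame (`drug`, `side_effect`) from [fire_select()].
#' @param nds Data frame (`drug`, `side_effect`, `probability`).
#' @param parts Integer part index per `nds` row, as from
#'   [partition_by_probability()].
#' @return List with `fraction_in_fire` (named per part), and
#'   `fire_distribution` (fraction of the FIRE set per part, plus
#'   `beyond_grid`).
#' @export
fire_partition_report <- function(fire_set, nds, parts) {
  stopifnot(length(parts) == nrow(nds))
  fire_key <- paste(fire_set$drug, fire_set$side_effect, sep = "\r")
  nds_key <- paste(nds$drug, nds$side_effect, sep = "\r")
  in_fire <- nds_key %in% fire_key
  part_levels <- sort(unique(parts))
  frac <- vapply(part_levels, function(p) mean(in_fire[parts == p]),
                 numeric(1))
  names(frac) <- paste0("part", part_levels)
  hits <- table(factor(parts[in_fire], levels = part_levels))
  dist <- as.numeric(hits) / nrow(fire_set)
  names(dist) <- paste0("part", part_levels)
  beyond <- 1 - sum(dist)
  list(fraction_in_fire = frac,
       fire_distribution = c(dist, beyond_grid = beyond))
}
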