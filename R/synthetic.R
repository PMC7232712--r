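#' Configuration of a synthetic drug/side-effect world
#'
#' The generator plants community structure: drugs are partitioned into
#' communities, edges are dense within and sparse between communities
#' (`p_in` vs `p_out`), and each side effect is carried by one or two
#' communities. Drugs in a carrying community own the side effect with
#' probability `carriage_prob`; the carriers that were not emitted as
#' positives are the planted *latent positives*, the pairs a naive random
#' negative sampler would mislabel. All other non-positive pairs are planted
#' true negatives. Similarity channels score `similarity_signal` (plus
#' noise) within communities and at most `similarity_noise` between them,
#' making the premise "interacting chemicals share similar properties"
#' literally true and auditable.
#'
#' Defaults are desk-scale: 300 drugs, 40 side effects, 6 communities.
#' `p_out = 1e-4` keeps the between-community edge count near the
#' connectivity threshold, reproducing the fragmented coverage of real CCI
#' networks in which a sizable fraction of drug/side-effect pairs has no
#' network path at all. Edge weights are uniform integers on 150-999, the
#' typical reporting range of combined scores.
#'
#' @param n_drugs,n_side_effects,n_communities World dimensions.
#' @param p_in,p_out Within/between-community edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param weight_low,weight_high Integer edge-weight range within 1-999.
#' @param carriage_prob Probability a drug in a carrying community owns the
#'   side effect.
#' @param similarity_signal,similarity_noise Channel generation parameters.
#' @param seed Integer seed; worlds are fully reproducible from it.
#' @return List of class `world_config`.
#' @export
world_config <- function(n_drugs = 300L, n_side_effects = 40L,
                         n_communities = 6L, p_in = 0.3, p_out = 1e-4,
                         weight_low = 150L, weight_high = 999L,
                         carriage_prob = 0.7, similarity_signal = 0.6,
                         similarity_noise = 0.1, seed = 1L) {
  stopifnot(n_drugs >= n_communities, n_side_effects >= 1L,
            p_out >= 0, p_out < p_in, p_in <= 1,
            weight_low >= 1L, weight_low <= weight_high, weight_high <= 999L,
            carriage_prob >= 0, carriage_prob <= 1,
            similarity_signal >= 0, similarity_noise >= 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_side_effects = as.integer(n_side_effects),
                 n_communities = as.integer(n_communities),
                 p_in = p_in, p_out = p_out,
                 weight_low = as.integer(weight_low),
                 weight_high = as.integer(weight_high),
                 carriage_prob = carriage_prob,
                 similarity_signal = similarity_signal,
                 similarity_noise = similarity_noise,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a synthetic drug/side-effect world
#'
#' See [world_config()] for the planted structure. Every side effect is
#' guaranteed at least two owners (resampled up to 20 times, then an
#' error), so the per-pair maximum-similarity feature is well posed.
#'
#' @param config A [world_config()].
#' @return List of class `synthetic_world` with elements `records`
#'   (interaction table), `pairs` (positive pairs), `channels` (five
#'   similarity matrices), `truth` (data frame `drug`, `side_effect`,
#'   `truth` in `true_negative`/`latent_positive` for every non-positive
#'   pair), `communities` (named membership vector), `carriers` (list:
#'   side effect -> carrying community ids), and `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  drugs <- sprintf("d%04d", seq_len(config$n_drugs))
  side_effects <- sprintf("se%03d", seq_len(config$n_side_effects))
  comm <- rep_len(seq_len(config$n_communities), config$n_drugs)
  names(comm) <- drugs

  # edges: Bernoulli per unordered pair, p_in within / p_out between
  pairs_idx <- utils::combn(config$n_drugs, 2L)
  same <- comm[pairs_idx[1L, ]] == comm[pairs_idx[2L, ]]
  p_edge <- ifelse(same, config$p_in, config$p_out)
  on <- stats::runif(ncol(pairs_idx)) < p_edge
  n_edges <- sum(on)
  records <- data.frame(
    drug_a = drugs[pairs_idx[1L, on]],
    drug_b = drugs[pairs_idx[2L, on]],
    score = sample(seq(config$weight_low, config$weight_high), n_edges,
                   replace = TRUE),
    stringsAsFactors = FALSE
  )

  # side-effect carriage and positive pairs
  carriers <- vector("list", config$n_side_effects)
  names(carriers) <- side_effects
  pos_list <- vector("list", config$n_side_effects)
  for (s in seq_len(config$n_side_effects)) {
    for (attempt in seq_len(20L)) {
      n_carry <- sample(1:2, 1L)
      cc <- sample(seq_len(config$n_communities), min(n_carry,
                                                      config$n_communities))
      carrying_drugs <- drugs[comm %in% cc]
      owners <- carrying_drugs[stats::runif(length(carrying_drugs)) <
                                 config$carriage_prob]
      if (length(owners) >= 2L) break
      owners <- character()
    }
    if (length(owners) < 2L) {
      stop("side effect ", side_effects[s],
           " could not be given two owners after 20 attempts")
    }
    carriers[[s]] <- cc
    pos_list[[s]] <- data.frame(drug = owners,
                                side_effect = side_effects[s],
                                stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pos_list)
  pairs <- pairs[order(pairs$side_effect, pairs$drug), , drop = FALSE]
  rownames(pairs) <- NULL

  # ground truth for every non-positive pair
  pos_key <- paste(pairs$drug, pairs$side_effect, sep = "\r")
  grid <- expand.grid(drug = drugs, side_effect = side_effects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[!(paste(grid$drug, grid$side_effect, sep = "\r") %in% pos_key),
               , drop = FALSE]
  in_carrier <- mapply(function(d, s) comm[[d]] %in% carriers[[s]],
                       grid$drug, grid$side_effect, USE.NAMES = FALSE)
  truth <- data.frame(drug = grid$drug, side_effect = grid$side_effect,
                      truth = ifelse(in_carrier, "latent_positive",
                                     "true_negative"),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  # five similarity channels: signal within communities, noise between
  channels <- lapply(stats::setNames(CHANNELS, CHANNELS), function(ch) {
    U <- matrix(0, config$n_drugs, config$n_drugs,
                dimnames = list(drugs, drugs))
    u <- stats::runif(ncol(pairs_idx))
    vals <- ifelse(same, config$similarity_signal +
                     config$similarity_noise * u,
                   config$similarity_noise * u)
    vals <- pmin(vals, 1)
    U[t(pairs_idx)] <- vals
    U <- U + t(U)
    diag(U) <- 1
    U
  })

  structure(list(records = records, pairs = pairs, channels = channels,
                 truth = truth, communities = comm, carriers = carriers,
                 drugs = drugs, side_effects = side_effects,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic world: ", length(x$drugs), " drugs, ",
      length(x$side_effects), " side effects, ",
      x$config$n_communities, " communities, ",
      nrow(x$records), " interactions, ", nrow(x$pairs),
      " positive pairs\n", sep = "")
  invisible(x)
}

#' Purity of a negative sample set against planted ground truth
#'
#' Purity is the fraction of selected negatives that are planted true
#' negatives (as opposed to latent positives). With a part grid the purity
#' is also reported per probability part.
#'
#' @param world A [generate_world()] result.
#' @param nds Negative set (`drug`, `side_effect`, `probability`) built on
#'   the same world.
#' @param grid Optional threshold grid for a per-part breakdown.
#' @return List with `purity`, `n`, `base_rate` (true-negative fraction
#'   among all non-positive pairs) and, with a grid, `per_part` (data frame
#'   `part`, `n`, `purity`).
#' @export
world_truth_report <- function(world, nds, grid = NULL) {
  truth_key <- paste(world$truth$drug, world$truth$side_effect, sep = "\r")
  nds_key <- paste(nds$drug, nds$side_effect, sep = "\r")
  hit <- match(nds_key, truth_key)
  if (anyNA(hit)) stop("negative set contains pairs unknown to the world")
  is_tn <- world$truth$truth[hit] == "true_negative"
  out <- list(purity = if (nrow(nds) > 0L) mean(is_tn) else NA_real_,
              n = nrow(nds),
              base_rate = mean(world$truth$truth == "true_negative"))
  if (!is.null(grid)) {
    part <- partition_by_probability(nds$probability, grid)
    per <- do.call(rbind, lapply(sort(unique(part)), function(p) {
      data.frame(part = p, n = sum(part == p),
                 purity = mean(is_tn[part == p]))
    }))
    out$per_part <- per
  }
  out
}
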