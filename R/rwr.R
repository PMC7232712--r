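#' Restart vector for a seed set
#'
#' Probability `1/|SN|` on each seed, zero elsewhere; sums to one exactly.
#'
#' @param seeds Character vector of seed drugs (the drugs owning the side
#'   effect under study).
#' @param nodes Node ordering of the network.
#' @return Named numeric vector over `nodes`.
#' @export
make_restart_vector <- function(seeds, nodes) {
  seeds <- unique(seeds)
  if (length(seeds) == 0L) stop("no seeds")
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    stop("seed drug(s) not in the network: ", paste(missing, collapse = ", "))
  }
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Random walk with restart, iterative solver
#'
#' Iterates `p <- (1 - lam) * M %*% p + lam * p0` from `p0` until the L1
#' change between successive iterates falls below `theta`. `lam` is the
#' restart probability: at every step the walker returns to the seed
#' distribution with probability `lam`, so large `lam` keeps probability
#' mass near the seeds.
#'
#' @param M Column-stochastic transition matrix (from [column_normalize()]).
#' @param p0 Restart vector (from [make_restart_vector()]).
#' @param lam Restart probability in (0, 1]; default 0.8.
#' @param theta L1 convergence tolerance; default 1e-6.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE` and a warning, never silently.
#' @return List with `p` (named probabilities), `iterations`, `converged`.
#' @export
rwr_iterate <- function(M, p0, lam = 0.8, theta = 1e-6, max_iter = 10000L) {
  stopifnot(lam > 0, lam <= 1, theta > 0)
  p <- as.numeric(p0)
  for (it in seq_len(max_iter)) {
    p_new <- (1 - lam) * as.numeric(M %*% p) + lam * as.numeric(p0)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < theta) {
      return(list(p = stats::setNames(p, names(p0)), iterations = it,
                  converged = TRUE))
    }
  }
  warning("RWR did not converge within ", max_iter, " iterations (last L1 ",
          "change ", format(delta), ")")
  list(p = stats::setNames(p, names(p0)), iterations = max_iter,
       converged = FALSE)
}

#' Random walk with restart, direct linear solve
#'
#' Solves the fixed point `p = (1 - lam) M p + lam p0` exactly as the linear
#' system `(I - (1 - lam) M) p = lam p0`. For `lam > 0` and sub-stochastic
#' `M` the system is always non-singular. Used as the exact solver for small
#' networks and as the independent oracle for the iterative solver.
#'
#' @inheritParams rwr_iterate
#' @return List with `p` (named), `iterations = NA`, `converged = TRUE`.
#' @export
rwr_direct_solve <- function(M, p0, lam = 0.8) {
  stopifnot(lam > 0, lam <= 1)
  n <- length(p0)
  lhs <- Matrix::Diagonal(n) - (1 - lam) * M
  p <- tryCatch(as.numeric(Matrix::solve(lhs, lam * as.numeric(p0))),
                error = function(e) {
                  stop("RWR linear system could not be solved: ",
                       conditionMessage(e))
                })
  list(p = stats::setNames(p, names(p0)), iterations = NA_integer_,
       converged = TRUE)
}

#' RWR probabilities for one seed set on a drug network
#'
#' Convenience wrapper: builds the transition matrix and restart vector and
#' dispatches to the direct solver for networks up to `direct_cutoff` nodes,
#' to the iterative solver beyond.
#'
#' @param network A `drug_network`.
#' @param seeds Character vector of seed drugs.
#' @param lam,theta,max_iter See [rwr_iterate()].
#' @param method `"auto"` (default), `"direct"` or `"iterative"`.
#' @param direct_cutoff Node count up to which `"auto"` uses the direct
#'   solver; default 2000.
#' @return As [rwr_iterate()].
#' @export
rwr <- function(network, seeds, lam = 0.8, theta = 1e-6, max_iter = 10000L,
                method = c("auto", "direct", "iterative"),
                direct_cutoff = 2000L) {
  method <- match.arg(method)
  M <- column_normalize(network)
  p0 <- make_restart_vector(seeds, network$nodes)
  use_direct <- switch(method,
                       auto = length(network$nodes) <= direct_cutoff,
                       direct = TRUE, iterative = FALSE)
  if (use_direct) rwr_direct_solve(M, p0, lam)
  else rwr_iterate(M, p0, lam, theta, max_iter)
}

#' RWR probability profiles for every side effect
#'
#' Runs the walk once per side effect with the drugs owning it as seeds and
#' stacks the results into a drugs-by-side-effects matrix. On small networks
#' all columns are obtained from one multi-right-hand-side direct solve.
#'
#' @param network A `drug_network`.
#' @param index Side-effect index (from [build_index()]); every side effect
#'   must have at least one owning drug present in the network.
#' @inheritParams rwr
#' @return Numeric matrix, rows = network nodes, columns = side effects.
#' @export
rwr_profiles <- function(network, index, lam = 0.8, theta = 1e-6,
                         max_iter = 10000L,
                         method = c("auto", "direct", "iterative"),
                         direct_cutoff = 2000L) {
  method <- match.arg(method)
  nodes <- network$nodes
  bad <- names(index)[vapply(index, function(s) {
    length(intersect(s, nodes)) == 0L
  }, logical(1))]
  if (length(bad) > 0L) {
    stop("side effect(s) with no owning drug in the network: ",
         paste(bad, collapse = ", "))
  }
  M <- column_normalize(network)
  P0 <- vapply(index, function(s) {
    make_restart_vector(intersect(s, nodes), nodes)
  }, numeric(length(nodes)))
  use_direct <- switch(method,
                       auto = length(nodes) <= direct_cutoff,
                       direct = TRUE, iterative = FALSE)
  if (use_direct) {
    lhs <- Matrix::Diagonal(length(nodes)) - (1 - lam) * M
    P <- as.matrix(Matrix::solve(lhs, lam * P0))
  } else {
    P <- apply(P0, 2L, function(p0) {
      rwr_iterate(M, stats::setNames(p0, nodes), lam, theta, max_iter)$p
    })
  }
  dimnames(P) <- list(nodes, names(index))
  P
}
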