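#' Build the weighted drug network
#'
#' Nodes are the drug universe in lexicographic order; two drugs are adjacent
#' iff they share an interaction record with positive `combined_score`, and
#' the edge weight is that score. Records mentioning drugs outside the
#' universe are dropped (real STITCH files contain many extra chemicals);
#' the number dropped is recorded and reported via `message()`.
#'
#' @param records Interaction data frame (`drug_a`, `drug_b`, `score`), as
#'   from [read_interaction_table()].
#' @param drug_universe Character vector of drug identifiers to use as nodes.
#' @return A `drug_network` object: list with `nodes` (character),
#'   `adjacency` (symmetric sparse [Matrix::Matrix] of weights, zero
#'   diagonal) and `n_dropped`.
#' @export
build_network <- function(records, drug_universe) {
  if (length(drug_universe) == 0L) stop("drug universe is empty")
  nodes <- sort(unique(drug_universe))
  n <- length(nodes)
  keep <- records$drug_a %in% nodes & records$drug_b %in% nodes &
    records$score > 0
  n_dropped <- sum(!(records$drug_a %in% nodes) | !(records$drug_b %in% nodes))
  if (n_dropped > 0L) {
    message(n_dropped, " interaction record(s) referenced drugs outside the ",
            "universe and were dropped")
  }
  rec <- records[keep, , drop = FALSE]
  i <- match(rec$drug_a, nodes)
  j <- match(rec$drug_b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = as.numeric(c(rec$score, rec$score)),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  structure(list(nodes = nodes, adjacency = A, n_dropped = n_dropped),
            class = "drug_network")
}

#' @export
print.drug_network <- function(x, ...) {
  n_edges <- Matrix::nnzero(x$adjacency) / 2
  iso <- sum(Matrix::colSums(x$adjacency) == 0)
  cat("drug network: ", length(x$nodes), " nodes, ", n_edges, " edges, ",
      iso, " isolated\n", sep = "")
  invisible(x)
}

#' Node degrees (weighted) of a drug network
#' @param network A `drug_network`.
#' @return Named numeric vector of weighted degrees (column sums).
#' @export
network_degree <- function(network) {
  d <- Matrix::colSums(network$adjacency)
  names(d) <- network$nodes
  d
}

#' Export the edge list of a drug network
#'
#' @param network A `drug_network`.
#' @param path Output TSV path (`drug_a`, `drug_b`, `weight`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  A <- methods::as(Matrix::triu(network$adjacency), "TsparseMatrix")
  df <- data.frame(drug_a = network$nodes[A@i + 1L],
                   drug_b = network$nodes[A@j + 1L],
                   weight = A@x)
  df <- df[order(df$drug_a, df$drug_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Column-stochastic transition matrix of a drug network
#'
#' Each column of the adjacency matrix is divided by its sum, so that
#' `M[i, j]` is the probability that a walker at node `j` moves to node `i`.
#' Columns of isolated nodes (zero degree) are left all-zero; no self-loop
#' is injected, so walker mass can leave but never enter an isolated node.
#'
#' @param network A `drug_network`.
#' @return Sparse column-stochastic matrix with the network's node dimnames.
#' @export
column_normalize <- function(network) {
  deg <- Matrix::colSums(network$adjacency)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  M <- network$adjacency %*% Matrix::Diagonal(x = inv)
  dimnames(M) <- list(network$nodes, network$nodes)
  M
}
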