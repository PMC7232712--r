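# In-code fixtures shared across test files.

# path network a - b - c with equal weights
path_network <- function(weight = 999L) {
  rec <- data.frame(drug_a = c("a", "b"), drug_b = c("b", "c"),
                    score = c(weight, weight), stringsAsFactors = FALSE)
  build_network(rec, c("a", "b", "c"))
}

# star with a hub and k leaves, equal weights
star_network <- function(k = 3L, weight = 500L) {
  leaves <- paste0("l", seq_len(k))
  rec <- data.frame(drug_a = rep("hub", k), drug_b = leaves,
                    score = rep(weight, k), stringsAsFactors = FALSE)
  build_network(rec, c("hub", leaves))
}

# random weighted graph instance: list(network, nodes)
random_instance <- function(n = 40L, m = 60L, seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  a <- sample(nodes, m, replace = TRUE)
  b <- sample(nodes, m, replace = TRUE)
  rec <- data.frame(drug_a = a, drug_b = b,
                    score = sample(1:999, m, replace = TRUE),
                    stringsAsFactors = FALSE)
  rec <- rec[rec$drug_a != rec$drug_b, , drop = FALSE]
  list(network = build_network(rec, nodes), nodes = nodes)
}

# random side-effect index over an instance's nodes
random_index <- function(nodes, n_se = 4L, seed = 1L) {
  set.seed(seed)
  idx <- lapply(seq_len(n_se), function(i) {
    sort(sample(nodes, sample(2:5, 1L)))
  })
  names(idx) <- sprintf("se%02d", seq_len(n_se))
  idx
}

# BFS reachability from a seed set over a drug_network, igraph-free
bfs_reachable <- function(network, seeds) {
  A <- network$adjacency > 0
  frontier <- intersect(seeds, network$nodes)
  seen <- frontier
  while (length(frontier) > 0L) {
    nbrs <- network$nodes[Matrix::rowSums(A[, frontier, drop = FALSE]) > 0]
    frontier <- setdiff(nbrs, seen)
    seen <- union(seen, frontier)
  }
  seen
}

# small synthetic world for fast unit tests (generator defaults untouched)
small_world <- function(seed = 1L, p_out = 1e-4) {
  generate_world(world_config(n_drugs = 90L, n_side_effects = 8L,
                              n_communities = 3L, p_out = p_out,
                              seed = seed))
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
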