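test_that("candidate extraction keeps p <= eps and excludes positives", {
  # a-b edge, c isolated; s owned by {a}: only c is unreachable
  rec <- data.frame(drug_a = "a", drug_b = "b", score = 500L)
  net <- build_network(rec, c("a", "b", "c"))
  positives <- data.frame(drug = "a", side_effect = "s")
  res <- rwr(net, "a")
  cand <- select_candidates_for_side_effect("s", res$p, eps = 0, positives)
  expect_equal(cand, data.frame(drug = "c", side_effect = "s",
                                probability = 0))

  # vacuous threshold selects every non-positive drug
  all_cand <- select_candidates_for_side_effect("s", res$p, eps = 1, positives)
  expect_setequal(all_cand$drug, c("b", "c"))

  # all drugs own s: nothing left
  pos_all <- data.frame(drug = c("a", "b", "c"), side_effect = "s")
  expect_equal(nrow(select_candidates_for_side_effect("s", res$p, 1, pos_all)),
               0L)
})

test_that("NDS grows monotonically with the threshold", {
  for (seed in 1:5) {
    inst <- random_instance(n = 30L, m = 45L, seed = seed)
    idx <- random_index(inst$nodes, n_se = 4L, seed = seed)
    prof <- rwr_profiles(inst$network, idx)
    grid <- c(0, 1e-6, 1e-4, 1e-2, 1)
    sizes <- vapply(grid, function(eps) {
      nrow(build_nds(inst$network, idx, eps, profiles = prof))
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
    # nested, not merely growing
    small <- build_nds(inst$network, idx, grid[2], profiles = prof)
    big <- build_nds(inst$network, idx, grid[4], profiles = prof)
    expect_true(all(paste(small$drug, small$side_effect) %in%
                      paste(big$drug, big$side_effect)))
  }
})

test_that("eps = 0 on a connected network with seeds everywhere is empty", {
  net <- path_network()
  idx <- list(s1 = "a", s2 = "b")
  nds <- build_nds(net, idx, eps = 0)
  expect_equal(nrow(nds), 0L)
})

test_that("side effects with no seed drug in the network are rejected", {
  net <- path_network()
  expect_error(build_nds(net, list(s1 = "a", s2 = "zz"), eps = 0), "s2")
})

test_that("zero-probability candidates equal the BFS-unreachable set", {
  for (seed in 1:10) {
    inst <- random_instance(n = 35L, m = 40L, seed = seed + 100L)
    idx <- random_index(inst$nodes, n_se = 3L, seed = seed)
    prof <- rwr_profiles(inst$network, idx)
    positives <- index_to_pairs(idx)
    for (s in names(idx)) {
      cand <- select_candidates_for_side_effect(s, prof[, s], 0, positives)
      unreachable <- setdiff(inst$nodes, bfs_reachable(inst$network, idx[[s]]))
      expect_setequal(cand$drug, setdiff(unreachable, idx[[s]]))
    }
  }
})

test_that("probability parts reproduce the printed interval brackets", {
  grid <- default_threshold_grid()
  expect_equal(partition_by_probability(0, grid), 1L)
  expect_equal(partition_by_probability(3e-6, grid), 3L)
  expect_equal(partition_by_probability(5.5e-5, grid), 9L)
  # part 2 is open on both sides: the boundary eps2 belongs to part 3
  expect_equal(partition_by_probability(5e-7, grid), 3L)
  expect_equal(partition_by_probability(1e-7, grid), 2L)
  # the final grid value is assigned to the last part
  expect_equal(partition_by_probability(6e-5, grid), 9L)
  expect_error(partition_by_probability(7e-5, grid), "last grid value")
})

test_that("vectorized partition agrees with a linear-scan oracle", {
  grid <- default_threshold_grid()
  scan_oracle <- function(p) {
    if (p <= grid[1]) return(1L)
    if (p < grid[2]) return(2L)
    for (i in 3:length(grid)) if (p < grid[i]) return(i)
    length(grid)
  }
  set.seed(31)
  probs <- unname(c(0, grid, runif(200, 0, 6e-5)))
  probs <- probs[probs <= grid[length(grid)]]
  expect_equal(partition_by_probability(probs, grid),
               vapply(probs, scan_oracle, integer(1)))
  counts <- table(partition_by_probability(probs, grid))
  expect_equal(sum(counts), length(probs))
})

test_that("score distribution diagnostic bins combined scores by part", {
  # unreachable candidates have no edges to owners: everything in the zero bin
  rec <- data.frame(drug_a = "a", drug_b = "b", score = 500L)
  net <- build_network(rec, c("a", "b", "c"))
  idx <- list(s = "a")
  triples <- data.frame(drug = "c", side_effect = "s", probability = 0)
  diag1 <- score_distribution_diagnostic(triples, net, idx)
  expect_equal(unname(diag1$proportions[1, "zero"]), 1)

  # exclude-zeros mode flags parts left empty
  diag2 <- score_distribution_diagnostic(triples, net, idx,
                                         include_zeros = FALSE)
  expect_equal(diag2$empty_parts, "part1")

  # owner scores {100, 950} with 10 bins: one count in bin 2, one in bin 10
  rec3 <- data.frame(drug_a = c("x", "x"), drug_b = c("o1", "o2"),
                     score = c(100L, 950L))
  net3 <- build_network(rec3, c("x", "o1", "o2"))
  idx3 <- list(s = c("o1", "o2"))
  tr3 <- data.frame(drug = "x", side_effect = "s", probability = 0.5)
  diag3 <- score_distribution_diagnostic(tr3, net3, idx3, n_bins = 10L,
                                         include_zeros = FALSE)
  expect_equal(unname(diag3$counts[1, ]),
               c(0, 1, 0, 0, 0, 0, 0, 0, 0, 1))
})

test_that("random negative pairs are deterministic and exclude positives", {
  drugs <- sprintf("d%02d", 1:10)
  ses <- c("s1", "s2")
  positives <- data.frame(drug = c("d01", "d02"), side_effect = c("s1", "s2"))
  a <- random_negative_pairs(drugs, ses, positives, 5L, seed = 4L)
  b <- random_negative_pairs(drugs, ses, positives, 5L, seed = 4L)
  expect_identical(a, b)
  expect_false(any(paste(a$drug, a$side_effect) %in%
                     paste(positives$drug, positives$side_effect)))
  expect_error(random_negative_pairs(drugs, ses, positives, 19L), "18")
})
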