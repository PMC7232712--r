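#' Read a STITCH-style chemical-chemical interaction table
#'
#' Reads a tab-separated file in the `chemical_chemical.links` dialect
#' (header columns `chemical1`, `chemical2`, `combined_score`; extra columns
#' are ignored). Rows are canonicalized to undirected pairs: self-pairs are
#' dropped, duplicate unordered pairs are collapsed keeping the maximum
#' score, and rows with a collapsed score below `min_score` are removed.
#'
#' @param path Path to the TSV file.
#' @param min_score Minimum `combined_score` to keep (STITCH scores run from
#'   1 to 999).
#' @return A data frame with columns `drug_a`, `drug_b`, `score`, one row per
#'   unordered pair, with `drug_a < drug_b` lexicographically.
#' @seealso [build_network()], [write_interaction_table()]
#' @export
read_interaction_table <- function(path, min_score = 1L) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("chemical1", "chemical2", "combined_score")
  absent <- setdiff(required, names(tab))
  if (length(absent) > 0L) {
    stop("interaction table missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(score) | score != floor(score))
  if (length(bad) > 0L) {
    stop("non-integer combined_score at data line ", bad[1L],
         " (value '", tab$combined_score[bad[1L]], "')")
  }
  canonicalize_interactions(data.frame(
    drug_a = tab$chemical1, drug_b = tab$chemical2,
    score = as.integer(score), stringsAsFactors = FALSE
  ), min_score = min_score)
}

# Canonical form: drug_a < drug_b, no self-pairs, duplicates keep max score,
# then the min_score filter.
canonicalize_interactions <- function(records, min_score = 1L) {
  keep <- records$drug_a != records$drug_b
  records <- records[keep, , drop = FALSE]
  if (nrow(records) > 0L) {
    a <- pmin(records$drug_a, records$drug_b)
    b <- pmax(records$drug_a, records$drug_b)
    key <- paste(a, b, sep = "\r")
    score_by_key <- tapply(records$score, key, max)
    keys <- names(score_by_key)
    score <- as.integer(score_by_key)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    records <- data.frame(
      drug_a = vapply(parts, `[`, character(1), 1L),
      drug_b = vapply(parts, `[`, character(1), 2L),
      score = as.integer(score), stringsAsFactors = FALSE
    )
    records <- records[records$score >= min_score, , drop = FALSE]
    records <- records[order(records$drug_a, records$drug_b), , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Write an interaction table in the same dialect read_interaction_table reads
#'
#' @param records Data frame with columns `drug_a`, `drug_b`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path) {
  out <- data.frame(chemical1 = records$drug_a, chemical2 = records$drug_b,
                    combined_score = records$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug/side-effect positive-pair table
#'
#' Two-column TSV with header `drug`, `side_effect` (SIDER-like). Duplicate
#' pairs are collapsed.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `drug`, `side_effect`, one row per
#'   distinct pair.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  absent <- setdiff(c("drug", "side_effect"), names(tab))
  if (length(absent) > 0L) {
    stop("pair table missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("pair table is empty (header only): ", path)
  if (any(!nzchar(tab$drug)) || any(!nzchar(tab$side_effect))) {
    stop("pair table contains empty identifiers")
  }
  pairs <- unique(data.frame(drug = tab$drug, side_effect = tab$side_effect,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$side_effect, pairs$drug), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write a pair table
#'
#' @param pairs Data frame with columns `drug`, `side_effect`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs[, c("drug", "side_effect")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Invert a positive-pair table into a side-effect index
#'
#' The index maps each side effect to the set of drugs owning it; these sets
#' are the seed sets of the random walk and the drug sets `S` over which the
#' per-pair similarity features take their maximum.
#'
#' @param pairs Data frame with columns `drug`, `side_effect`.
#' @return Named list: side effect -> sorted character vector of drugs.
#' @seealso [index_to_pairs()] for the inverse.
#' @export
build_index <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("pair table is empty")
  idx <- split(pairs$drug, pairs$side_effect)
  idx <- lapply(idx, function(d) sort(unique(d)))
  idx[order(names(idx))]
}

#' Expand a side-effect index back into a pair table
#'
#' Exact inverse of [build_index()]: round-tripping reproduces the input
#' pair set.
#'
#' @param index Named list as returned by [build_index()].
#' @return Data frame with columns `drug`, `side_effect`.
#' @export
index_to_pairs <- function(index) {
  pairs <- data.frame(
    drug = unlist(index, use.names = FALSE),
    side_effect = rep(names(index), lengths(index)),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$side_effect, pairs$drug), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Read a square drug-drug similarity matrix
#'
#' TSV whose first column and header row are drug identifiers. The matrix
#' must be square over an identical row/column identifier set and symmetric
#' to within `tol`. The result is restricted (and zero-extended) to
#' `drug_universe`: drugs absent from the file get all-zero rows and columns,
#' the "no evidence of association" convention under which the per-pair
#' maximum feature remains well defined.
#'
#' @param path Path to the TSV file.
#' @param drug_universe Character vector of drug identifiers for the output.
#' @param tol Symmetry tolerance.
#' @return Symmetric numeric matrix with dimnames `sort(drug_universe)`.
#' @export
read_similarity_matrix <- function(path, drug_universe, tol = 1e-9) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    stop("similarity matrix is not square: ", nrow(m), " rows vs ",
         ncol(m), " columns")
  }
  if (!setequal(rownames(m), colnames(m))) {
    stop("similarity matrix row and column identifiers differ")
  }
  m <- m[, rownames(m), drop = FALSE]
  storage.mode(m) <- "double"
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop("similarity matrix is asymmetric (max |W - t(W)| = ",
         format(asym), ")")
  }
  universe <- sort(unique(drug_universe))
  out <- matrix(0, length(universe), length(universe),
                dimnames = list(universe, universe))
  shared <- intersect(universe, rownames(m))
  out[shared, shared] <- m[shared, shared]
  out
}

#' Write a similarity matrix in the dialect read_similarity_matrix reads
#'
#' @param W Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(W, path) {
  df <- data.frame(drug = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
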