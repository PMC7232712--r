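# Five drug-association channels feed the per-pair features, in fixed order:
# fingerprint, structure, atc, literature, target. Fingerprint (Tanimoto over
# ECFP-style bit sets) and target (cosine over 0/1 target-protein profiles)
# are computed natively; structure (SIMCOMP), ATC and literature scores come
# from external tools and are consumed as precomputed matrices.

CHANNELS <- c("fingerprint", "structure", "atc", "literature", "target")

#' Tanimoto coefficient of two fingerprint bit sets
#'
#' `|intersection| / |union|`; 0 when both sets are empty.
#'
#' @param fp1,fp2 Integer vectors of on-bit indices.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp1, fp2) {
  fp1 <- unique(fp1)
  fp2 <- unique(fp2)
  u <- length(union(fp1, fp2))
  if (u == 0L) return(0)
  length(intersect(fp1, fp2)) / u
}

#' Cosine similarity of two 0/1 target profiles
#'
#' `dot(v1, v2) / (|v1| |v2|)`; 0 when either vector is all-zero.
#'
#' @param v1,v2 Numeric 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
target_cosine <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("target profile length mismatch: ", length(v1), " vs ", length(v2))
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

#' Fingerprint similarity matrix over a set of drugs
#'
#' Pairwise Tanimoto coefficients; drugs with empty fingerprints are allowed
#' (zero similarity to everything) and flagged with a message.
#'
#' @param fingerprints Named list: drug -> integer vector of on-bit indices.
#' @return Symmetric matrix with unit diagonal for non-empty fingerprints.
#' @export
fingerprint_similarity <- function(fingerprints) {
  drugs <- sort(names(fingerprints))
  empty <- drugs[lengths(fingerprints[drugs]) == 0L]
  if (length(empty) > 0L) {
    message(length(empty), " drug(s) have empty fingerprints")
  }
  n <- length(drugs)
  W <- matrix(0, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n)) {
    for (j in i:n) {
      W[i, j] <- W[j, i] <- tanimoto(fingerprints[[drugs[i]]],
                                     fingerprints[[drugs[j]]])
    }
  }
  W
}

#' Target-profile cosine similarity matrix
#'
#' @param profiles 0/1 matrix, rows = drugs, columns = target proteins
#'   (a shared protein universe).
#' @return Symmetric cosine similarity matrix over the row names.
#' @export
target_similarity <- function(profiles) {
  profiles <- profiles[sort(rownames(profiles)), , drop = FALSE]
  norms <- sqrt(rowSums(profiles^2))
  W <- tcrossprod(as.matrix(profiles))
  denom <- outer(norms, norms)
  W <- ifelse(denom > 0, W / denom, 0)
  dimnames(W) <- list(rownames(profiles), rownames(profiles))
  W
}

#' Read a fingerprint table
#'
#' TSV with columns `drug` and `bits`, the latter a comma-separated list of
#' on-bit indices (may be empty).
#'
#' @param path Path to the TSV file.
#' @return Named list: drug -> integer vector.
#' @export
read_fingerprint_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  absent <- setdiff(c("drug", "bits"), names(tab))
  if (length(absent) > 0L) {
    stop("fingerprint table missing column(s): ", paste(absent, collapse = ", "))
  }
  fps <- lapply(tab$bits, function(b) {
    if (!nzchar(b)) return(integer())
    as.integer(strsplit(b, ",", fixed = TRUE)[[1L]])
  })
  names(fps) <- tab$drug
  fps
}

#' Read a drug-by-protein target incidence table
#'
#' TSV whose first column holds drug identifiers and remaining columns are
#' proteins, entries 0/1.
#'
#' @param path Path to the TSV file.
#' @return Numeric 0/1 matrix, rows = drugs.
#' @export
read_target_profile_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1))) stop("target profiles must be 0/1")
  m
}

#' Per-pair feature from one similarity channel
#'
#' For a pair (drug d, side effect s) with owner set S, the feature is
#' `max W(d, d') over d' in S minus d` — the strongest association between
#' the drug and the other drugs already known to own the side effect.
#' Returns 0 when no competitor exists (`S - {d}` empty).
#'
#' @param d Drug identifier (must be a row of `W`).
#' @param s Side-effect identifier.
#' @param W Symmetric similarity matrix with drug dimnames.
#' @param index Side-effect index.
#' @return Non-negative feature value.
#' @export
pair_feature <- function(d, s, W, index) {
  if (!s %in% names(index)) stop("unknown side effect: ", s)
  if (!d %in% rownames(W)) stop("unknown drug: ", d)
  competitors <- setdiff(index[[s]], d)
  competitors <- intersect(competitors, colnames(W))
  if (length(competitors) == 0L) return(0)
  max(W[d, competitors])
}

#' Five-channel feature vectors for labeled pairs
#'
#' One feature per association channel, in the fixed order fingerprint,
#' structure, atc, literature, target; each is the [pair_feature()] maximum
#' for that channel. All-zero channels are accepted (and logged).
#'
#' @param pairs Data frame with columns `drug`, `side_effect` and `label`
#'   (`"positive"` or `"negative"`).
#' @param channels Named list of five similarity matrices with names
#'   `fingerprint`, `structure`, `atc`, `literature`, `target`.
#' @param index Side-effect index.
#' @return Data frame: `drug`, `side_effect`, `q_fingerprint`, `q_structure`,
#'   `q_atc`, `q_literature`, `q_target`, `label`; one row per input pair.
#' @export
featurize <- function(pairs, channels, index) {
  absent <- setdiff(CHANNELS, names(channels))
  if (length(absent) > 0L) {
    stop("missing channel(s): ", paste(absent, collapse = ", "))
  }
  for (ch in CHANNELS) {
    unknown <- setdiff(pairs$drug, rownames(channels[[ch]]))
    if (length(unknown) > 0L) {
      stop("pair references drug absent from the ", ch, " channel: ",
           unknown[1L])
    }
    if (all(channels[[ch]] == 0)) message("channel '", ch, "' is all-zero")
  }
  out <- pairs[, c("drug", "side_effect"), drop = FALSE]
  for (ch in CHANNELS) {
    W <- channels[[ch]]
    vals <- numeric(nrow(pairs))
    # group by side effect so the max is one vectorized row scan per group
    for (s in unique(pairs$side_effect)) {
      rows <- which(pairs$side_effect == s)
      owners <- intersect(index[[s]], colnames(W))
      if (length(owners) == 0L) next
      sub <- W[pairs$drug[rows], owners, drop = FALSE]
      self <- match(pairs$drug[rows], owners)
      hit <- which(!is.na(self))
      if (length(hit) > 0L) sub[cbind(hit, self[hit])] <- -Inf
      mx <- apply(sub, 1L, max)
      vals[rows] <- ifelse(is.finite(mx), pmax(mx, 0), 0)
    }
    out[[paste0("q_", ch)]] <- vals
  }
  out$label <- pairs$label
  rownames(out) <- NULL
  out
}
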