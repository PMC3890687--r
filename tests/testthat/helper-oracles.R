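# Independent brute-force oracles and fixture generators used across the
# suite. These deliberately avoid the package's own code paths: per-column
# if/else enumeration for site classification, a sort-based
# re-implementation of the identification criteria, and a grid recount for
# the threshold scan.

# per-column brute force classification of a pair of aligned sequences
oracle_classify <- function(a, b) {
  a <- toupper(strsplit(a, "")[[1]])
  b <- toupper(strsplit(b, "")[[1]])
  pure <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(a)) {
    x <- a[k]; y <- b[k]
    if (!(x %in% pure) || !(y %in% pure)) next
    n <- n + 1L
    if (x == y) next
    pair <- paste(sort(c(x, y)), collapse = "")
    if (pair == "AG" || pair == "CT") ts <- ts + 1L else tv <- tv + 1L
  }
  list(n = n, ts = ts, tv = tv)
}

oracle_k2p <- function(a, b) {
  cnt <- oracle_classify(a, b)
  if (cnt$n == 0L) return(NA_real_)
  P <- cnt$ts / cnt$n; Q <- cnt$tv / cnt$n
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# sort-based identification oracle: returns category for one query
oracle_identify <- function(query_id, m, labels, threshold = Inf) {
  others <- setdiff(rownames(m), query_id)
  d <- m[query_id, others]
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_character_)
  d <- sort(d)
  best <- d[1]
  if (best > threshold) return("no_match_closer_than_threshold")
  set <- unique(labels[names(d)[d == best]])
  truth <- labels[[query_id]]
  if (!(truth %in% set)) "incorrect"
  else if (length(set) > 1L) "ambiguous"
  else "correct"
}

# brute-force total error at a threshold
oracle_total_error <- function(intra, inter, t) {
  sum(intra > t) / length(intra) + sum(inter <= t) / length(inter)
}

# random aligned fixture with optional gaps/ambiguity, as labeled_alignment
random_alignment <- function(n = 6, len = 40, n_species = 3,
                             chars = c("A", "C", "G", "T"), gap_p = 0) {
  pool <- chars
  mat <- matrix(sample(pool, n * len, replace = TRUE), n, len)
  if (gap_p > 0) {
    idx <- which(runif(n * len) < gap_p)
    mat[idx] <- "-"
  }
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  labeled_alignment(mat, species = sprintf("sp%d",
                                           rep_len(seq_len(n_species), n)))
}

# random distance matrix with species labels for identification tests
random_labeled_matrix <- function(n_species = 3, n_per = 3, scale = 0.2) {
  n <- n_species * n_per
  ids <- sprintf("t%02d", seq_len(n))
  labels <- stats::setNames(sprintf("sp%d", rep(seq_len(n_species), each = n_per)),
                            ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- round(runif(n * (n - 1) / 2, 0, scale), 3)  # rounding forces ties
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  list(m = m, labels = labels)
}
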