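# Kimura two-parameter (K2P) distances with pairwise deletion.
#
# For each pair of aligned rows, columns where either sequence carries a
# gap or an ambiguity code are skipped (pairwise deletion); the remaining
# pure-base columns are classified into transitions (A<->G, C<->T) and
# transversions, giving the proportions P and Q that feed Kimura's (1980)
# estimator  d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)].

.char_vec <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) != 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(as.character(x))
}

# TRUE for purines, FALSE for pyrimidines, NA otherwise
.IS_PURINE <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

#' Classify aligned site pairs into transitions and transversions
#'
#' Pairwise deletion: any column where either sequence has a gap, `N` or an
#' IUPAC ambiguity code is excluded from the comparison. Among the retained
#' pure-base columns, differences are split into transitions (`A<->G`,
#' `C<->T`) and transversions (all other differing pairs).
#'
#' @param a,b Aligned sequences of equal length, as strings or character
#'   vectors.
#' @return Object of class `site_pair_counts`: list with `n_compared`,
#'   `n_transitions`, `n_transversions`, the proportions `P` and `Q`, and
#'   `defined` (`FALSE` when no columns survive deletion, in which case
#'   `P` and `Q` are `NA` and the caller decides).
#' @export
classify_sites <- function(a, b) {
  a <- .char_vec(a); b <- .char_vec(b)
  if (length(a) != length(b))
    stop("sequences must have equal (aligned) length", call. = FALSE)
  ok <- a %in% PURE_BASES & b %in% PURE_BASES
  n <- sum(ok)
  if (n == 0L) {
    return(structure(list(n_compared = 0L, n_transitions = 0L,
                          n_transversions = 0L, P = NA_real_, Q = NA_real_,
                          defined = FALSE), class = "site_pair_counts"))
  }
  ai <- a[ok]; bi <- b[ok]
  diff <- ai != bi
  ts <- diff & (.IS_PURINE[ai] == .IS_PURINE[bi])
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  structure(list(n_compared = n, n_transitions = n_ts, n_transversions = n_tv,
                 P = n_ts / n, Q = n_tv / n, defined = TRUE),
            class = "site_pair_counts")
}

#' @export
print.site_pair_counts <- function(x, ...) {
  cat("site pair counts: ", x$n_compared, " compared, ",
      x$n_transitions, " transitions, ", x$n_transversions,
      " transversions (P = ", format(x$P, digits = 4),
      ", Q = ", format(x$Q, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Kimura two-parameter distance from site counts
#'
#' Evaluates `d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]` in substitutions
#' per site. The estimator is undefined (saturated) when `1 - 2P - Q <= 0`
#' or `1 - 2Q <= 0`; such pairs return `NA` with a `reason` attribute
#' (`"saturated"`), as do pairs with no comparable sites (`"no_sites"`).
#'
#' @param counts A `site_pair_counts` object from [classify_sites], or the
#'   transition proportion `P` as a plain number.
#' @param Q Transversion proportion, required when `counts` is numeric.
#' @return Distance in substitutions/site, or `NA_real_` with attribute
#'   `reason` when undefined.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (inherits(counts, "site_pair_counts")) {
    if (!counts$defined)
      return(structure(NA_real_, reason = "no_sites"))
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
    if (is.null(Q)) stop("supply Q when P is given as a number", call. = FALSE)
  }
  if (is.na(P) || is.na(Q)) return(structure(NA_real_, reason = "no_sites"))
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(structure(NA_real_, reason = "saturated"))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#'
#' Applies [classify_sites] + [k2p_distance] to every unordered pair of
#' rows. Undefined entries (saturated pairs, or pairs with zero overlap
#' after deletion) are `NA` in the matrix and listed, with their reason, in
#' the `undefined_pairs` attribute; downstream summaries exclude them and
#' the NJ module refuses matrices containing them.
#'
#' @param aln A `labeled_alignment`.
#' @param pairwise_deletion If `TRUE` (default) gap/ambiguous columns are
#'   dropped per pair; if `FALSE` (complete deletion) every column
#'   containing any gap or ambiguity in any sequence is dropped once for
#'   all pairs.
#' @return Symmetric numeric matrix (substitutions/site, zero diagonal)
#'   with sequence ids as dimnames and attributes `n_compared` (matrix of
#'   per-pair compared sites) and `undefined_pairs` (data frame `id_a`,
#'   `id_b`, `reason`).
#' @export
k2p_matrix <- function(aln, pairwise_deletion = TRUE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  mat <- aln$seq
  if (nrow(mat) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (!pairwise_deletion) {
    keep <- colSums(!apply(mat, 2L, `%in%`, PURE_BASES)) == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  ids <- rownames(mat)
  # integer coding: 1..4 for A,C,G,T; NA for everything else
  code <- matrix(match(mat, PURE_BASES), n, ncol(mat))
  purine <- matrix(.IS_PURINE[mat], n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ncmp <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  diag(ncmp) <- ncol(mat)
  undef <- list()
  for (i in seq_len(n - 1L)) {
    ci <- code[i, ]; pi <- purine[i, ]
    for (j in (i + 1L):n) {
      cj <- code[j, ]
      ok <- !is.na(ci) & !is.na(cj)
      m <- sum(ok)
      ncmp[i, j] <- ncmp[j, i] <- m
      if (m == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[[length(undef) + 1L]] <- c(ids[i], ids[j], "no_sites")
        next
      }
      diff <- ok & ci != cj
      nd <- sum(diff)
      n_ts <- if (nd) sum(pi[diff] == purine[j, diff]) else 0L
      P <- n_ts / m
      Q <- (nd - n_ts) / m
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[[length(undef) + 1L]] <- c(ids[i], ids[j], "saturated")
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
      }
    }
  }
  undef_df <- if (length(undef)) {
    tmp <- do.call(rbind, undef)
    data.frame(id_a = tmp[, 1L], id_b = tmp[, 2L], reason = tmp[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id_a = character(), id_b = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  attr(d, "n_compared") <- ncmp
  attr(d, "undefined_pairs") <- undef_df
  d
}

#' Mean pairwise distance
#'
#' Arithmetic mean over the defined off-diagonal entries, each unordered
#' pair counted once. The number of undefined (excluded) pairs is reported
#' in attribute `n_undefined`, the number averaged in `n_pairs`.
#'
#' @param m Distance matrix (as from [k2p_matrix]).
#' @param subset Optional character vector of ids restricting the mean.
#' @param percent Report the mean as a percentage (`d * 100`).
#' @return Numeric mean with attributes `n_pairs` and `n_undefined`.
#' @export
mean_pairwise_distance <- function(m, subset = NULL, percent = FALSE) {
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(m))
    if (length(missing))
      stop("subset id(s) not in matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- m[subset, subset, drop = FALSE]
  }
  vals <- m[upper.tri(m)]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no defined off-diagonal pairs to average", call. = FALSE)
  out <- mean(vals)
  if (percent) out <- out * 100
  structure(out, n_pairs = length(vals), n_undefined = n_undef)
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param m Distance matrix with dimnames.
#' @param path Output file.
#' @param digits Significant digits (default 6). Undefined entries are
#'   written as `NA` (with a warning), which standard PHYLIP consumers will
#'   reject; exclude saturated pairs first for interoperability.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(m, path, digits = 6L) {
  ids <- rownames(m)
  if (anyNA(m)) warning("matrix contains undefined entries; written as NA")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(format(ids[i], width = 12L),
          paste(formatC(m[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1L))
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#' @param path File in square PHYLIP format (count line, then one labeled
#'   row per sequence).
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  toks <- strsplit(trimws(lines[1L + seq_len(n)]), "[[:space:]]+")
  ids <- vapply(toks, `[`, character(1L), 1L)
  m <- t(vapply(toks, function(x) as.numeric(x[-1L]), numeric(n)))
  dimnames(m) <- list(ids, ids)
  m
}

#' Long-format export of a distance matrix
#'
#' One row per unordered pair: `id_a`, `id_b`, `d`, `n_compared` (when the
#' matrix carries that attribute) and `flag` (`"ok"`, `"saturated"` or
#' `"no_sites"`).
#'
#' @param m Distance matrix from [k2p_matrix].
#' @param path Optional TSV output file.
#' @return Data frame, invisibly when `path` is given.
#' @export
distance_long_table <- function(m, path = NULL) {
  ids <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ncmp <- attr(m, "n_compared")
  undef <- attr(m, "undefined_pairs")
  out <- data.frame(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
                    d = m[idx],
                    n_compared = if (is.null(ncmp)) NA_integer_ else ncmp[idx],
                    flag = "ok", stringsAsFactors = FALSE)
  if (!is.null(undef) && nrow(undef)) {
    key <- paste(out$id_a, out$id_b)
    ukey <- c(paste(undef$id_a, undef$id_b), paste(undef$id_b, undef$id_a))
    ureason <- rep(undef$reason, 2L)
    hit <- match(key, ukey)
    out$flag[!is.na(hit)] <- ureason[hit[!is.na(hit)]]
  } else {
    out$flag[is.na(out$d)] <- "undefined"
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
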