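# Barcode-gap and best-compromise-threshold analysis.
#
# Distances are split into intraspecific and interspecific sets using the
# species labels as ground truth. Two cumulative error curves are scanned
# over candidate thresholds t:
#   e_intra(t) = fraction of intraspecific distances  > t   (missed
#                conspecifics; non-increasing in t)
#   e_inter(t) = fraction of interspecific distances <= t   (admitted
#                heterospecifics; non-decreasing in t)
# The best compromise threshold (BCTh) minimizes their sum — graphically,
# the intersection of the two cumulative frequency curves.

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Every defined unordered pair lands in exactly one set: `intra` when both
#' ids share a species label, `inter` otherwise. Singleton species
#' contribute only interspecific pairs. Undefined (saturated/no-overlap)
#' distances are excluded and counted.
#'
#' @param m Distance matrix (as from [k2p_matrix]).
#' @param labels Named character vector mapping every id in `m` to a
#'   non-empty species label (e.g. from [species_labels]).
#' @return Object of class `distance_partition`: list with data frames
#'   `intra` and `inter` (columns `id_a`, `id_b`, `d`) and `n_undefined`.
#' @export
partition_distances <- function(m, labels) {
  ids <- rownames(m)
  lab <- labels[ids]
  if (anyNA(lab) || any(!nzchar(lab)))
    stop("unlabeled id(s): ",
         paste(ids[is.na(lab) | !nzchar(lab)], collapse = ", "), call. = FALSE)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  d <- m[idx]
  defined <- !is.na(d)
  same <- lab[idx[, 1L]] == lab[idx[, 2L]]
  mk <- function(sel) data.frame(id_a = ids[idx[sel, 1L]],
                                 id_b = ids[idx[sel, 2L]],
                                 d = d[sel], stringsAsFactors = FALSE)
  structure(list(intra = mk(defined & same),
                 inter = mk(defined & !same),
                 n_undefined = sum(!defined)),
            class = "distance_partition")
}

#' @export
print.distance_partition <- function(x, ...) {
  cat("distance partition: ", nrow(x$intra), " intraspecific, ",
      nrow(x$inter), " interspecific pairs (", x$n_undefined,
      " undefined excluded)\n", sep = "")
  invisible(x)
}

#' Histogram table with half-open bins
#'
#' Bins are `[k*w, (k+1)*w)`: a value exactly on an edge falls in the upper
#' bin. Counts always sum to the number of input distances.
#'
#' @param distances Numeric vector of distances (substitutions/site).
#' @param bin_width Positive bin width; default 0.005 (0.5%).
#' @return Data frame with `bin_lower`, `bin_upper`, `count`.
#' @export
histogram_bins <- function(distances, bin_width = 0.005) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be > 0", call. = FALSE)
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0L) {
    warning("no distances to bin; empty histogram")
    return(data.frame(bin_lower = numeric(), bin_upper = numeric(),
                      count = integer()))
  }
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  k <- floor(distances / bin_width)
  nb <- max(k) + 1L
  counts <- tabulate(k + 1L, nbins = nb)
  data.frame(bin_lower = (seq_len(nb) - 1L) * bin_width,
             bin_upper = seq_len(nb) * bin_width,
             count = counts)
}

#' Barcode gap report
#'
#' The barcode gap exists iff the smallest interspecific distance strictly
#' exceeds the largest intraspecific distance; the gap interval is then
#' `(max_intra, min_inter)`.
#'
#' @param p A `distance_partition`.
#' @return Object of class `gap_report`: list with `max_intra`,
#'   `min_inter`, `has_gap`, `gap_interval` (`NULL` when absent) and
#'   `status` (`"ok"`, or `"undefined_no_intra"` when every species is a
#'   singleton and the gap cannot be assessed).
#' @export
barcode_gap <- function(p) {
  stopifnot(inherits(p, "distance_partition"))
  if (nrow(p$inter) == 0L)
    stop("no interspecific distances; need at least 2 species", call. = FALSE)
  if (nrow(p$intra) == 0L) {
    return(structure(list(max_intra = NA_real_, min_inter = min(p$inter$d),
                          has_gap = NA, gap_interval = NULL,
                          status = "undefined_no_intra"),
                     class = "gap_report"))
  }
  max_intra <- max(p$intra$d)
  min_inter <- min(p$inter$d)
  has_gap <- min_inter > max_intra
  structure(list(max_intra = max_intra, min_inter = min_inter,
                 has_gap = has_gap,
                 gap_interval = if (has_gap) c(max_intra, min_inter) else NULL,
                 status = "ok"),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (identical(x$status, "undefined_no_intra")) {
    cat("barcode gap: undefined (no intraspecific pairs)\n")
  } else if (x$has_gap) {
    cat(sprintf("barcode gap: yes, (%.4g, %.4g) [%.2f%% - %.2f%%]\n",
                x$max_intra, x$min_inter,
                100 * x$max_intra, 100 * x$min_inter))
  } else {
    cat(sprintf("barcode gap: no (max intra %.4g >= min inter %.4g)\n",
                x$max_intra, x$min_inter))
  }
  invisible(x)
}

.default_candidates <- function(pooled) {
  u <- sort(unique(pooled))
  rng <- max(u) - min(u)
  if (rng == 0) rng <- max(u[1L], 1e-8)  # degenerate: all distances equal
  mids <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric()
  c(min(u) - rng / 2, mids, max(u) + rng / 2)
}

#' Cumulative error curves over candidate thresholds
#'
#' By default candidates are the midpoints between consecutive pooled
#' sorted unique distances, plus one candidate below the pooled minimum and
#' one above the pooled maximum — the exact optimum of the step function
#' without a resolution parameter. A fixed-step grid can be supplied via
#' `candidates` (e.g. `seq(0, 0.3, by = 1e-4)`) for figure replication.
#'
#' @param p A `distance_partition` with non-empty intra and inter sets.
#' @param candidates Optional ascending numeric vector of thresholds.
#' @return Data frame (class `threshold_scan`) with `threshold`, `e_intra`,
#'   `e_inter`, `total`, and attributes `n_intra`, `n_inter`, `max_intra`,
#'   `min_inter`.
#' @export
error_curves <- function(p, candidates = NULL) {
  stopifnot(inherits(p, "distance_partition"))
  if (nrow(p$intra) == 0L)
    stop("no intraspecific distances (all species singletons); ",
         "error curves are undefined", call. = FALSE)
  if (nrow(p$inter) == 0L)
    stop("no interspecific distances", call. = FALSE)
  intra <- p$intra$d
  inter <- p$inter$d
  if (is.null(candidates)) candidates <- .default_candidates(c(intra, inter))
  candidates <- sort(candidates)
  e_intra <- vapply(candidates, function(t) mean(intra > t), numeric(1L))
  e_inter <- vapply(candidates, function(t) mean(inter <= t), numeric(1L))
  out <- data.frame(threshold = candidates, e_intra = e_intra,
                    e_inter = e_inter, total = e_intra + e_inter)
  class(out) <- c("threshold_scan", "data.frame")
  attr(out, "n_intra") <- length(intra)
  attr(out, "n_inter") <- length(inter)
  attr(out, "max_intra") <- max(intra)
  attr(out, "min_inter") <- min(inter)
  out
}

#' Best compromise threshold (BCTh)
#'
#' The smallest candidate attaining the minimum total error
#' `e_intra + e_inter`; all tied optima are reported. When the minimum is
#' zero (a true barcode gap) the whole zero-error plateau
#' `(max_intra, min_inter)` is reported alongside. A scan whose total error
#' is constant over all candidates carries no information and is flagged
#' degenerate.
#'
#' @param scan A `threshold_scan` from [error_curves].
#' @return Object of class `bcth_result`: list with `bcth`,
#'   `min_total_error`, `tie_candidates`, `plateau` (`NULL` unless the
#'   minimum is zero) and `degenerate`.
#' @export
best_compromise_threshold <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  tot <- scan$total
  mn <- min(tot)
  opt <- abs(tot - mn) < 1e-12
  ties <- scan$threshold[opt]
  plateau <- NULL
  if (mn < 1e-12)
    plateau <- c(attr(scan, "max_intra"), attr(scan, "min_inter"))
  structure(list(bcth = min(ties), min_total_error = mn,
                 tie_candidates = ties, plateau = plateau,
                 degenerate = all(opt)),
            class = "bcth_result")
}

#' @export
print.bcth_result <- function(x, ...) {
  cat(sprintf("BCTh = %.6g (%.4g%%), min total error = %.4g\n",
              x$bcth, 100 * x$bcth, x$min_total_error))
  if (length(x$tie_candidates) > 1L)
    cat("  tied optima at:", paste(signif(x$tie_candidates, 6), collapse = ", "),
        "\n")
  if (!is.null(x$plateau))
    cat(sprintf("  zero-error plateau: (%.6g, %.6g)\n",
                x$plateau[1L], x$plateau[2L]))
  if (x$degenerate)
    cat("  degenerate scan: total error constant over all candidates\n")
  invisible(x)
}
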