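# Best match (BM) and best close-match (BCM) species identification.
#
# Leave-one-out: each sequence is queried against all others in the same
# reference set. BM assigns the species of the nearest sequence(s); exact
# distance ties are pooled, so a query whose tied nearest neighbours span
# several species (the shared-haplotype case) is "ambiguous". BCM first
# rejects queries whose nearest match lies strictly beyond the threshold
# ("no match closer than threshold"); a distance exactly equal to the
# threshold still matches.

ID_CATEGORIES <- c("correct", "ambiguous", "incorrect",
                   "no_match_closer_than_threshold")

#' Remove singleton species before BM/BCM analysis
#'
#' Species represented by a single sequence cannot have a conspecific match
#' and would be scored incorrect by construction, so they are removed
#' before identification.
#'
#' @param labels Named character vector (id -> species).
#' @return List with `retained_ids`, `removed_ids` and `removed_species`.
#'   Errors when every species is a singleton, since BM/BCM is then
#'   inapplicable.
#' @export
filter_singletons <- function(labels) {
  if (is.null(names(labels)) || any(!nzchar(labels)))
    stop("'labels' must be a named vector of non-empty species labels",
         call. = FALSE)
  tab <- table(labels)
  removed_species <- names(tab)[tab < 2L]
  removed <- names(labels)[labels %in% removed_species]
  retained <- setdiff(names(labels), removed)
  if (length(retained) == 0L)
    stop("every species is a singleton: best match / best close-match ",
         "identification is inapplicable (no query has a conspecific)",
         call. = FALSE)
  list(retained_ids = retained, removed_ids = removed,
       removed_species = removed_species)
}

.id_record <- function(query_id, true_species, best_distance,
                       match_species, category, reason = NA_character_) {
  data.frame(query_id = query_id, true_species = true_species,
             best_distance = best_distance,
             best_match_species = paste(sort(unique(match_species)),
                                        collapse = ";"),
             category = category, reason = reason, stringsAsFactors = FALSE)
}

.bm_core <- function(query_id, m, labels, tie_tol) {
  if (!query_id %in% rownames(m))
    stop("query '", query_id, "' not in distance matrix", call. = FALSE)
  truth <- labels[[query_id]]
  d <- m[query_id, ]
  d <- d[names(d) != query_id]          # leave-one-out
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    return(.id_record(query_id, truth, NA_real_, character(),
                      NA_character_, "all_distances_undefined"))
  best <- min(d)
  hits <- names(d)[d <= best + tie_tol]
  set <- unique(labels[hits])
  category <- if (!truth %in% set) "incorrect"
  else if (length(set) > 1L) "ambiguous"
  else "correct"
  .id_record(query_id, truth, best, set, category)
}

#' Best match identification of one query
#'
#' @param query_id Id of the query sequence (must be labeled).
#' @param m Distance matrix containing the query and at least one other
#'   sequence.
#' @param labels Named character vector (id -> species) covering all ids.
#' @param tie_tol Distances within `tie_tol` of the minimum are pooled into
#'   the best-match set; default 0 (exact ties only, the operative case
#'   being identical haplotypes at distance 0).
#' @return One-row data frame: `query_id`, `true_species`, `best_distance`,
#'   `best_match_species` (`;`-separated), `category`, `reason` (`NA`
#'   unless no distance to the query is defined).
#' @export
best_match <- function(query_id, m, labels, tie_tol = 0) {
  .bm_core(query_id, m, labels, tie_tol)
}

#' Best close-match identification of one query
#'
#' As [best_match], but a query whose best distance strictly exceeds
#' `threshold` is categorized `no_match_closer_than_threshold`; a best
#' distance exactly equal to the threshold still matches. With
#' `threshold = Inf` BCM reduces to BM exactly.
#'
#' @inheritParams best_match
#' @param threshold Non-negative distance threshold (typically the BCTh).
#' @return One-row data frame as in [best_match].
#' @export
best_close_match <- function(query_id, m, labels, threshold, tie_tol = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single non-negative number", call. = FALSE)
  rec <- .bm_core(query_id, m, labels, tie_tol)
  if (!is.na(rec$best_distance) && rec$best_distance > threshold) {
    rec$category <- "no_match_closer_than_threshold"
    rec$best_match_species <- ""
  }
  rec
}

#' Identification success table (BM and BCM)
#'
#' Applies the singleton filter, queries every retained sequence in
#' leave-one-out fashion under both criteria, and tallies the outcomes as
#' counts and percentages per category (percentages on the number of
#' queries, reported to 2 decimals).
#'
#' @param m Distance matrix over the full data set.
#' @param labels Named character vector (id -> species).
#' @param threshold BCM threshold (typically `best_compromise_threshold()`'s
#'   `bcth`).
#' @param tie_tol Passed to [best_match] / [best_close_match].
#' @param drop_singletons Apply the singleton filter first (default
#'   `TRUE`; the filter errors when all species are singletons).
#' @return Object of class `success_table`: list with `per_query` (one row
#'   per query with both categories), `summary` (criterion x category
#'   counts and percentages), `threshold`, `n_queries`,
#'   `removed_species`.
#' @export
identification_summary <- function(m, labels, threshold, tie_tol = 0,
                                   drop_singletons = TRUE) {
  removed_species <- character()
  ids <- intersect(rownames(m), names(labels))
  labels <- labels[ids]
  if (drop_singletons) {
    flt <- filter_singletons(labels)
    ids <- flt$retained_ids
    removed_species <- flt$removed_species
  }
  sub <- m[ids, ids, drop = FALSE]
  lab <- labels[ids]
  bm <- do.call(rbind, lapply(ids, best_match, m = sub, labels = lab,
                              tie_tol = tie_tol))
  bcm <- do.call(rbind, lapply(ids, best_close_match, m = sub, labels = lab,
                               threshold = threshold, tie_tol = tie_tol))
  per_query <- data.frame(query_id = bm$query_id,
                          true_species = bm$true_species,
                          best_distance = bm$best_distance,
                          best_match_species = bm$best_match_species,
                          category_bm = bm$category,
                          category_bcm = bcm$category,
                          stringsAsFactors = FALSE)
  tally <- function(cat) {
    counts <- vapply(ID_CATEGORIES, function(k) sum(cat == k, na.rm = TRUE),
                     integer(1L))
    data.frame(category = ID_CATEGORIES, count = counts,
               percent = round(100 * counts / length(cat), 2L),
               stringsAsFactors = FALSE)
  }
  s_bm <- cbind(criterion = "BM", tally(per_query$category_bm))
  s_bm <- s_bm[s_bm$category != "no_match_closer_than_threshold", ]
  s_bcm <- cbind(criterion = "BCM", tally(per_query$category_bcm))
  structure(list(per_query = per_query,
                 summary = rbind(s_bm, s_bcm),
                 threshold = threshold,
                 n_queries = length(ids),
                 removed_species = removed_species),
            class = "success_table")
}

#' @export
print.success_table <- function(x, ...) {
  cat("identification success over ", x$n_queries, " queries (BCM threshold ",
      sprintf("%.4g%%", 100 * x$threshold), ")\n", sep = "")
  if (length(x$removed_species))
    cat("  singleton species removed: ",
        paste(x$removed_species, collapse = ", "), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
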