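# Contamination screening of clone sequences against a labeled reference
# panel, formalizing the visual reading of a reference NJ tree: a clone is
# called on-target (e.g. Platyhelminthes) when its evidence — nearest
# reference by distance, and the group purity of the surrounding clades —
# points to the target group.

#' Assign queries to the group of their nearest reference
#'
#' Each query receives the group label of its closest reference sequence
#' (minimum defined distance over the panel). Exact distance ties spanning
#' more than one group yield `"unassigned"`.
#'
#' @param m Distance matrix over queries and references combined.
#' @param query_ids Ids of the query (clone) sequences.
#' @param ref_groups Named character vector (reference id -> group label);
#'   every reference must carry a non-empty group.
#' @return Data frame with `query_id`, `nearest_ref_id`,
#'   `nearest_ref_distance`, `nearest_group` (`"unassigned"` on cross-group
#'   ties or when no distance to any reference is defined) and `reason`.
#' @export
assign_nearest_reference <- function(m, query_ids, ref_groups) {
  ref_ids <- names(ref_groups)
  if (is.null(ref_ids) || length(ref_ids) == 0L)
    stop("'ref_groups' must be a non-empty named vector", call. = FALSE)
  bad <- ref_ids[!nzchar(ref_groups)]
  if (length(bad))
    stop("reference(s) without group label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c(query_ids, ref_ids), rownames(m))
  if (length(missing))
    stop("id(s) not in distance matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(unique(ref_groups)) == 1L)
    warning("reference panel contains a single group; every query will be ",
            "assigned to it")
  rows <- lapply(query_ids, function(q) {
    d <- stats::setNames(m[q, ref_ids], ref_ids)
    d <- d[names(d) != q]
    d <- d[!is.na(d)]
    if (length(d) == 0L)
      return(data.frame(query_id = q, nearest_ref_id = NA_character_,
                        nearest_ref_distance = NA_real_,
                        nearest_group = "unassigned",
                        reason = "no_defined_distance",
                        stringsAsFactors = FALSE))
    best <- min(d)
    hits <- names(d)[d == best]
    groups <- unique(unname(ref_groups[hits]))
    if (length(groups) > 1L)
      return(data.frame(query_id = q, nearest_ref_id = hits[1L],
                        nearest_ref_distance = best,
                        nearest_group = "unassigned",
                        reason = "tie_across_groups",
                        stringsAsFactors = FALSE))
    data.frame(query_id = q, nearest_ref_id = hits[1L],
               nearest_ref_distance = best, nearest_group = groups,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-edge tip sets of an (un)rooted phylo, as indices into tip labels
.edge_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)   # tip sets per internal node, root first
  lapply(seq_len(nrow(phy$edge)), function(k) {
    child <- phy$edge[k, 2L]
    if (child <= ntip) child else pp[[child - ntip]]
  })
}

#' Assign queries to groups by clade membership in a tree
#'
#' Works on bipartitions of the unrooted tree: every edge splits the
#' leaves in two, and the side containing the query is a "subtree around
#' the query". Scanning these from the smallest outward, the smallest
#' subtree(s) containing the query and at least one reference decide: if
#' their references all carry one group (equivalently, the maximal
#' pure-group subtree around the query is non-empty), the query takes that
#' group; if the smallest reference-containing subtree already mixes
#' groups — or equally small subtrees disagree — the query is
#' `"unassigned"`.
#'
#' @param phy A `phylo` tree over queries and references (from
#'   [neighbor_joining]).
#' @param ref_groups Named character vector (reference id -> group).
#' @param query_ids Query tip labels.
#' @return Data frame with `query_id` and `clade_group`.
#' @export
assign_by_clade <- function(phy, ref_groups, query_ids) {
  stopifnot(inherits(phy, "phylo"))
  tips <- phy$tip.label
  ref_idx <- match(names(ref_groups), tips)
  if (all(is.na(ref_idx)))
    stop("tree contains no reference leaves", call. = FALSE)
  ref_groups <- ref_groups[!is.na(ref_idx)]
  ref_idx <- ref_idx[!is.na(ref_idx)]
  ntip <- length(tips)
  is_ref <- logical(ntip); is_ref[ref_idx] <- TRUE
  grp <- rep(NA_character_, ntip); grp[ref_idx] <- unname(ref_groups)
  sets <- .edge_tip_sets(phy)

  assign_one <- function(q) {
    qi <- match(q, tips)
    if (is.na(qi)) stop("query '", q, "' not in tree", call. = FALSE)
    # query-side of every bipartition, as logical tip masks
    masks <- lapply(sets, function(s) {
      msk <- logical(ntip); msk[s] <- TRUE
      if (!msk[qi]) msk <- !msk
      msk
    })
    with_ref <- vapply(masks, function(m) any(m & is_ref), logical(1L))
    masks <- masks[with_ref]
    sizes <- vapply(masks, sum, integer(1L))
    # smallest subtree(s) containing the query and at least one reference;
    # ties in size must agree on a single group
    smallest <- masks[sizes == min(sizes)]
    groups <- unique(unlist(lapply(smallest,
                                   function(m) unique(grp[m & is_ref]))))
    if (length(groups) == 1L) groups else "unassigned"
  }

  data.frame(query_id = query_ids,
             clade_group = vapply(query_ids, assign_one, character(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a contamination screen
#'
#' Combines the per-query assignments into group tallies and on-target
#' counts. When both the nearest-reference and the clade rule are present
#' the clade assignment is authoritative and disagreements are flagged;
#' with a single rule that rule decides.
#'
#' @param assignments Data frame with `query_id` and at least one of
#'   `nearest_group` / `clade_group` (merge the outputs of
#'   [assign_nearest_reference] and [assign_by_clade]).
#' @param target_group Declared on-target group label (e.g.
#'   `"Platyhelminthes"`).
#' @param species_labels Optional named vector (query id -> species) for
#'   counting distinct on-target species.
#' @return Object of class `screen_report`: list with `assignments` (input
#'   plus `assigned_group`, `on_target`, `disagreement`), `group_tally`,
#'   `n_queries`, `n_on_target`, `n_on_target_species` (`NA` without
#'   species labels) and `target_group`.
#' @export
screen_report <- function(assignments, target_group, species_labels = NULL) {
  a <- as.data.frame(assignments)
  has_near <- "nearest_group" %in% names(a)
  has_clade <- "clade_group" %in% names(a)
  if (!has_near && !has_clade)
    stop("'assignments' needs a nearest_group and/or clade_group column",
         call. = FALSE)
  if (nrow(a) == 0L) {
    return(structure(list(assignments = a,
                          group_tally = data.frame(group = character(),
                                                   count = integer()),
                          n_queries = 0L, n_on_target = 0L,
                          n_on_target_species = if (is.null(species_labels))
                            NA_integer_ else 0L,
                          target_group = target_group),
                     class = "screen_report"))
  }
  a$assigned_group <- if (has_clade) a$clade_group else a$nearest_group
  a$disagreement <- if (has_near && has_clade)
    a$nearest_group != a$clade_group else FALSE
  a$on_target <- a$assigned_group == target_group
  tal <- as.data.frame(table(group = a$assigned_group),
                       stringsAsFactors = FALSE)
  names(tal) <- c("group", "count")
  n_sp <- NA_integer_
  if (!is.null(species_labels)) {
    sp <- species_labels[a$query_id[a$on_target]]
    n_sp <- length(unique(sp[!is.na(sp) & nzchar(sp)]))
  }
  structure(list(assignments = a, group_tally = tal,
                 n_queries = nrow(a), n_on_target = sum(a$on_target),
                 n_on_target_species = n_sp, target_group = target_group),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("contamination screen: ", x$n_queries, " queries, ", x$n_on_target,
      " on-target (", x$target_group, ")", sep = "")
  if (!is.na(x$n_on_target_species))
    cat(", ", x$n_on_target_species, " distinct on-target species", sep = "")
  cat("\n")
  print(x$group_tally, row.names = FALSE)
  ndis <- sum(x$assignments$disagreement, na.rm = TRUE)
  if (ndis) cat(ndis, "query/queries with rule disagreement flagged\n")
  invisible(x)
}
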