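# Orchestration of the two workflows: marker evaluation (distances ->
# partition -> histograms -> gap -> BCTh -> BM/BCM success table) and the
# contamination screen (combined matrix -> NJ tree -> assignment rules ->
# screen report). Each run writes a bundle of machine-readable tables plus
# a manifest, so a bundle can be reproduced from its manifest alone.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.prep_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  invisible(out_dir)
}

#' Run the marker-evaluation workflow
#'
#' Chains the full barcoding evaluation for one marker: K2P distance
#' matrix, intra/interspecific partition, histogram tables, barcode-gap
#' report, threshold scan and BCTh, singleton filter, and the BM/BCM
#' identification success table. Writes TSV/JSON tables plus a
#' `manifest.json`; distances are substitutions/site in machine tables and
#' percent in the human-facing summary (the unit is stated in each
#' header).
#'
#' Degenerate inputs are handled explicitly rather than silently: with no
#' intraspecific pairs (every species a singleton) the gap, scan and BCTh
#' are skipped, and BM/BCM is skipped because no query can have a
#' conspecific match; the manifest records the rationale.
#'
#' @param aln A species-labeled [labeled_alignment].
#' @param out_dir Output directory (created if needed).
#' @param marker Marker name used in the manifest.
#' @param bin_width Histogram bin width (substitutions/site).
#' @param threshold BCM threshold; `NULL` (default) uses the computed
#'   BCTh.
#' @param pairwise_deletion Passed to [k2p_matrix].
#' @return Invisibly, a list with every intermediate result (`matrix`,
#'   `partition`, `gap`, `scan`, `bcth`, `success`, `manifest`).
#' @export
run_marker_evaluation <- function(aln, out_dir, marker = "marker",
                                  bin_width = 0.005, threshold = NULL,
                                  pairwise_deletion = TRUE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  labels <- species_labels(aln)
  if (any(!nzchar(labels)))
    stop("marker evaluation needs species labels on every sequence",
         call. = FALSE)
  .prep_out_dir(out_dir)

  m <- k2p_matrix(aln, pairwise_deletion = pairwise_deletion)
  n_undef <- nrow(attr(m, "undefined_pairs"))
  message("stage distance: ", nrow(m), " sequences, ",
          sum(upper.tri(m)) - n_undef, " defined pairs, ", n_undef,
          " undefined")
  distance_long_table(m, file.path(out_dir, "distances_long.tsv"))
  write_phylip_dist(m, file.path(out_dir, "distances.phylip"))

  part <- partition_distances(m, labels)
  message("stage partition: ", nrow(part$intra), " intraspecific, ",
          nrow(part$inter), " interspecific pairs")
  tag <- function(df, type) {
    if (nrow(df)) cbind(type = type, df)
    else cbind(type = character(), df)
  }
  part_tab <- rbind(tag(part$intra, "intraspecific"),
                    tag(part$inter, "interspecific"))
  names(part_tab) <- c("type", "id_a", "id_b", "d_subst_per_site")
  .write_tsv(part_tab, file.path(out_dir, "partition.tsv"))

  hist_tab <- rbind(
    tag(suppressWarnings(histogram_bins(part$intra$d, bin_width)),
        "intraspecific"),
    tag(suppressWarnings(histogram_bins(part$inter$d, bin_width)),
        "interspecific"))
  .write_tsv(hist_tab, file.path(out_dir, "histogram.tsv"))

  gap <- scan <- bcth <- success <- NULL
  skip_reason <- NULL
  if (nrow(part$intra) == 0L) {
    skip_reason <- paste("all species are singletons: barcode gap, BCTh and",
                         "BM/BCM identification are undefined (no query has",
                         "a conspecific in the dataset)")
    message("stage gap/threshold/identify: skipped - ", skip_reason)
  } else {
    gap <- barcode_gap(part)
    .write_json(list(max_intra = gap$max_intra, min_inter = gap$min_inter,
                     has_gap = gap$has_gap,
                     gap_interval = gap$gap_interval, status = gap$status),
                file.path(out_dir, "gap.json"))
    message("stage gap: ", if (isTRUE(gap$has_gap)) "barcode gap present"
            else "no barcode gap")

    scan <- error_curves(part)
    scan_tab <- as.data.frame(scan)
    names(scan_tab) <- c("threshold_subst_per_site", "e_intra", "e_inter",
                         "total")
    .write_tsv(scan_tab, file.path(out_dir, "threshold_scan.tsv"))
    bcth <- best_compromise_threshold(scan)
    .write_json(list(bcth = bcth$bcth, bcth_percent = 100 * bcth$bcth,
                     min_total_error = bcth$min_total_error,
                     tie_candidates = bcth$tie_candidates,
                     plateau = bcth$plateau, degenerate = bcth$degenerate),
                file.path(out_dir, "bcth.json"))
    message("stage threshold: BCTh = ", signif(bcth$bcth, 6), " (",
            signif(100 * bcth$bcth, 4), "%)")

    thr <- if (is.null(threshold)) bcth$bcth else threshold
    success <- identification_summary(m, labels, threshold = thr)
    message("stage identify: ", success$n_queries, " queries, ",
            length(success$removed_species), " singleton species removed")
    .write_tsv(success$per_query, file.path(out_dir, "per_query.tsv"))
    sum_tab <- success$summary
    .write_tsv(sum_tab, file.path(out_dir, "summary.tsv"))
    .write_json(list(threshold = success$threshold,
                     threshold_percent = 100 * success$threshold,
                     n_queries = success$n_queries,
                     removed_species = success$removed_species,
                     table = sum_tab),
                file.path(out_dir, "summary.json"))
  }

  manifest <- list(
    workflow = "marker_evaluation",
    package = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    marker = marker,
    n_sequences = n_sequences(aln),
    alignment_length = alignment_length(aln),
    n_species = length(unique(labels)),
    parameters = list(bin_width = bin_width,
                      threshold = threshold,
                      pairwise_deletion = pairwise_deletion),
    counts = list(pairs_defined = sum(upper.tri(m)) - n_undef,
                  pairs_undefined = n_undef,
                  intra_pairs = nrow(part$intra),
                  inter_pairs = nrow(part$inter)),
    skipped = skip_reason)
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(matrix = m, partition = part, gap = gap, scan = scan,
                 bcth = bcth, success = success, manifest = manifest))
}

#' Run the contamination-screen workflow
#'
#' Builds the combined K2P matrix over query clones and the labeled
#' reference panel, the NJ tree (written as Newick), applies both
#' assignment rules (nearest reference and clade membership) and writes the
#' per-clone report and group tally.
#'
#' @param aln Combined [labeled_alignment] of queries and references.
#' @param target_group Declared on-target group (e.g.
#'   `"Platyhelminthes"`).
#' @param out_dir Output directory.
#' @param query_ids Query ids; default: sequences with an empty group
#'   label.
#' @param ref_groups Named vector (reference id -> group); default: taken
#'   from the alignment's group labels. References lacking a group label
#'   are an error naming the offending records.
#' @param species_labels Optional named vector for on-target species
#'   counting; defaults to the alignment's species labels where non-empty.
#' @return Invisibly, a list with `matrix`, `tree`, `assignments`,
#'   `report`, `manifest`.
#' @export
run_contamination_screen <- function(aln, target_group, out_dir,
                                     query_ids = NULL, ref_groups = NULL,
                                     species_labels = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  grp <- group_labels(aln)
  if (is.null(query_ids)) query_ids <- names(grp)[!nzchar(grp)]
  if (is.null(ref_groups)) {
    ref_ids <- setdiff(names(grp), query_ids)
    no_grp <- ref_ids[!nzchar(grp[ref_ids])]
    if (length(no_grp))
      stop("reference record(s) without group label: ",
           paste(no_grp, collapse = ", "), call. = FALSE)
    ref_groups <- grp[ref_ids]
  }
  if (length(query_ids) == 0L)
    message("stage screen: no queries; empty report")
  .prep_out_dir(out_dir)

  m <- k2p_matrix(aln)
  if (anyNA(m))
    stop("combined matrix has undefined entries; remove saturated pairs ",
         "before screening", call. = FALSE)
  phy <- neighbor_joining(m)
  to_newick(phy, path = file.path(out_dir, "screen_tree.nwk"))

  near <- assign_nearest_reference(m, query_ids, ref_groups)
  clade <- assign_by_clade(phy, ref_groups, query_ids)
  assignments <- merge(near, clade, by = "query_id", sort = FALSE)
  if (is.null(species_labels)) {
    sp <- stats::setNames(aln$meta$species, aln$meta$seq_id)
    species_labels <- sp[nzchar(sp)]
  }
  report <- screen_report(assignments, target_group,
                          species_labels = species_labels)
  message("stage screen: ", report$n_queries, " clones, ",
          report$n_on_target, " on-target (", target_group, ")")
  .write_tsv(report$assignments, file.path(out_dir, "per_clone.tsv"))
  .write_json(list(target_group = target_group,
                   n_queries = report$n_queries,
                   n_on_target = report$n_on_target,
                   n_on_target_species = report$n_on_target_species,
                   group_tally = report$group_tally),
              file.path(out_dir, "tally.json"))

  manifest <- list(
    workflow = "contamination_screen",
    package = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    n_sequences = n_sequences(aln),
    alignment_length = alignment_length(aln),
    n_queries = length(query_ids),
    n_references = length(ref_groups),
    target_group = target_group,
    groups = sort(unique(unname(ref_groups))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(matrix = m, tree = phy, assignments = assignments,
                 report = report, manifest = manifest))
}
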