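# K2P sequence simulator: species-structured alignments with controllable
# intra/interspecific divergence, singletons, shared haplotypes and deeply
# diverged contaminant groups.
#
# The generating tree is a star phylogeny at both levels: a root sequence,
# species ancestors at branch length d_inter from the root, and individuals
# at d_intra from their ancestor. Sites evolve independently under the
# Kimura two-parameter model with transition/transversion rate ratio kappa,
# so the expected transition/transversion proportions on any path are
# available in closed form and the K2P estimator is exactly consistent with
# the generator.

#' Closed-form K2P substitution probabilities for a branch
#'
#' For a branch of length `d` (expected substitutions/site) under the
#' Kimura model with rate ratio `kappa = alpha/beta`, using
#' `alpha*t = d*kappa/(kappa+2)` and `beta*t = d/(kappa+2)` so the total
#' rate `(alpha + 2 beta) t` equals `d`:
#' `p_transversion = (1 - exp(-4 beta t)) / 2` (split equally over the two
#' transversion targets),
#' `p_transition = 1/4 + exp(-4 beta t)/4 - exp(-2 (alpha+beta) t)/2`,
#' and `p_same` the remainder, so the three sum to 1 exactly.
#'
#' @param d Branch length(s) in expected substitutions/site, `>= 0`.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @return List with `p_same`, `p_transition`, `p_transversion` (each the
#'   length of `d`).
#' @export
k2p_site_probs <- function(d, kappa = 2) {
  if (any(d < 0)) stop("'d' must be >= 0", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be a single positive number", call. = FALSE)
  bt <- d / (kappa + 2)
  at <- d * kappa / (kappa + 2)
  p_tv <- 0.5 * (1 - exp(-4 * bt))
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  list(p_same = 1 - p_ts - p_tv, p_transition = p_ts, p_transversion = p_tv)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_FIRST   <- c(A = "C", G = "C", C = "A", T = "A")
.TV_SECOND  <- c(A = "T", G = "T", C = "G", T = "G")

# evolve a character vector of pure bases along a branch of length d
.evolve <- function(x, d, kappa) {
  if (d == 0) return(x)
  pr <- k2p_site_probs(d, kappa)
  u <- stats::runif(length(x))
  out <- x
  ts <- u < pr$p_transition
  tv1 <- !ts & u < pr$p_transition + pr$p_transversion / 2
  tv2 <- !ts & !tv1 & u < pr$p_transition + pr$p_transversion
  out[ts] <- .TS_PARTNER[x[ts]]
  out[tv1] <- .TV_FIRST[x[tv1]]
  out[tv2] <- .TV_SECOND[x[tv2]]
  out
}

#' Simulate a species-structured alignment under the K2P model
#'
#' Root sequence uniform over `A/C/G/T`; each species ancestor evolves from
#' the root along `d_inter`; each individual evolves from its ancestor
#' along `d_intra`. Expected pairwise K2P distances are therefore
#' `2*d_intra` within species and `2*(d_inter + d_intra)` between species.
#' Species listed with one individual in `n_per_species` are singletons.
#'
#' Shared haplotypes (the case of two species sharing an identical marker
#' sequence) are injected over consecutive species pairs (1,2), (3,4), ...:
#' with `shared_haplotype_mode = "species"` every individual of both
#' species receives one common haplotype — the biologically motivated case
#' of a marker with no variation within or between the pair, which makes
#' every affected query ambiguous under best match; with `"individual"` a
#' single individual's sequence is copied into the second species, creating
#' exactly one zero interspecific distance.
#'
#' @param n_species Number of species.
#' @param n_per_species Individuals per species: a scalar or a
#'   length-`n_species` vector (entries of 1 create singletons).
#' @param seq_length Number of sites.
#' @param d_intra Ancestor-to-individual branch length
#'   (substitutions/site).
#' @param d_inter Root-to-species-ancestor branch length.
#' @param kappa Transition/transversion rate ratio.
#' @param shared_haplotype_pairs Number of species pairs forced to share a
#'   haplotype.
#' @param shared_haplotype_mode `"species"` (default) or `"individual"`;
#'   see Details.
#' @param gap_rate Optional column-wise gap injection rate: each column is
#'   selected with this probability and, within a selected column, each row
#'   is gapped with probability 1/2 — a stress test for pairwise deletion,
#'   not a biological indel model.
#' @param seed Optional integer; fixing it makes the output reproducible.
#' @return A [labeled_alignment] with attribute `truth` (list with the
#'   generating parameters and the shared-pair table).
#' @export
simulate_alignment <- function(n_species = 20, n_per_species = 5,
                               seq_length = 600, d_intra = 0.005,
                               d_inter = 0.10, kappa = 2,
                               shared_haplotype_pairs = 0,
                               shared_haplotype_mode = c("species",
                                                         "individual"),
                               gap_rate = 0, seed = NULL) {
  shared_haplotype_mode <- match.arg(shared_haplotype_mode)
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_species) == 1L)
    n_per_species <- rep(n_per_species, n_species)
  if (length(n_per_species) != n_species)
    stop("'n_per_species' must be a scalar or have length n_species",
         call. = FALSE)
  if (2L * shared_haplotype_pairs > n_species)
    stop("not enough species for ", shared_haplotype_pairs,
         " shared-haplotype pair(s)", call. = FALSE)
  stopifnot(seq_length >= 1, d_intra >= 0, d_inter >= 0)

  root <- sample(PURE_BASES, seq_length, replace = TRUE)
  species <- sprintf("species%02d", seq_len(n_species))
  seqs <- list(); sp_of <- character()
  for (s in seq_len(n_species)) {
    anc <- .evolve(root, d_inter, kappa)
    for (k in seq_len(n_per_species[s])) {
      id <- sprintf("%s_%d", species[s], k)
      seqs[[id]] <- .evolve(anc, d_intra, kappa)
      sp_of[id] <- species[s]
    }
  }
  shared <- NULL
  if (shared_haplotype_pairs > 0) {
    shared <- data.frame(species_a = species[2L * seq_len(shared_haplotype_pairs) - 1L],
                         species_b = species[2L * seq_len(shared_haplotype_pairs)],
                         stringsAsFactors = FALSE)
    for (p in seq_len(shared_haplotype_pairs)) {
      ids_a <- names(sp_of)[sp_of == shared$species_a[p]]
      ids_b <- names(sp_of)[sp_of == shared$species_b[p]]
      hap <- seqs[[ids_a[1L]]]
      if (shared_haplotype_mode == "species") {
        for (id in c(ids_a, ids_b)) seqs[[id]] <- hap
      } else {
        seqs[[ids_b[1L]]] <- hap
      }
    }
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  if (gap_rate > 0) {
    gcols <- which(stats::runif(seq_length) < gap_rate)
    for (j in gcols) {
      rows <- stats::runif(nrow(mat)) < 0.5
      mat[rows, j] <- "-"
    }
  }
  aln <- labeled_alignment(mat, species = unname(sp_of))
  attr(aln, "truth") <- list(n_species = n_species,
                             n_per_species = n_per_species,
                             seq_length = seq_length, d_intra = d_intra,
                             d_inter = d_inter, kappa = kappa,
                             shared_pairs = shared,
                             shared_haplotype_mode = shared_haplotype_mode,
                             gap_rate = gap_rate, seed = seed)
  aln
}

#' Simulate a contaminated clone set with a labeled reference panel
#'
#' Emulates a clone-triage setting: several taxon groups (one declared
#' target plus contaminants) diverge from a common root along per-group
#' offsets that are large compared to the within-group structure; within
#' each group, species and individuals are generated as in
#' [simulate_alignment]. Reference sequences carry species and group
#' labels; query (clone) sequences are emitted unlabeled, with their true
#' group and species kept in a separate truth table for scoring.
#'
#' @param groups Character vector of group names; the first is taken as
#'   the target unless `target_group` says otherwise.
#' @param target_group Declared on-target group (default `groups[1]`).
#' @param group_offset Root-to-group-ancestor branch length(s), recycled
#'   over groups; offsets of 0 make groups indistinguishable (warned).
#' @param n_species_per_group,n_per_species,seq_length,d_intra,d_inter,kappa
#'   Within-group structure, as in [simulate_alignment].
#' @param n_queries_per_group Number of query clones drawn per group
#'   (recycled); each query evolves from a random species ancestor of its
#'   group along `d_intra`.
#' @param seed Optional integer seed.
#' @return List with `alignment` (references labeled, queries with empty
#'   species/group), `query_ids`, `ref_groups` (named vector id -> group)
#'   and `truth` (data frame `query_id`, `group`, `species`).
#' @export
simulate_contaminated_set <- function(groups = c("Platyhelminthes",
                                                 "Arthropoda", "Nematoda"),
                                      target_group = groups[1L],
                                      group_offset = 0.5,
                                      n_species_per_group = 3,
                                      n_per_species = 2,
                                      seq_length = 600,
                                      d_intra = 0.005, d_inter = 0.05,
                                      kappa = 2,
                                      n_queries_per_group = 3,
                                      seed = NULL) {
  if (length(groups) < 2L)
    stop("need a target plus at least one contaminant group", call. = FALSE)
  if (!target_group %in% groups)
    stop("'target_group' must be one of 'groups'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  group_offset <- rep_len(group_offset, length(groups))
  n_queries_per_group <- rep_len(n_queries_per_group, length(groups))
  if (any(group_offset == 0))
    warning("group offset 0: groups are indistinguishable by construction")

  root <- sample(PURE_BASES, seq_length, replace = TRUE)
  seqs <- list(); meta <- list(); truth <- list()
  for (g in seq_along(groups)) {
    ganc <- .evolve(root, group_offset[g], kappa)
    anc_list <- list()
    for (s in seq_len(n_species_per_group)) {
      sp <- sprintf("%s_sp%02d", tolower(substr(groups[g], 1L, 4L)), s)
      anc <- .evolve(ganc, d_inter, kappa)
      anc_list[[sp]] <- anc
      for (k in seq_len(n_per_species)) {
        id <- sprintf("ref_%s_%d", sp, k)
        seqs[[id]] <- .evolve(anc, d_intra, kappa)
        meta[[id]] <- c(sp, groups[g])
      }
    }
    if (n_queries_per_group[g] > 0) {
      pick <- sample(names(anc_list), n_queries_per_group[g], replace = TRUE)
      for (q in seq_len(n_queries_per_group[g])) {
        id <- sprintf("clone_%s_%d", tolower(substr(groups[g], 1L, 4L)), q)
        seqs[[id]] <- .evolve(anc_list[[pick[q]]], d_intra, kappa)
        meta[[id]] <- c("", "")
        truth[[id]] <- data.frame(query_id = id, group = groups[g],
                                  species = pick[q], stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  mm <- do.call(rbind, meta)
  aln <- labeled_alignment(mat, species = mm[, 1L], group = mm[, 2L])
  ref_sel <- nzchar(aln$meta$group)
  truth_df <- if (length(truth))
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else data.frame(query_id = character(), group = character(),
                  species = character(), stringsAsFactors = FALSE)
  list(alignment = aln,
       query_ids = aln$meta$seq_id[!ref_sel],
       ref_groups = stats::setNames(aln$meta$group[ref_sel],
                                    aln$meta$seq_id[ref_sel]),
       truth = truth_df,
       target_group = target_group)
}
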