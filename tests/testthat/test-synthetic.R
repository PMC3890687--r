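test_that("K2P site probabilities honour the boundary and stationary limits", {
  p0 <- k2p_site_probs(0, kappa = 2)
  expect_equal(c(p0$p_same, p0$p_transition, p0$p_transversion), c(1, 0, 0))

  pinf <- k2p_site_probs(50, kappa = 2)
  expect_equal(pinf$p_transition, 0.25, tolerance = 1e-6)
  expect_equal(pinf$p_transversion, 0.5, tolerance = 1e-6)
  expect_equal(pinf$p_same, 0.25, tolerance = 1e-6)

  # probabilities sum to one exactly, for a sweep of d and kappa
  for (kap in c(0.5, 1, 2, 10)) {
    pr <- k2p_site_probs(seq(0, 1, by = 0.05), kappa = kap)
    expect_equal(pr$p_same + pr$p_transition + pr$p_transversion,
                 rep(1, 21))
    expect_true(all(unlist(pr) >= 0))
  }
  expect_error(k2p_site_probs(-0.1), ">= 0")
  expect_error(k2p_site_probs(0.1, kappa = 0), "positive")
})

test_that("expected proportions invert through the K2P estimator", {
  pr <- k2p_site_probs(0.1, kappa = 2)
  # closed form: 1/4 + exp(-0.1)/4 - exp(-0.15)/2 and (1 - exp(-0.1))/2
  expect_equal(pr$p_transition, 0.25 + exp(-0.1) / 4 - exp(-0.15) / 2)
  expect_equal(pr$p_transition, 0.045855, tolerance = 1e-4)
  expect_equal(pr$p_transversion, (1 - exp(-0.1)) / 2)
  expect_equal(pr$p_transversion, 0.047581, tolerance = 1e-4)
  expect_equal(k2p_distance(pr$p_transition, pr$p_transversion), 0.1,
               tolerance = 1e-6)
  # round trip across the whole range of interest
  for (d in seq(0.01, 0.5, by = 0.01)) {
    pr <- k2p_site_probs(d, kappa = 2)
    expect_equal(k2p_distance(pr$p_transition, pr$p_transversion), d,
                 tolerance = 1e-9)
  }
})

test_that("simulator is deterministic under a fixed seed", {
  a1 <- simulate_alignment(n_species = 5, n_per_species = 3, seq_length = 100,
                           seed = 71)
  a2 <- simulate_alignment(n_species = 5, n_per_species = 3, seq_length = 100,
                           seed = 71)
  expect_identical(a1$seq, a2$seq)
  expect_identical(a1$meta, a2$meta)
  a3 <- simulate_alignment(n_species = 5, n_per_species = 3, seq_length = 100,
                           seed = 72)
  expect_false(identical(a1$seq, a3$seq))

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_labeled_fasta(a1, f1); write_labeled_fasta(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero intraspecific branch length makes conspecifics identical", {
  aln <- simulate_alignment(n_species = 4, n_per_species = 3,
                            seq_length = 200, d_intra = 0, d_inter = 0.1,
                            seed = 73)
  m <- k2p_matrix(aln)
  p <- partition_distances(m, species_labels(aln))
  expect_true(all(p$intra$d == 0))
  expect_true(all(p$inter$d > 0))
})

test_that("estimated distances recover the generating branch lengths", {
  # star pairs at total path length 2d: mean K2P estimate within 3 standard
  # errors of the truth
  set.seed(74)
  for (d in c(0.01, 0.05, 0.1, 0.2)) {
    ests <- replicate(100, {
      aln <- simulate_alignment(n_species = 1, n_per_species = 2,
                                seq_length = 1000, d_intra = d, d_inter = 0)
      k2p_matrix(aln)[1, 2]
    })
    se <- stats::sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - 2 * d), 3 * se + 1e-9)
  }
})

test_that("simulated site patterns match the closed-form composition", {
  set.seed(75)
  d <- 0.15; kappa <- 2
  aln <- simulate_alignment(n_species = 1, n_per_species = 2,
                            seq_length = 20000, d_intra = d, d_inter = 0)
  cnt <- classify_sites(paste(aln$seq[1, ], collapse = ""),
                        paste(aln$seq[2, ], collapse = ""))
  pr <- k2p_site_probs(2 * d, kappa)
  # binomial MC tolerance: 4 sigma
  tol_ts <- 4 * sqrt(pr$p_transition * (1 - pr$p_transition) / 20000)
  tol_tv <- 4 * sqrt(pr$p_transversion * (1 - pr$p_transversion) / 20000)
  expect_lt(abs(cnt$P - pr$p_transition), tol_ts)
  expect_lt(abs(cnt$Q - pr$p_transversion), tol_tv)
})

test_that("shared-haplotype injection follows the requested mode", {
  # individual mode: exactly one zero interspecific distance
  aln <- simulate_alignment(n_species = 6, n_per_species = 3,
                            seq_length = 400, d_intra = 0.005, d_inter = 0.1,
                            shared_haplotype_pairs = 1,
                            shared_haplotype_mode = "individual", seed = 76)
  p <- partition_distances(k2p_matrix(aln), species_labels(aln))
  expect_equal(sum(p$inter$d == 0), 1L)

  # species mode: the whole pair collapses onto one haplotype
  aln2 <- simulate_alignment(n_species = 6, n_per_species = 3,
                             seq_length = 400, d_intra = 0.005,
                             d_inter = 0.1, shared_haplotype_pairs = 1,
                             shared_haplotype_mode = "species", seed = 76)
  sp <- species_labels(aln2)
  shared_ids <- names(sp)[sp %in% c("species01", "species02")]
  sub <- aln2$seq[shared_ids, , drop = FALSE]
  expect_true(all(apply(sub, 2, function(col) length(unique(col)) == 1L)))

  expect_error(simulate_alignment(n_species = 3, shared_haplotype_pairs = 2,
                                  seed = 1), "not enough species")
})

test_that("per-species counts and singletons are honoured", {
  aln <- simulate_alignment(n_species = 4, n_per_species = c(3, 1, 2, 1),
                            seq_length = 100, seed = 77)
  tab <- table(species_labels(aln))
  expect_equal(unname(as.integer(tab[sprintf("species%02d", 1:4)])),
               c(3L, 1L, 2L, 1L))
  expect_error(simulate_alignment(n_species = 3, n_per_species = c(2, 2),
                                  seed = 1), "length")
})

test_that("gap injection produces gap columns that pairwise deletion absorbs", {
  aln <- simulate_alignment(n_species = 4, n_per_species = 3,
                            seq_length = 500, gap_rate = 0.1, seed = 78)
  expect_gt(sum(aln$seq == "-"), 0)
  m <- k2p_matrix(aln)
  expect_true(all(!is.na(m)))
  expect_true(all(attr(m, "n_compared")[upper.tri(m)] < 500))
})

test_that("contaminated set separates groups and keeps truth apart", {
  cs <- simulate_contaminated_set(seed = 79)
  expect_equal(length(cs$query_ids), nrow(cs$truth))
  expect_true(all(!nzchar(cs$alignment$meta$species[
    cs$alignment$meta$seq_id %in% cs$query_ids])))
  expect_true(all(nzchar(cs$ref_groups)))

  none <- simulate_contaminated_set(n_queries_per_group = 0, seed = 80)
  expect_equal(length(none$query_ids), 0L)
  expect_equal(nrow(none$truth), 0L)

  expect_warning(simulate_contaminated_set(group_offset = 0, seed = 81),
                 "indistinguishable")
  expect_error(simulate_contaminated_set(groups = "OnlyOne", seed = 1),
               "at least one contaminant")
})
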