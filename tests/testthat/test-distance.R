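test_that("classify_sites counts transitions, transversions and skips gaps", {
  c1 <- classify_sites("AAAA", "AGAA")
  expect_equal(c1$n_compared, 4L)
  expect_equal(c1$n_transitions, 1L)
  expect_equal(c1$n_transversions, 0L)
  expect_equal(c1$P, 0.25)
  expect_equal(c1$Q, 0)

  c2 <- classify_sites("AC-T", "ACGT")
  expect_equal(c2$n_compared, 3L)
  expect_equal(c2$n_transitions + c2$n_transversions, 0L)

  # ambiguity codes are missing data, like gaps
  c3 <- classify_sites("ACNT", "ACGT")
  expect_equal(c3$n_compared, 3L)

  c4 <- classify_sites("ACGT", "TGCA")
  expect_equal(c4$n_transitions, 0L)
  expect_equal(c4$n_transversions, 4L)
  expect_equal(c4$Q, 1)

  c5 <- classify_sites("----", "ACGT")
  expect_false(c5$defined)
  expect_true(is.na(c5$P))
})

test_that("k2p_distance evaluates Kimura's closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.25, 0), -0.5 * log(0.5), tolerance = 1e-12)
  d <- k2p_distance(0.3, 0.4)  # 1 - 2P - Q = 0: boundary of the domain
  expect_true(is.na(d))
  expect_equal(attr(d, "reason"), "saturated")
  d2 <- k2p_distance(0, 0.5)   # 1 - 2Q = 0
  expect_true(is.na(d2))
  cnt <- classify_sites("----", "ACGT")
  d3 <- k2p_distance(cnt)
  expect_true(is.na(d3))
  expect_equal(attr(d3, "reason"), "no_sites")
})

test_that("K2P distance is monotone in P and in Q over the defined domain", {
  for (Q in c(0, 0.1, 0.2)) {
    P <- seq(0, (1 - Q) / 2 - 0.02, by = 0.02)
    d <- vapply(P, k2p_distance, numeric(1), Q = Q)
    expect_true(all(diff(d) > 0))
  }
  for (P in c(0, 0.1, 0.2)) {
    Q <- seq(0, min(0.49, 1 - 2 * P) - 0.02, by = 0.02)
    d <- vapply(Q, function(q) k2p_distance(P, q), numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("k2p_matrix composes classify_sites and k2p_distance", {
  set.seed(31)
  aln <- random_alignment(n = 3, len = 50, gap_p = 0.1)
  m <- k2p_matrix(aln)
  ids <- rownames(m)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- paste(aln$seq[i, ], collapse = "")
    b <- paste(aln$seq[j, ], collapse = "")
    expect_equal(m[i, j], unclass(k2p_distance(classify_sites(a, b))),
                 ignore_attr = TRUE)
  }
  expect_true(isSymmetric(m))
  expect_equal(diag(m), stats::setNames(rep(0, 3), ids))
})

test_that("identical sequences give an all-zero matrix", {
  mat <- matrix("A", 4, 20, dimnames = list(sprintf("s%d", 1:4), NULL))
  mat[, 1:10] <- rep(c("C", "G", "T", "A"), each = 4, length.out = 40)
  aln <- labeled_alignment(mat, species = "x")
  m <- k2p_matrix(aln)
  expect_true(all(m == 0))
})

test_that("permuting input order permutes the matrix consistently", {
  set.seed(32)
  aln <- random_alignment(n = 6, len = 60)
  m <- k2p_matrix(aln)
  perm <- sample(6)
  aln2 <- subset_alignment(aln, aln$meta$seq_id[perm])
  m2 <- k2p_matrix(aln2)
  expect_equal(m2, m[perm, perm], ignore_attr = TRUE)
})

test_that("matrix agrees with the per-column brute-force oracle", {
  set.seed(33)
  for (rep in 1:25) {
    aln <- random_alignment(n = 4, len = sample(20:60, 1),
                            gap_p = runif(1, 0, 0.2))
    m <- k2p_matrix(aln)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(m[i, j],
                   oracle_k2p(paste(aln$seq[i, ], collapse = ""),
                              paste(aln$seq[j, ], collapse = "")),
                   tolerance = 1e-12)
    }
  }
})

test_that("matrix agrees with ape::dist.dna K80 under pairwise deletion", {
  set.seed(34)
  aln <- simulate_alignment(n_species = 4, n_per_species = 3,
                            seq_length = 400, d_intra = 0.01, d_inter = 0.08,
                            seed = 101)
  m <- k2p_matrix(aln)
  db <- ape::as.DNAbin(aln$seq)
  ref <- as.matrix(ape::dist.dna(db, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(m), unname(ref[rownames(m), rownames(m)]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("saturated pairs are NA, listed with a reason, and logged in exports", {
  mat <- rbind(s1 = strsplit("ACGTACGTACGT", "")[[1]],
               s2 = strsplit("TGCATGCATGCA", "")[[1]],   # all transversions
               s3 = strsplit("ACGTACGTACGA", "")[[1]])
  aln <- labeled_alignment(mat, species = c("a", "b", "c"))
  m <- k2p_matrix(aln)
  expect_true(is.na(m["s1", "s2"]))
  und <- attr(m, "undefined_pairs")
  # s2 is transversion-saturated against both others
  expect_equal(und$reason, c("saturated", "saturated"))
  expect_true("s1" %in% und$id_a & "s2" %in% und$id_b)
  long <- distance_long_table(m)
  expect_equal(long$flag[long$id_a == "s1" & long$id_b == "s2"], "saturated")
  expect_equal(sum(long$flag == "ok"), 1L)
  expect_false(is.na(m["s1", "s3"]))
})

test_that("mean pairwise distance averages each unordered pair once", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 0.1
  m["a", "c"] <- m["c", "a"] <- 0.2
  m["b", "c"] <- m["c", "b"] <- 0.3
  expect_equal(as.numeric(mean_pairwise_distance(m)), 0.2)
  expect_equal(as.numeric(mean_pairwise_distance(m, subset = c("a", "c"))), 0.2)
  expect_equal(as.numeric(mean_pairwise_distance(m, percent = TRUE)), 20)

  set.seed(35)
  aln <- simulate_alignment(n_species = 19, n_per_species = 1,
                            seq_length = 200, d_intra = 0, d_inter = 0.15,
                            seed = 77)
  big <- k2p_matrix(aln)
  vals <- big[upper.tri(big)]
  expect_equal(length(vals), 171L)  # 19 * 18 / 2
  expect_equal(as.numeric(mean_pairwise_distance(big)), mean(vals))
  expect_equal(attr(mean_pairwise_distance(big), "n_pairs"), 171L)
})

test_that("complete deletion drops every column with a gap or ambiguity", {
  mat <- rbind(s1 = strsplit("AC-TACGT", "")[[1]],
               s2 = strsplit("ACGTACGT", "")[[1]],
               s3 = strsplit("ACGTNCGT", "")[[1]])
  aln <- labeled_alignment(mat, species = "x")
  m <- k2p_matrix(aln, pairwise_deletion = FALSE)
  expect_equal(attr(m, "n_compared")["s1", "s2"], 6L)
  m2 <- k2p_matrix(aln, pairwise_deletion = TRUE)
  expect_equal(attr(m2, "n_compared")["s1", "s2"], 7L)
})

test_that("PHYLIP export/import round-trips a matrix", {
  aln <- simulate_alignment(n_species = 5, n_per_species = 1,
                            seq_length = 200, d_inter = 0.1, seed = 36)
  m <- k2p_matrix(aln)
  f <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_dist(m, f)
  back <- read_phylip_dist(f)
  expect_equal(back, m[rownames(back), colnames(back)], tolerance = 1e-5,
               ignore_attr = TRUE)
})
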