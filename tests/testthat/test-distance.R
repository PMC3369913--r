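test_that("p-distance matches hand examples and flags undefined pairs", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_error(p_distance("ACGT", "ACG"), "length mismatch")
  # zero comparable sites is NA, not 0
  expect_true(is.na(p_distance("NN--", "AC-G")))
  # ambiguity codes count as missing, never as match or mismatch
  expect_equal(p_distance("ANGT", "ACGT"), 0)
  expect_equal(p_distance("ANGT", "TCGT"), 1 / 3)
})

test_that("p-distance equals the site-by-site brute-force oracle", {
  set.seed(201)
  chars <- c("A", "C", "G", "T", "N", "-", "R")
  for (i in 1:200) {
    a <- random_nt(75, chars)
    b <- random_nt(75, chars)
    expect_identical(p_distance(a, b), oracle_p_distance(a, b))
  }
})

test_that("distance matrix equals elementwise calls and respects labels", {
  set.seed(202)
  set <- random_record_set(6, 50, chars = c("A", "C", "G", "T", "-", "N"))
  d <- distance_matrix(set)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  ids <- set_ids(set)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_identical(d[i, j],
                     p_distance(set$records[[i]], set$records[[j]]))
  }
  # permuting the input order permutes the matrix identically
  perm <- sample(6)
  d2 <- distance_matrix(build_aligned_set(set$records[perm]))
  expect_equal(d2, d[ids[perm], ids[perm]], ignore_attr = TRUE)
  # identical sequences give an all-zero matrix
  same <- build_aligned_set(lapply(1:3, function(i) {
    seq_record(paste0("s", i), "ACGTACGT")
  }))
  expect_true(all(distance_matrix(same) == 0))
})

test_that("pairwise deletion ignores an inserted all-gap column", {
  set.seed(203)
  set <- random_record_set(5, 40)
  d <- distance_matrix(set)
  gapped <- build_aligned_set(lapply(set$records, function(r) {
    seq_record(r$id, paste0(substr(r$sequence, 1, 20), "-",
                            substr(r$sequence, 21, 40)))
  }))
  expect_equal(unname(distance_matrix(gapped)), unname(d))
})

test_that("p-distances agree with ape's raw pairwise-deletion distances", {
  set.seed(204)
  set <- random_record_set(8, 60, chars = c("A", "C", "G", "T", "-"))
  d <- distance_matrix(set)
  mats <- lapply(set$records, function(r) strsplit(tolower(r$sequence), "")[[1]])
  bin <- ape::as.DNAbin(do.call(rbind, mats))
  rownames(bin) <- set_ids(set)
  dref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(dref[rownames(d), colnames(d)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("complete deletion masks every unresolved column for all pairs", {
  recs <- list(seq_record("a", "ACGTAC"),
               seq_record("b", "ACGTCC"),
               seq_record("c", "AC-TCA"))
  set <- build_aligned_set(recs)
  d <- distance_matrix(set, deletion = "complete")
  # column 3 is masked for all pairs, so every pair compares 5 sites
  expect_equal(d["a", "b"], 1 / 5)
  expect_equal(d["a", "c"], 2 / 5)
})

test_that("within-group means enumerate all unordered pairs", {
  # three sequences engineered to pairwise distances 0.1, 0.2, 0.3
  base <- paste(rep("A", 10), collapse = "")
  s2 <- "CAAAAAAAAA"          # d(x,y) = 0.1
  s3 <- "ACCAAAAAAA"          # d(x,z) = 0.2, d(y,z) = 0.3
  set <- build_aligned_set(list(seq_record("x", base), seq_record("y", s2),
                                seq_record("z", s3)))
  g <- group_assignment(c("x", "y", "z"), rep("G", 3), rep("insect", 3))
  s <- within_group_mean(set, g, "G")
  expect_equal(s$mean_p_percent, 20)
  expect_equal(s$n_taxa, 3L)
  expect_equal(s$n_sites, 10L)
  # identical pair -> 0 %
  twin <- build_aligned_set(list(seq_record("x", base), seq_record("y", base)))
  g2 <- group_assignment(c("x", "y"), c("G", "G"), c("insect", "insect"))
  expect_equal(within_group_mean(twin, g2, "G")$mean_p_percent, 0)
  # singleton group is an error
  g3 <- group_assignment("x", "G", "insect")
  expect_error(within_group_mean(twin, g3, "G"), "mean undefined")
})

test_that("simulated groups hit their target mean p-distance", {
  set.seed(205)
  target <- 26       # percent, the lab/Insecta figure
  means <- replicate(40, {
    g <- simulate_group("grp", 8, 75, 396, target / 396)
    ga <- group_assignment(set_ids(g), rep("grp", 8), rep("insect", 8))
    within_group_mean(g, ga, "grp")$mean_p_percent
  })
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * mc_se + 0.5)
})
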