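test_that("zero rate yields identical sequences; same seed, same output", {
  g0 <- simulate_group("G", 5, 60, 396, 0, seed = 601)
  seqs <- vapply(g0$records, function(r) r$sequence, "")
  expect_length(unique(seqs), 1L)
  a <- simulate_group("G", 6, 75, 396, 0.05, seed = 602)
  b <- simulate_group("G", 6, 75, 396, 0.05, seed = 602)
  expect_identical(vapply(a$records, function(r) r$sequence, ""),
                   vapply(b$records, function(r) r$sequence, ""))
})

test_that("the linear model is unbiased for the target p-distance", {
  set.seed(603)
  rate <- 0.066; age <- 396   # target pairwise p = 26.14 %
  means <- replicate(60, {
    g <- simulate_group("G", 10, 75, age, rate)
    d <- distance_matrix(g)
    100 * mean(d[upper.tri(d)])
  })
  target <- rate * age
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * mc_se + 0.3)
})

test_that("expected divergence increases with age until saturation", {
  set.seed(604)
  mean_p_at_age <- function(age) {
    mean(replicate(25, {
      g <- simulate_group("G", 6, 75, age, 0.06)
      d <- distance_matrix(g)
      mean(d[upper.tri(d)])
    }))
  }
  p_young <- mean_p_at_age(100)
  p_mid <- mean_p_at_age(400)
  p_old <- mean_p_at_age(900)
  expect_lt(p_young, p_mid)
  expect_lt(p_mid, p_old)
})

test_that("the jukes-cantor model saturates below the linear target", {
  set.seed(605)
  rate <- 0.1; age <- 500     # nominal pairwise divergence d = 0.5
  obs <- mean(replicate(30, {
    g <- simulate_group("G", 6, 75, age, rate,
                        saturation_model = "jukes-cantor")
    d <- distance_matrix(g)
    mean(d[upper.tri(d)])
  }))
  expected <- 0.75 * (1 - exp(-4 / 3 * 0.5))
  expect_lt(abs(obs - expected), 0.02)
  expect_lt(obs, 0.5)
  # saturation guard
  expect_error(simulate_group("G", 4, 60, 1000, 0.08,
                              saturation_model = "jukes-cantor"),
               "saturated")
  expect_error(simulate_group("G", 4, 60, 1000, 0.08), "saturated")
})

test_that("fixture bundles are pipeline-ready and bit-reproducible", {
  spec <- default_simulation_spec()[1:5, ]   # small slice: 5 groups, 1 gene
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_study_fixture(spec, d1, seed = 606)
  b2 <- generate_study_fixture(spec, d2, seed = 606)
  f1 <- readLines(b1$fasta[["lab"]])
  expect_identical(f1, readLines(b2$fasta[["lab"]]))
  # bundle parses and the distance stage runs
  set <- build_aligned_set(read_fasta(b1$fasta[["lab"]]))
  groups <- read_group_table(b1$groups_tsv)
  s <- within_group_mean(set, groups, "Insecta")
  expect_equal(s$n_taxa, spec$n_taxa[spec$group == "Insecta"])
  # manifest records the ground truth
  man <- jsonlite::fromJSON(b1$manifest)
  expect_equal(man$seed, 606)
  expect_equal(nrow(man$truth), 5L)
  # degenerate inputs
  expect_error(generate_study_fixture(spec[0, ], withr::local_tempdir()),
               "empty")
  bad <- spec; bad$n_taxa[1] <- 1L
  expect_error(generate_study_fixture(bad, withr::local_tempdir()),
               "n_taxa >= 2")
})

test_that("a minimal two-taxon bundle runs the distance stage", {
  spec <- data.frame(gene = "lab", group = "Insecta", super_label = "insect",
                     n_taxa = 2L, n_sites = 75L, age_my = 396,
                     true_rate = 0.05)
  b <- generate_study_fixture(spec, withr::local_tempdir(), seed = 607)
  set <- build_aligned_set(read_fasta(b$fasta[["lab"]]))
  expect_equal(length(set), 2L)
  expect_true(is.finite(distance_matrix(set)[1, 2]))
})
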