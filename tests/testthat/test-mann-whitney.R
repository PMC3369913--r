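test_that("fully separated samples give the enumerated exact p", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)   # 2 of C(6,3) = 20 labelings as extreme
  r2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3), method = "exact")
  expect_equal(r2$U, 9)
  expect_equal(r2$p_two_sided, 0.1)
})

test_that("exact pmf matches brute-force enumeration, with and without ties", {
  set.seed(301)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(1:6, n1 + n2, replace = TRUE)  # heavy ties
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    if (length(unique(vals)) == 1L) next
    p_pkg <- mann_whitney_u(x, y, method = "exact")$p_two_sided
    expect_equal(p_pkg, oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
  # null distribution normalizes and has the documented tiny-case supports
  d11 <- exact_null_distribution(1, 1, c(3, 7))
  expect_equal(d11$prob, c(0.5, 0.5))
  expect_equal(d11$u, c(0, 1))
  d12 <- exact_null_distribution(1, 2, c(3, 7, 9))
  expect_equal(d12$u, c(0, 1, 2))
  expect_equal(d12$prob, rep(1 / 3, 3))
  dt <- exact_null_distribution(3, 3, c(1, 1, 2, 2, 3, 3))
  expect_equal(sum(dt$prob), 1)
})

test_that("swapping samples reflects U and preserves the two-sided p", {
  set.seed(302)
  for (rep in 1:15) {
    x <- rnorm(6); y <- rnorm(9)
    a <- mann_whitney_u(x, y, method = "exact")
    b <- mann_whitney_u(y, x, method = "exact")
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
    # invariant 0 <= U <= n1 n2
    expect_gte(a$U, 0); expect_lte(a$U, length(x) * length(y))
  }
})

test_that("degenerate samples are handled explicitly", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_warning(r <- mann_whitney_u(c(2, 2, 2), c(2, 2)), "tied")
  expect_equal(r$p_two_sided, 1)
  # identical multisets overlap maximally
  r2 <- mann_whitney_u(c(1, 5, 9), c(1, 5, 9), method = "exact")
  expect_equal(r2$p_two_sided, 1)
})

test_that("normal path matches the standard tie-corrected implementation", {
  set.seed(303)
  for (rep in 1:20) {
    x <- sample(1:12, 15, replace = TRUE)
    y <- sample(3:14, 18, replace = TRUE)
    mine <- mann_whitney_u(x, y, method = "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal paths agree for balanced tie-light samples", {
  set.seed(304)
  for (rep in 1:25) {
    x <- rnorm(15); y <- rnorm(15)
    pe <- mann_whitney_u(x, y, method = "exact")$p_two_sided
    pn <- mann_whitney_u(x, y, method = "normal",
                         continuity = TRUE)$p_two_sided
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("auto method switches on the labeling count", {
  expect_identical(mann_whitney_u(rnorm(5), rnorm(5))$method, "exact")
  expect_identical(mann_whitney_u(rnorm(30), rnorm(30))$method, "normal")
  expect_error(exact_null_distribution(30, 30, rnorm(60),
                                       enumeration_bound = 2e5),
               "normal approximation")
})

test_that("results serialize to JSON with all fields", {
  r <- mann_whitney_u(1:4, 3:9, method = "normal")
  js <- jsonlite::fromJSON(mwu_to_json(r))
  expect_equal(js$U, r$U)
  expect_equal(js$p_two_sided, r$p_two_sided)
  expect_true(all(c("n1", "n2", "method", "z", "tie_correction_applied")
                  %in% names(js)))
})
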