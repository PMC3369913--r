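# Mann-Whitney U with mid-rank ties. Two paths:
#  * exact: the permutation null of U under random relabeling, ties respected,
#    computed by a rank-sum convolution (subset-count DP over doubled
#    mid-ranks) that is mathematically identical to enumerating all
#    C(n1+n2, n1) labelings;
#  * normal: mean n1*n2/2 and tie-corrected variance, no continuity
#    correction by default so the convention is explicit.

u_from_ranks <- function(rank_sum1, n1) rank_sum1 - n1 * (n1 + 1) / 2

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Probability mass of U for sample 1 of size `n1` under random labeling of
#' the pooled values, with mid-rank ties respected. Computed by dynamic
#' programming over the doubled mid-ranks (so all sums are integers), which
#' agrees with full enumeration of the C(n1+n2, n1) labelings.
#'
#' @param n1,n2 Sample sizes.
#' @param pooled_values Numeric vector of length `n1 + n2` (the observed
#'   pooled data; ties shape the support).
#' @param enumeration_bound Maximum C(n1+n2, n1) accepted; beyond it an
#'   error directs to the normal approximation. The default is generous
#'   because the convolution cost is polynomial, not combinatorial.
#' @return Data.frame with columns `u` and `prob` (sums to 1).
#' @export
exact_null_distribution <- function(n1, n2, pooled_values,
                                    enumeration_bound = 1e12) {
  stopifnot(n1 >= 1L, n2 >= 1L, length(pooled_values) == n1 + n2)
  if (choose(n1 + n2, n1) > enumeration_bound) {
    stop("C(n1+n2, n1) exceeds the enumeration bound; ",
         "use the normal approximation")
  }
  r2 <- as.integer(round(2 * rank(pooled_values)))  # doubled mid-ranks
  total <- sum(r2)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) {
        f[k + 1L, nz + r] <- f[k + 1L, nz + r] + f[k, nz]
      }
    }
  }
  counts <- f[n1 + 1L, ]
  sums2 <- which(counts > 0) - 1L
  u <- sums2 / 2 - n1 * (n1 + 1) / 2     # rank sum -> U
  data.frame(u = u, prob = counts[sums2 + 1L] / choose(n1 + n2, n1))
}

two_sided_from_pmf <- function(pmf, u_obs, n1, n2) {
  mu <- n1 * n2 / 2
  dev <- abs(u_obs - mu)
  p <- sum(pmf$prob[abs(pmf$u - mu) >= dev - 1e-9])
  min(1, p)
}

#' Mann-Whitney U test (two-sided), tie-aware
#'
#' U for `sample_x` is computed by mid-rank assignment:
#' `U = R1 - n1(n1+1)/2`. The exact path evaluates the permutation null
#' (ties respected); the normal path standardizes with mean `n1 n2 / 2` and
#' the tie-corrected variance. The two-sided p is `2 * min(tail, 0.5)`
#' (normal path) or the symmetric-deviation tail mass (exact path), capped
#' at 1.
#'
#' @param sample_x,sample_y Non-empty numeric samples.
#' @param method `"auto"` (exact when C(n1+n2, n1) <= 2e5, else normal),
#'   `"exact"`, or `"normal"`.
#' @param continuity Apply a 0.5 continuity correction in the normal path
#'   (default `FALSE`).
#' @param exact_bound Enumeration bound for an explicit `method = "exact"`.
#' @return Object of class `mwu_result`: `U` (of sample x), `n1`, `n2`,
#'   `method`, `z` (normal path; `NA` otherwise), `p_two_sided`,
#'   `tie_correction_applied`.
#' @export
mann_whitney_u <- function(sample_x, sample_y,
                           method = c("auto", "exact", "normal"),
                           continuity = FALSE, exact_bound = 1e12) {
  method <- match.arg(method)
  x <- as.numeric(sample_x); y <- as.numeric(sample_y)
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- u_from_ranks(sum(rk[seq_len(n1)]), n1)
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  all_tied <- length(ties) == 1L
  if (method == "auto") {
    method <- if (choose(n, n1) <= 2e5) "exact" else "normal"
  }
  if (all_tied) {
    warning("all values tied across both samples; p = 1")
    res <- list(U = U, n1 = n1, n2 = n2, method = method,
                z = if (method == "normal") 0 else NA_real_,
                p_two_sided = 1, tie_correction_applied = has_ties)
    class(res) <- "mwu_result"
    return(res)
  }
  if (method == "exact") {
    pmf <- exact_null_distribution(n1, n2, pooled,
                                   enumeration_bound = exact_bound)
    p <- two_sided_from_pmf(pmf, U, n1, n2)
    z <- NA_real_
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    cc <- if (continuity) sign(U - mu) * 0.5 else 0
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  res <- list(U = U, n1 = n1, n2 = n2, method = method, z = z,
              p_two_sided = p, tie_correction_applied = has_ties)
  class(res) <- "mwu_result"
  res
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (two-sided, %s)\n", x$method))
  cat(sprintf("  U = %g (n1 = %d, n2 = %d)", x$U, x$n1, x$n2))
  if (!is.na(x$z)) cat(sprintf(", z = %.4f", x$z))
  cat(sprintf("\n  p = %.6g%s\n", x$p_two_sided,
              if (x$tie_correction_applied) "  [tie-corrected]" else ""))
  invisible(x)
}

#' Serialize a test result to JSON
#' @param result An `mwu_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
mwu_to_json <- function(result, path = NULL) {
  obj <- unclass(result)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
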