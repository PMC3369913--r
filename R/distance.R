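# p-distances: proportion of differing sites among sites where both
# sequences carry a resolved character. Ambiguity codes (N, R, Y, ..., X)
# and gaps never count as match or mismatch.

resolved_chars <- function(alphabet) {
  switch(alphabet,
         nt = c("A", "C", "G", "T"),
         aa = setdiff(AA_CHARS, c("X", "-", "?", "*")))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of sites whose resolved characters differ, over the sites
#' where both sequences are resolved (not gap, not missing, not an ambiguity
#' code). No multiple-hit correction is applied.
#'
#' @param seq_a,seq_b Equal-length sequence strings, or [seq_record]s.
#' @param alphabet `"nt"` or `"aa"` (ignored when records carry their own).
#' @param site_mask Optional logical vector of sites to use (the
#'   complete-deletion mask of a containing set); default all sites.
#' @return A length-1 numeric in \[0, 1\], or `NA` when no site is comparable
#'   (an explicitly undefined distance, distinct from 0).
#' @export
p_distance <- function(seq_a, seq_b, alphabet = "nt", site_mask = NULL) {
  if (inherits(seq_a, "seq_record")) { alphabet <- seq_a$alphabet; seq_a <- seq_a$sequence }
  if (inherits(seq_b, "seq_record")) seq_b <- seq_b$sequence
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  }
  res <- resolved_chars(match.arg(alphabet, c("nt", "aa")))
  ok <- a %in% res & b %in% res
  if (!is.null(site_mask)) {
    stopifnot(length(site_mask) == length(a))
    ok <- ok & site_mask
  }
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(a[ok] != b[ok]) / n
}

#' Pairwise p-distance matrix of an aligned set
#'
#' @param aligned_set An [aligned_set] with at least 2 records.
#' @param deletion `"pairwise"` (default; sites dropped per pair, the common
#'   setting for fragmentary homeobox data) or `"complete"` (one mask of
#'   sites resolved in every record, applied to all pairs).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxon ids.
#'   Cells with no comparable sites are `NA` (undefined, flagged via
#'   `attr(, "undefined_pairs")`).
#' @export
distance_matrix <- function(aligned_set, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aligned_set, "aligned_set"))
  deletion <- match.arg(deletion)
  n <- length(aligned_set)
  if (n < 2L) stop("need at least 2 records for a distance matrix")
  m <- as_char_matrix(aligned_set)
  res <- resolved_chars(aligned_set$alphabet)
  okm <- matrix(m %in% res, nrow = nrow(m))
  mask <- if (deletion == "complete") apply(okm, 2L, all) else NULL
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- okm[i, ] & okm[j, ]
      if (!is.null(mask)) ok <- ok & mask
      cnt <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (cnt == 0L) NA_real_ else sum(m[i, ok] != m[j, ok]) / cnt
    }
  }
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  attr(d, "undefined_pairs") <-
    if (nrow(und)) data.frame(a = rownames(m)[und[, 1L]],
                              b = rownames(m)[und[, 2L]]) else NULL
  attr(d, "deletion") <- deletion
  d
}

#' Mean within-group p-distance (Table-style summary)
#'
#' Arithmetic mean over all C(n, 2) unordered within-group pairs, expressed
#' in percent, together with the taxon and site counts carried into the rate
#' table.
#'
#' @param aligned_set An [aligned_set].
#' @param groups A `group_assignment` covering the set's taxa.
#' @param group_label Group to summarise (needs >= 2 members in the set).
#' @param deletion Passed to [distance_matrix()].
#' @return A one-row data.frame: `group`, `n_taxa`, `n_sites`,
#'   `mean_p_percent`.
#' @export
within_group_mean <- function(aligned_set, groups, group_label,
                              deletion = "pairwise") {
  members <- intersect(group_members(groups, group_label), set_ids(aligned_set))
  if (length(members) < 2L) {
    stop("mean undefined: group '", group_label,
         "' has fewer than 2 members in the set")
  }
  sub <- build_aligned_set(
    aligned_set$records[match(members, set_ids(aligned_set))])
  d <- distance_matrix(sub, deletion = deletion)
  vals <- d[upper.tri(d)]
  if (anyNA(vals)) {
    warning("group '", group_label, "': ", sum(is.na(vals)),
            " undefined pair(s) excluded from the mean")
    vals <- vals[!is.na(vals)]
  }
  data.frame(group = group_label,
             n_taxa = length(members),
             n_sites = sub$length,
             mean_p_percent = 100 * mean(vals),
             stringsAsFactors = FALSE)
}

#' Write a distance matrix as a PHYLIP square matrix
#' @param d Matrix from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10L), " ",
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
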