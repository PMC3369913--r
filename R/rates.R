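# Fossil-calibrated divergence rates: r = mean within-group p-distance (%)
# divided by the group's fossil minimum age (My), giving % per million years.
# Ages are fixed constants (minimum ages); no uncertainty propagation.

#' Read a fossil calibration table
#'
#' TSV with columns `group`, `age_my`, `fossil_name`, `reference`. The
#' packaged default transcribes the study's calibrations (e.g. Insecta
#' 396 My on *Rhyniognatha hirsti*, molluscan classes 510-528 My, mammalian
#' clusters 195 My on *Hadrocodium wui*).
#'
#' @param path Path to the TSV; defaults to the packaged table.
#' @return Data.frame of class `fossil_calibration`.
#' @export
read_calibration_table <- function(path = system.file(
    "extdata", "fossil_calibrations.tsv", package = "hoxrates")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "age_my")
  if (!all(need %in% names(df))) {
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$age_my)) || any(df$age_my <= 0)) {
    stop("calibration ages must be positive")
  }
  if (anyDuplicated(df$group)) stop("duplicate calibration group")
  class(df) <- c("fossil_calibration", "data.frame")
  df
}

#' Absolute divergence rate from a p-distance and a fossil age
#'
#' @param mean_p_percent Mean within-group p-distance, in percent.
#' @param age_my Fossil minimum age of the group, in million years (> 0).
#' @return Rate in percent per million years: `mean_p_percent / age_my`.
#' @export
divergence_rate <- function(mean_p_percent, age_my) {
  if (any(!is.finite(age_my)) || any(age_my <= 0)) {
    stop("age_my must be positive")
  }
  if (any(mean_p_percent < 0)) stop("mean_p_percent must be >= 0")
  mean_p_percent / age_my
}

#' Build a gene x group divergence-rate table
#'
#' Joins per-(gene, group) p-distance summaries to fossil calibrations and
#' computes the rate column. Rates are kept at full precision; use
#' [format_rate_table()] for the reporting convention (p% to 1 decimal,
#' rates to 3 decimals).
#'
#' @param summaries Data.frame with columns `gene`, `group`, `super_label`,
#'   `n_taxa`, `n_sites`, `mean_p_percent`.
#' @param calibrations A `fossil_calibration` table covering every group.
#' @return Data.frame of class `rate_table`: the summaries plus `age_my` and
#'   `rate_percent_per_my`, one row per unique (gene, group).
#' @export
build_rate_table <- function(summaries, calibrations) {
  need <- c("gene", "group", "super_label", "n_taxa", "n_sites",
            "mean_p_percent")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(summaries) == 0L) {
    out <- summaries
    out$age_my <- numeric(0)
    out$rate_percent_per_my <- numeric(0)
    class(out) <- c("rate_table", "data.frame")
    return(out)
  }
  key <- paste(summaries$gene, summaries$group, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, group) pair(s): ",
         paste(unique(gsub("\r", " / ", key[duplicated(key)])), collapse = "; "))
  }
  idx <- match(summaries$group, calibrations$group)
  if (anyNA(idx)) {
    stop("missing calibration for group(s): ",
         paste(unique(summaries$group[is.na(idx)]), collapse = ", "))
  }
  out <- summaries[need]
  out$age_my <- calibrations$age_my[idx]
  out$rate_percent_per_my <- divergence_rate(out$mean_p_percent, out$age_my)
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Summarise rates by super-label (insect vs non-insect)
#'
#' One value per (gene, group) row enters the sample: the study-style
#' construction that gives 8 insect values (one per Hox gene) and the
#' remaining non-insect values.
#'
#' @param rate_table A `rate_table`.
#' @param super_label `"insect"` or `"non-insect"`.
#' @return List with `mean`, `sd`, `se` (sample SD / sqrt(n); `NA` when
#'   n = 1), `n`, and the `rates` vector itself.
#' @export
group_rate_summary <- function(rate_table, super_label) {
  r <- rate_table$rate_percent_per_my[rate_table$super_label == super_label]
  if (length(r) == 0L) stop("no rates with super_label '", super_label, "'")
  list(mean = mean(r),
       sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
       se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
       n = length(r),
       rates = r)
}

#' Format a rate table with the reporting precision
#'
#' p-distances to 1 decimal, rates to 3 decimals; internal values stay at
#' full precision in the unformatted table.
#'
#' @param rate_table A `rate_table`.
#' @return Data.frame of character-formatted columns, for writing/printing.
#' @export
format_rate_table <- function(rate_table) {
  out <- rate_table
  out$mean_p_percent <- formatC(round(out$mean_p_percent, 1L), format = "fg")
  out$rate_percent_per_my <- sprintf("%.3f", out$rate_percent_per_my)
  out
}

#' Load the packaged transcription of the study's divergence-rate table
#'
#' Columns: `gene`, `group`, `super_label`, `n_taxa`, `n_sites`,
#' `mean_p_percent`, `age_my`, and `printed_rate` (the published rounded
#' rate, for cross-checking only — never used in computation).
#'
#' @return Data.frame with 60 (gene, group) rows.
#' @export
load_hox_divergence_table <- function() {
  utils::read.delim(system.file("extdata", "hox_divergence_table.tsv",
                                package = "hoxrates"),
                    stringsAsFactors = FALSE)
}
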