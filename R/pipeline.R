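# End-to-end orchestration: distances -> rates -> insect/non-insect
# comparison (-> optional NJ trees), with a precomputed-distance mode that
# reproduces the published table arithmetic from its printed p-distance and
# age columns alone.

log_stage <- function(log_con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the divergence-rate analysis
#'
#' Two input modes:
#' * full-sequence mode: `fasta` (named per-gene FASTA paths), `groups_tsv`
#'   and `calibration_tsv` — p-distances are computed from the alignments;
#' * precomputed-distance mode: `precomputed` rows (`gene`, `group`,
#'   `super_label`, `n_taxa`, `n_sites`, `mean_p_percent`) — the mean
#'   p-distances are taken as given, which reproduces published-table
#'   arithmetic exactly without the underlying sequences.
#'
#' Outputs written under `outdir`: `rate_table.tsv` (full precision),
#' `rate_table_formatted.tsv` (p% to 1 decimal, rates to 3 decimals),
#' `summary.tsv` (per super-label mean/SD/SE/n), `comparison.json` (the
#' Mann-Whitney result), optional `tree_<gene>.nwk`, and `run.log`.
#'
#' @param fasta Named character vector of per-gene FASTA paths (full mode).
#' @param groups_tsv Taxon-to-group TSV path (full mode).
#' @param calibration_tsv Calibration TSV path; default the packaged table.
#' @param precomputed Optional data.frame for precomputed-distance mode.
#' @param outdir Output directory.
#' @param deletion Deletion mode for [distance_matrix()].
#' @param comparison_method Passed to [mann_whitney_u()].
#' @param write_trees Also write one NJ Newick per gene (full mode only).
#' @param alphabet Sequence alphabet of the FASTA inputs.
#' @return List: `rate_table`, `summaries` (insect / non-insect), and
#'   `comparison` (`mwu_result`), invisibly also written to `outdir`.
#' @export
run_rate_analysis <- function(fasta = NULL, groups_tsv = NULL,
                              calibration_tsv = NULL, precomputed = NULL,
                              outdir, deletion = "pairwise",
                              comparison_method = "auto",
                              write_trees = FALSE, alphabet = "nt") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), "w")
  started <- character(0)
  ok <- FALSE
  on.exit({
    close(log_con)
    if (!ok) unlink(file.path(outdir, started))  # no partial outputs
  })
  cal <- if (is.null(calibration_tsv)) read_calibration_table() else
    read_calibration_table(calibration_tsv)

  if (!is.null(precomputed)) {
    log_stage(log_con, "stage distances: precomputed-distance mode (%d rows)",
              nrow(precomputed))
    summaries <- precomputed
  } else {
    if (is.null(fasta) || is.null(groups_tsv)) {
      stop("stage input: need either precomputed rows or fasta + groups_tsv")
    }
    groups <- read_group_table(groups_tsv)
    rows <- list()
    for (g in names(fasta)) {
      log_stage(log_con, "stage distances: gene %s (%s deletion)", g, deletion)
      set <- build_aligned_set(read_fasta(fasta[[g]], alphabet = alphabet))
      present <- unique(groups$group[groups$taxon_id %in% set_ids(set)])
      for (grp in present) {
        members <- intersect(group_members(groups, grp), set_ids(set))
        if (length(members) < 2L) next
        s <- within_group_mean(set, groups, grp, deletion = deletion)
        s$gene <- g
        s$super_label <-
          groups$super_label[match(members[[1L]], groups$taxon_id)]
        rows[[length(rows) + 1L]] <- s
      }
      if (write_trees) {
        d <- distance_matrix(set, deletion = deletion)
        if (!anyNA(d)) {
          tr <- neighbor_joining(d)
          tree_file <- paste0("tree_", g, ".nwk")
          writeLines(to_newick(tr), file.path(outdir, tree_file))
          started <- c(started, tree_file)
          log_stage(log_con, "stage trees: wrote %s", tree_file)
        }
      }
    }
    summaries <- do.call(rbind, rows)
    summaries <- summaries[, c("gene", "group", "super_label", "n_taxa",
                               "n_sites", "mean_p_percent")]
  }

  log_stage(log_con, "stage rates: calibrating %d (gene, group) rows",
            nrow(summaries))
  rt <- build_rate_table(summaries, cal)
  utils::write.table(rt, file.path(outdir, "rate_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format_rate_table(rt),
                     file.path(outdir, "rate_table_formatted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  started <- c(started, "rate_table.tsv", "rate_table_formatted.tsv")

  log_stage(log_con, "stage summaries: insect vs non-insect")
  ins <- group_rate_summary(rt, "insect")
  non <- group_rate_summary(rt, "non-insect")
  summary_df <- data.frame(
    super_label = c("insect", "non-insect"),
    n = c(ins$n, non$n),
    mean_rate = c(ins$mean, non$mean),
    sd_rate = c(ins$sd, non$sd),
    se_rate = c(ins$se, non$se))
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  started <- c(started, "summary.tsv")

  log_stage(log_con, "stage comparison: Mann-Whitney U (%s, two-sided)",
            comparison_method)
  cmp <- mann_whitney_u(ins$rates, non$rates, method = comparison_method)
  mwu_to_json(cmp, file.path(outdir, "comparison.json"))
  started <- c(started, "comparison.json")
  log_stage(log_con, "done: U = %g, p = %.3g", cmp$U, cmp$p_two_sided)

  ok <- TRUE
  invisible(list(rate_table = rt,
                 summaries = list(insect = ins, `non-insect` = non),
                 comparison = cmp))
}

#' Run the homolog classification stage
#'
#' Assigns each query fragment to a Hox family against the reference
#' panels and writes an assignment report TSV; ambiguous queries are
#' flagged with their candidate families.
#'
#' @param query_fasta FASTA of query fragments aligned to the panel frame.
#' @param panel_fastas Named character vector: family -> FASTA path.
#' @param outdir Output directory.
#' @param alphabet Alphabet of queries and panels (default `"aa"`, the
#'   homeodomain frame).
#' @param ... Passed to [assign_family()].
#' @return The report data.frame, invisibly written to
#'   `<outdir>/assignments.tsv`. An empty query file yields an empty report
#'   with a warning.
#' @export
run_classification <- function(query_fasta, panel_fastas, outdir,
                               alphabet = "aa", ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  queries <- read_fasta(query_fasta, alphabet = alphabet)
  panels <- read_panels(panel_fastas, alphabet = alphabet)
  if (length(queries) == 0L) {
    warning("empty query file: ", query_fasta)
    report <- data.frame(query_id = character(0), best_family = character(0),
                         best_distance = numeric(0), margin = numeric(0),
                         ambiguous = logical(0), candidates = character(0),
                         n_covered = integer(0), short_window = logical(0))
  } else {
    report <- assignment_report(queries, panels, ...)
  }
  utils::write.table(report, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
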