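# Distance-based assignment of homeobox fragments to Hox gene families.
# Panels are reference sets aligned to the homeodomain coordinate frame
# (amino-acid positions 1-60); a query may cover only a sub-window, which is
# exactly the situation that makes Scr and Antp indistinguishable: their
# homeodomains differ at positions 1, 4, 6, 7 and 60 only, so a fragment
# spanning positions 20-45 carries no diagnostic signal.

#' Build a Hox reference panel
#'
#' @param family Family label (e.g. "lab", "Scr", "Antp").
#' @param records List of [seq_record]s aligned to the common homeodomain
#'   frame (all the same length).
#' @return Object of class `hox_panel`.
#' @export
hox_panel <- function(family, records) {
  set <- build_aligned_set(records)
  structure(list(family = family, set = set, length = set$length),
            class = "hox_panel")
}

#' Read reference panels from FASTA files
#'
#' @param paths Named character vector: family label -> FASTA path.
#' @param alphabet `"nt"` or `"aa"`.
#' @return Named list of `hox_panel`s.
#' @export
read_panels <- function(paths, alphabet = "aa") {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  if (anyDuplicated(names(paths))) stop("family labels must be unique")
  out <- lapply(names(paths), function(fam) {
    hox_panel(fam, read_fasta(paths[[fam]], alphabet = alphabet))
  })
  names(out) <- names(paths)
  out
}

query_covered_positions <- function(query) {
  chars <- strsplit(query$sequence, "")[[1L]]
  which(chars %in% resolved_chars(query$alphabet))
}

#' Assign a query fragment to a Hox family
#'
#' The best family minimizes the mean p-distance from the query to the
#' panel members, computed over the positions where both query and member
#' are resolved. A result is flagged ambiguous when the margin to the
#' second-best family is below `ambiguity_margin` or when the best distance
#' is tied; fragments covering fewer than `min_window` homeodomain positions
#' additionally carry a short-window flag (short fragments are the root of
#' the Scr/Antp problem).
#'
#' @param query A [seq_record] aligned to the panel coordinate frame
#'   (unresolved positions mark the uncovered part of the frame).
#' @param panels List of `hox_panel`s, all of the query's length.
#' @param ambiguity_margin Distance margin below which the call is
#'   ambiguous; default 0 (absolute ties only).
#' @param min_window Covered-position count below which `short_window` is
#'   set (default 30).
#' @return Object of class `hox_assignment`: `query_id`, `best_family`,
#'   `best_distance`, `margin`, `ambiguous`, `candidates`,
#'   `covered_positions`, `short_window`, `distances` (per family).
#' @export
assign_family <- function(query, panels, ambiguity_margin = 0,
                          min_window = 30L) {
  stopifnot(inherits(query, "seq_record"), length(panels) >= 1L)
  lens <- vapply(panels, function(p) p$length, numeric(1L))
  if (length(unique(lens)) > 1L || nchar(query$sequence) != lens[[1L]]) {
    stop("query and panels must share one coordinate frame (equal lengths)")
  }
  covered <- query_covered_positions(query)
  dists <- vapply(panels, function(p) {
    dd <- vapply(p$set$records, function(r) {
      p_distance(query, r)
    }, numeric(1L))
    mean(dd)
  }, numeric(1L))
  if (all(is.na(dists))) {
    stop("no overlapping resolved positions between query '", query$id,
         "' and any panel")
  }
  ord <- order(dists, names(dists), na.last = TRUE)
  best <- ord[[1L]]
  margin <- if (length(dists) > 1L) dists[[ord[[2L]]]] - dists[[best]] else Inf
  tied <- names(dists)[!is.na(dists) &
                         dists <= dists[[best]] + ambiguity_margin + 1e-12]
  ambiguous <- length(tied) > 1L
  structure(list(query_id = query$id,
                 best_family = names(dists)[[best]],
                 best_distance = dists[[best]],
                 margin = margin,
                 ambiguous = ambiguous,
                 candidates = sort(tied),
                 covered_positions = covered,
                 short_window = length(covered) < min_window,
                 distances = dists),
            class = "hox_assignment")
}

#' @export
print.hox_assignment <- function(x, ...) {
  cat(sprintf("<hox_assignment> %s -> %s (d = %.4f, margin = %.4f)%s\n",
              x$query_id, x$best_family, x$best_distance, x$margin,
              if (x$ambiguous)
                paste0("  AMBIGUOUS {", paste(x$candidates, collapse = ", "), "}")
              else ""))
  if (x$short_window) {
    cat(sprintf("  note: only %d homeodomain positions covered\n",
                length(x$covered_positions)))
  }
  invisible(x)
}

#' Diagnostic positions between two reference panels
#'
#' Positions (1-based, homeodomain frame) at which the observed residue
#' sets of the two panels are disjoint — the only positions that can
#' discriminate the families. For Scr vs Antp homeodomains these are
#' confined to positions 1, 4, 6, 7 and 60.
#'
#' @param panel_a,panel_b `hox_panel`s on the same coordinate frame.
#' @return Increasing integer vector of diagnostic positions (possibly
#'   empty).
#' @export
diagnostic_positions <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "hox_panel"), inherits(panel_b, "hox_panel"))
  if (panel_a$length != panel_b$length) {
    stop("coordinate frame mismatch: panels have lengths ",
         panel_a$length, " and ", panel_b$length)
  }
  ma <- as_char_matrix(panel_a$set)
  mb <- as_char_matrix(panel_b$set)
  res <- resolved_chars(panel_a$set$alphabet)
  out <- integer(0)
  for (pos in seq_len(panel_a$length)) {
    sa <- intersect(unique(ma[, pos]), res)
    sb <- intersect(unique(mb[, pos]), res)
    if (length(sa) && length(sb) && length(intersect(sa, sb)) == 0L) {
      out <- c(out, pos)
    }
  }
  out
}

#' Assignment report for a set of queries
#'
#' @param queries List of [seq_record]s.
#' @param panels List of `hox_panel`s.
#' @param ... Passed to [assign_family()].
#' @return Data.frame, one row per query: id, best family, distance,
#'   margin, ambiguity flag, candidates (comma-joined), covered-position
#'   count, short-window flag.
#' @export
assignment_report <- function(queries, panels, ...) {
  rows <- lapply(queries, function(q) {
    a <- assign_family(q, panels, ...)
    data.frame(query_id = a$query_id,
               best_family = a$best_family,
               best_distance = a$best_distance,
               margin = a$margin,
               ambiguous = a$ambiguous,
               candidates = paste(a$candidates, collapse = ","),
               n_covered = length(a$covered_positions),
               short_window = a$short_window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
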