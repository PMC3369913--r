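# Degenerate-primer model: IUPAC matching, degeneracy accounting, binding
# sites on both strands, amplicon prediction and Wallace-rule melting
# temperature ranges. Product lengths are counted inclusive of both primer
# footprints; coordinates are 0-based half-open on the plus strand.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W",
                      K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

check_iupac <- function(s) {
  chars <- strsplit(toupper(s), "")[[1L]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad)) {
    stop("illegal IUPAC character(s): ", paste(bad, collapse = ", "))
  }
  chars
}

#' Define a degenerate primer
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string, written 5' to 3'.
#' @param orientation `"forward"` or `"reverse"` (a reverse primer reads 5'
#'   to 3' on the minus strand).
#' @param annealing_c Optional reported annealing temperature (deg C).
#' @return Object of class `degenerate_primer` with its `degeneracy`.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse"),
                              annealing_c = NA_real_) {
  orientation <- match.arg(orientation)
  sequence <- toupper(as.character(sequence))
  check_iupac(sequence)
  structure(list(name = name, sequence = sequence, orientation = orientation,
                 annealing_c = annealing_c, degeneracy = degeneracy(sequence)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) %s  degeneracy %d\n",
              x$name, x$orientation, x$sequence, x$degeneracy))
  invisible(x)
}

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the per-code cardinalities (N = 4; B, D, H,
#' V = 3; R, Y, S, W, K, M = 2; plain bases = 1).
#'
#' @param primer IUPAC string or `degenerate_primer`.
#' @return Integer count of distinct plain-base expansions.
#' @export
degeneracy <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer <- primer$sequence
  chars <- check_iupac(primer)
  prod(vapply(IUPAC_SETS[chars], length, integer(1L)))
}

#' IUPAC code / template base compatibility
#'
#' @param primer_char Single IUPAC code.
#' @param template_char Template base; plain `A`/`C`/`G`/`T` in `strict`
#'   mode, any IUPAC code in `intersect` mode (compatible iff the two sets
#'   share a base).
#' @param ambiguous_template `"strict"` (error on ambiguous template) or
#'   `"intersect"`.
#' @return Logical flag.
#' @export
iupac_match <- function(primer_char, template_char,
                        ambiguous_template = c("strict", "intersect")) {
  ambiguous_template <- match.arg(ambiguous_template)
  p <- IUPAC_SETS[[toupper(primer_char)]]
  if (is.null(p)) stop("illegal IUPAC primer character: ", primer_char)
  tc <- toupper(template_char)
  if (!tc %in% c("A", "C", "G", "T")) {
    if (ambiguous_template == "strict") {
      stop("ambiguous template base: ", template_char)
    }
    t_set <- IUPAC_SETS[[tc]]
    if (is.null(t_set)) stop("illegal template character: ", template_char)
    return(length(intersect(p, t_set)) > 0L)
  }
  tc %in% p
}

#' Reverse complement of an IUPAC string
#' @param sequence IUPAC nucleotide string.
#' @return The reverse complement, degeneracy-preserving.
#' @export
reverse_complement <- function(sequence) {
  chars <- check_iupac(sequence)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

mismatch_profile <- function(template_chars, primer_chars, start) {
  idx <- seq_along(primer_chars) + start - 1L
  tmpl <- template_chars[idx]
  !mapply(function(pc, tc) tc %in% IUPAC_SETS[[pc]], primer_chars, tmpl)
}

#' Find primer binding sites on a template
#'
#' Slides the primer along both strands of a plain-base template and
#' reports every window with at most `max_mismatch` mismatches (uniform
#' weighting; no 3'-anchoring). Reverse-orientation primers are matched
#' against the reverse complement; all sites are reported in plus-strand
#' 0-based half-open coordinates with a strand flag.
#'
#' @param template Plain A/C/G/T string (or [seq_record]).
#' @param primer A `degenerate_primer` (or IUPAC string, taken as forward).
#' @param max_mismatch Maximum mismatches tolerated (default 0).
#' @return Data.frame: `start`, `end` (0-based half-open, plus strand),
#'   `strand` (`"+"`/`"-"`), `mismatches`. Empty when the primer is longer
#'   than the template.
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0L) {
  if (inherits(template, "seq_record")) template <- template$sequence
  template <- toupper(template)
  tchars <- strsplit(template, "")[[1L]]
  if (!all(tchars %in% c("A", "C", "G", "T"))) {
    stop("template must be a plain A/C/G/T sequence")
  }
  if (is.character(primer)) primer <- degenerate_primer("primer", primer)
  plen <- nchar(primer$sequence)
  tlen <- length(tchars)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0))
  if (plen > tlen) return(empty)
  scan_one <- function(primer_seq) {
    pchars <- strsplit(primer_seq, "")[[1L]]
    sets <- IUPAC_SETS[pchars]
    starts <- integer(0); mms <- integer(0)
    for (s in seq_len(tlen - plen + 1L)) {
      window <- tchars[s:(s + plen - 1L)]
      mm <- sum(!mapply(`%in%`, window, sets))
      if (mm <= max_mismatch) { starts <- c(starts, s); mms <- c(mms, mm) }
    }
    list(starts = starts, mms = mms)
  }
  rows <- list()
  if (primer$orientation == "forward") {
    hit <- scan_one(primer$sequence)
    if (length(hit$starts)) {
      rows[[1L]] <- data.frame(start = hit$starts - 1L,
                               end = hit$starts - 1L + plen,
                               strand = "+", mismatches = hit$mms)
    }
  } else {
    # a reverse primer anneals to the plus strand; its binding footprint on
    # the plus strand is the reverse complement of the primer
    hit <- scan_one(reverse_complement(primer$sequence))
    if (length(hit$starts)) {
      rows[[1L]] <- data.frame(start = hit$starts - 1L,
                               end = hit$starts - 1L + plen,
                               strand = "-", mismatches = hit$mms)
    }
  }
  if (length(rows)) rows[[1L]] else empty
}

#' Predict PCR amplicons on a template
#'
#' Pairs every forward site with every downstream reverse site and keeps
#' products whose length (inclusive of both primer footprints:
#' `rev_end - fw_start`) falls in `size_range`.
#'
#' @param template Plain-base template string (or [seq_record]).
#' @param fw_primer,rev_primer `degenerate_primer`s of forward and reverse
#'   orientation respectively.
#' @param max_mismatch Maximum mismatches per primer site.
#' @param size_range Length-2 numeric `c(min, max)` product filter in bp;
#'   default no constraint.
#' @return Data.frame: `template_id`, `fw_start`, `fw_end`, `rev_start`,
#'   `rev_end`, `product_length`, `fw_mismatches`, `rev_mismatches`.
#' @export
predict_amplicons <- function(template, fw_primer, rev_primer,
                              max_mismatch = 0L, size_range = c(1, Inf)) {
  template_id <- if (inherits(template, "seq_record")) template$id else "template"
  if (fw_primer$orientation != "forward" || rev_primer$orientation != "reverse") {
    stop("primers must be one forward and one reverse")
  }
  fw <- find_binding_sites(template, fw_primer, max_mismatch)
  rv <- find_binding_sites(template, rev_primer, max_mismatch)
  rv <- rv[rv$strand == "-", , drop = FALSE]
  fw <- fw[fw$strand == "+", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fw))) {
    for (j in seq_len(nrow(rv))) {
      if (rv$start[j] >= fw$end[i]) {
        len <- rv$end[j] - fw$start[i]
        if (len >= size_range[[1L]] && len <= size_range[[2L]]) {
          out[[length(out) + 1L]] <- data.frame(
            template_id = template_id,
            fw_start = fw$start[i], fw_end = fw$end[i],
            rev_start = rv$start[j], rev_end = rv$end[j],
            product_length = len,
            fw_mismatches = fw$mismatches[i],
            rev_mismatches = rv$mismatches[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(template_id = character(0), fw_start = integer(0),
               fw_end = integer(0), rev_start = integer(0),
               rev_end = integer(0), product_length = integer(0),
               fw_mismatches = integer(0), rev_mismatches = integer(0))
}

#' Wallace-rule melting temperature range of a degenerate primer
#'
#' `Tm = 2(A+T) + 4(G+C)`, evaluated over the minimal-GC and maximal-GC
#' expansions of the degenerate positions. Advisory output only; reported
#' annealing optima are empirical.
#'
#' @param primer IUPAC string or `degenerate_primer`.
#' @return Named numeric `c(min = , max = )` in deg C.
#' @export
melting_temperature_range <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer <- primer$sequence
  chars <- check_iupac(primer)
  per_min <- vapply(IUPAC_SETS[chars], function(s) {
    min(ifelse(s %in% c("G", "C"), 4, 2))
  }, numeric(1L))
  per_max <- vapply(IUPAC_SETS[chars], function(s) {
    max(ifelse(s %in% c("G", "C"), 4, 2))
  }, numeric(1L))
  c(min = sum(per_min), max = sum(per_max))
}

#' Load the packaged degenerate primer definitions
#'
#' The four published insect-specific primer pairs (Dfd, Scr, Ubx, abd-A)
#' with their reported annealing temperatures and expected fragment lengths
#' (120-164 bp).
#'
#' @return Data.frame: `name`, `sequence`, `orientation`, `annealing_c`,
#'   `pair`, `expected_fragment_bp`.
#' @export
load_primer_table <- function() {
  utils::read.delim(system.file("extdata", "degenerate_primers.tsv",
                                package = "hoxrates"),
                    stringsAsFactors = FALSE)
}

#' One random plain-base expansion of an IUPAC string
#' @param sequence IUPAC string.
#' @return Plain A/C/G/T string drawn uniformly over the expansions.
#' @export
sample_expansion <- function(sequence) {
  chars <- check_iupac(sequence)
  paste(vapply(IUPAC_SETS[chars], function(s) {
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1L)), collapse = "")
}
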